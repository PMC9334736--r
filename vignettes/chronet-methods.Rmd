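---
title: "Body-wide circadian co-expression networks: models and methods"
author: "chronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Body-wide circadian co-expression networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Mammalian organs each run an autonomous circadian clock, yet homeostasis
requires those clocks to stay synchronized across the body. Given a
multi-organ time-course expression atlas — FPKM-like values for each gene in
each organ at each Zeitgeber time (ZT) over one 24-h cycle, one animal per
time point — chronet asks five questions:

1. Which genes oscillate *body-wide* (global cycling genes)?
2. Which gene *pairs* are rhythmically co-expressed — i.e. the correlation of
   their expression **across organs**, computed separately at each time
   point, itself oscillates over the day?
3. How do weighted co-expression networks built at each time point differ in
   topology, in particular between noon and midnight?
4. Which modules of the all-sample co-expression network are themselves
   rhythmic?
5. Which disease gene sets form significant network modules at specific
   times of day, and how close are gene sets on an interactome (network
   proximity)?

Every stage is exercised end-to-end on a synthetic atlas/interactome
generator with planted ground truth, so the statistical claims of the
pipeline (power, FDR control, calibration) are testable without external
downloads.

# The rhythm engine

## Statistic

A series is arranged as ordered time groups (one per ZT); with organs stacked
as replicates a group holds the organ values at that ZT. For a reference
cosine waveform with period $T$ and phase lag $\varphi$ evaluated at the
group times, the test statistic is the Kendall-type concordance count

$$S = \sum_{(i,j)} \operatorname{sign}(x_i - x_j)\,
      \operatorname{sign}(r_i - r_j),$$

over all observation pairs with distinct reference values. Pairs tied in the
data contribute 0 and also reduce the attainable maximum (a tau-b-like
normalization $\tau = S/\max|S|$); pairs tied in the reference (cosine
symmetry produces systematic ties) are excluded from the pair universe. The
test is rank-based, hence invariant under strictly monotone transforms of the
expression values — no normalization of FPKM scale is required.

## Exact null and approximations

Under the null hypothesis of exchangeable observations, the distribution of
$S$ over random orderings is computed exactly:

* untied data: Harding-style convolution of Mann–Whitney generating
  functions (Gaussian binomial coefficients) over the reference tie blocks;
* tied data: an exact dynamic programme over block assignments of the data
  multiset, feasible when $\prod_v (m_v + 1) \le 5\times10^4$ (value
  multiplicities $m_v$) and $N \le 30$;
* otherwise (default beyond 50 observations): a normal approximation with
  continuity correction and the classical tie-corrected variance of Kendall's
  $S$ (validated in the test suite against the exact pmf's variance).

The exact pmf is verified against full permutation enumeration for all
configurations with up to 8 observations, including replicate and tie
structures. One subtlety the enumeration exposed: with *tied data* the null
pmf of $S$ is generally **not** symmetric about 0 (tie position skews it);
symmetry holds exactly for untied data.

## Reference grid and within-gene multiplicity

The default grid tests the 24-h period only — the design targets diurnal
rhythmicity on a single cycle — with one phase lag per sampling interval (12
lags at 2-h sampling). Duplicate rank patterns are deduplicated. A lag and
its half-period shift produce mirrored statistics and identical two-sided
p-values, so the 12 lags collapse to 6 effective two-sided tests.

The per-gene p-value is the minimum over references, Bonferroni-adjusted by
the number of reversal-collapsed distinct rank patterns (6 by default). The
unadjusted minimum is available as `multiplicity = "minp"`, but it is
anti-conservative under the null (the minimum of ~6 correlated uniform
p-values), and the pipeline's contract is that pure-noise p-values are
stochastically *no smaller than* uniform; the Bonferroni default satisfies
that (conservatively) and is what the FDR-control guarantees are stated for.

Phase is reported as the best reference's lag (ties broken by minimum p, then
maximum $S$ — which separates a phase from its antiphase — then smallest
lag). Amplitude is the absolute least-squares cosine coefficient fitted on
the group means at the best (period, phase): half the fitted peak-to-trough.
The literature does not fix an amplitude definition for this family of tests;
this one is deterministic and scale-faithful.

# Stage models

**Global cycling.** All organ values at a time point are pooled as
replicates (240 observations at 20 organs × 12 ZT; 756 at 63 organs), the
engine runs per gene, and Benjamini–Hochberg is applied across genes at
$\alpha = 0.05$. Robustness is assessed by leave-one-organ-out re-detection;
the summary reports the fraction of full-data cyclers reproduced in at least
half and in all runs. Phase concordance compares each cycler's body-wide
phase with the circular median (minimizer of summed circular distances, ties
to the smaller ZT) of its per-organ phases over organs where it is
individually rhythmic (per-organ BH at the same $\alpha$); the correlation is
Pearson on the linear ZT scale, the field's plotting convention — adequate
here because phases concentrate at ZT06/ZT18, away from the wrap-around.

**Rhythmic interactions.** For a gene pair, Spearman correlation across
organs at each ZT gives a 12-point series; the engine tests it with a single
replicate per group (exact Harding null, cached per tie-block structure), BH
within each sampled batch (10,000 pairs × 100 repeats at full scale; the
synthetic study uses 2,000-pair batches). Series are z-scored with the
population (divide-by-$n$) standard deviation over the fixed 12 values for
export. Pairs with more than 25% undefined coefficients (zero cross-organ
variance at a ZT) are excluded with a reason; isolated undefined points are
dropped from that pair's test.

**Co-expression networks.** Unsigned soft-thresholded adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta}$ with $\beta = 16$, the
conventional power for unsigned body-wide networks. The six fundamental
network concepts use the standard weighted-network formulas: connectivity
$k_i=\sum_j a_{ij}$; cluster coefficient
$\sum_{j\neq k} a_{ij}a_{jk}a_{ki} / (k_i^2 - \sum_j a_{ij}^2)$; maximum
adjacency ratio $\sum_j a_{ij}^2/\sum_j a_{ij}$; density
$\sum_i k_i/(n(n-1))$; centralization $\frac{n}{n-2}(\max k/(n-1) -
\text{density})$; heterogeneity $\mathrm{sd}(k)/\mathrm{mean}(k)$
(population sd). All six are checked against an independent brute-force
implementation to $10^{-10}$.

**Modules.** Unsigned topological overlap
$\omega_{ij} = (L_{ij}+a_{ij})/(\min(k_i,k_j)+1-a_{ij})$, average-linkage
clustering of $1-\omega$, and a deterministic fixed-height cut (default 0.95
on the $1-\omega$ scale) with clusters below 30 genes left unassigned — a
simplified, reproducible stand-in for dynamic tree cutting. Module *count* on
real data is therefore descriptive, not a reproduction target; what is
contractual is that planted blocks (within-correlation 0.9) are recovered
with ≤5% misassignment and pure noise stays ≥95% unassigned. The module
eigengene is the unit-norm first principal component of the standardized
member rows, sign-oriented to correlate positively with members; eigengene
and module mean expression are each grouped by ZT (organs as replicates) and
tested; a module is rhythmic if either variant passes BH across modules.

**Network comparison (ZT06 vs ZT18).** Differential connectivity flags genes
with fold change $\max(k_A,k_B)/\min(k_A,k_B) > 2$; when exactly one side is
0 a machine-epsilon pseudo-count keeps the ratio finite and the gene is
flagged separately. The per-gene Euclidean distance is taken between the
gene's adjacency rows over common partners. Pairwise differences
$|w_A - w_B|$ are computed on the raw $|\mathrm{cor}|$ scale by default
(adjacency de-powered by $1/\beta$) — comparing "correlation coefficients"
rather than their 16th powers — with a flag for the powered scale. Module
similarity is the Jaccard index over all module pairs; consensus modules are
mutual best matches with $J \ge 0.3$.

**Network medicine.** Unweighted graphs connect genes whose Pearson
correlation across organs at one ZT exceeds 0.8 (strict, signed; an
$|\mathrm{cor}|$ mode is available). The disease-module distance $d_s$ is the
mean over disease genes of the hop distance to the nearest other disease
gene; significance comes from uniformly random same-size sets. Gene-set
proximity is

$$d_{AB}=\frac{1}{\|A\|+\|B\|}\Big(\sum_{a\in A}\min_{b\in B} d(a,b)
 + \sum_{b\in B}\min_{a\in A} d(a,b)\Big),$$

scored against random set pairs matched in size and degree distribution
(log2-degree bins with a minimum occupancy of 10 nodes, widened until
satisfiable). All computations are restricted to the largest connected
component — the common network-medicine convention — with dropped genes
reported, and the full LCC distance matrix is precomputed once so the
permutation loops are array lookups.

Empirical p-values use the add-one estimator
$p = (1 + \#\{\text{null} \le \text{obs}\})/(n_{\text{perm}}+1)$. Because
$d_s$ and $d_{AB}$ are discrete, that estimator is conservative at the
atoms and cannot be exactly uniform under the null; a companion
`p_smoothed` with randomized tie-breaking (reproducible from the seed) is
reported alongside, and it is the quantity whose null uniformity the
calibration tests assert (KS distance below the 1% critical value over 200
null draws). The reported `p_empirical` keeps the conventional, conservative
form.

# The synthetic atlas generator

The generator emulates the statistical structure the pipeline assumes:

* **Baselines**: per-gene log-normal level (meanlog $\log 5$, sdlog 0.4)
  with mild per-organ wobble (sdlog 0.1) — non-negative, organ-structured,
  FPKM-like.
* **Global cyclers** (default 20%): a shared cosine with one phase per gene
  drawn from a 50/50 von Mises mixture at ZT06/ZT18 ($\kappa = 2$),
  amplitude 2 against noise sd 1 (the amplitude/noise = 2 regime the
  pipeline's power guarantees are stated at).
* **Organ cyclers** (default 20%): the same rhythm applied in a random organ
  subset with organ-specific uniform phases.
* **Coupled pairs**: both members load on a pair-specific organ-level latent
  factor $L_o \sim N(0,1)$; member 1 with constant loading $c$, member 2
  with loading $c\cos(2\pi(t-\psi)/T)$. The pair's cross-organ correlation
  then oscillates **sinusoidally with 24-h period**, peaking at $\psi$ and
  turning negative in antiphase. (Modulating *both* members identically
  would make the correlation proportional to the squared modulation —
  non-negative and 12-h periodic — which a 24-h reference grid cannot
  detect; the asymmetric-loading design is what makes "coupling phase"
  well defined.) Planted pairs are allocated across cycling strata
  (both/one/neither = 0.5/0.3/0.2) so the stratified ordering of rhythmic
  proportions is a planted, testable property.
* **Modules**: members share a standardized latent profile (cosine plus an
  organ factor for rhythmic modules; an organ factor plus temporal noise for
  flat ones) scaled so the within-module correlation hits its target (0.9).
* **Night coupling** (off by default): a global organ factor whose per-gene
  couplings are multiplied by a night gain at night ZTs — the planted cause
  of day/night topological dimorphism.
* **Clipping**: negative values are set to 0 and the clip rate reported.
  Coupled-pair and module genes receive a baseline floor (three times their
  shared-signal scale plus two noise sd), and module members use organ-flat
  baselines; without that headroom, clipping erases the planted covariance
  and the expression filter removes the plants — the ground-truth contract
  (planted signal is present and detectable) would silently fail.

What the generator does **not** model: read-count (negative binomial) noise,
library-size effects, batch structure, and inter-individual variability
beyond the one-animal-per-time-point design. Passing tests therefore
demonstrate the statistical machinery under idealized Gaussian-plus-baseline
conditions, not performance on raw sequencing data.

The interactome generator produces a connected scale-free (or
Erdős–Rényi) graph; planted disease modules are BFS prefixes (connected by
construction); planted proximal set pairs are built so the second set
*covers* the first (one node within the hop budget per member) — free
sampling from the hop ball leaves half the proximity terms uncontrolled on a
small-world graph and the "planted" pair would barely beat the
degree-matched null.

# Numerical and design choices

* Expression filter: value strictly > 0 at ≥ half the time points per organ;
  per-organ verdicts combine with `organ_rule = "all"` by default so stacked
  series have no organ-specific gaps ("any" is offered for sensitivity).
* Time is ZT hours on the half-open $[0, T)$ circle; day is $[0, 12)$, so
  ZT06 is noon (day) and ZT18 midnight (night), ZT12 night by the half-open
  convention.
* All randomness flows from one master seed through labelled sub-streams
  (`derive_seed`), and `run_all()` reruns byte-identically for the result
  tables (the manifest alone carries timing).
* Output tables are TSV with a header and floats at 6 significant digits.
* Missing expression values are an error unless median imputation is
  explicitly requested (per gene per organ, count logged).
* Problem sizes in the shipped analysis and acceptance runs: 2,000 genes ×
  20 organs for power/FDR, 2,000 genes × 63 organs with 200 planted pairs
  for interactions, 400–600 genes for network stages, an 800-node
  interactome with 15-gene modules; permutation counts 1,000–5,000.
  These sizes give binomial margins comfortably inside the stated
  tolerances while keeping a full run in minutes.

# Known limitations

* The fixed-height tree cut is cruder than dynamic tree cutting: nested or
  close modules can merge, and module counts are not comparable to
  WGCNA-derived counts on real atlases.
* The normal-approximation regime (series over 50 observations) has a
  slightly conservative continuity correction; exactness claims apply to the
  exact regimes only.
* Pearson phase concordance on the linear ZT scale is a convention, not a
  circular statistic; with phase mass near ZT0 it would understate
  concordance.
* One animal per (organ, time) means organ-level baseline effects recur
  across time groups; the permutation null assumes full exchangeability.
  The concordance statistic is insensitive to *static* organ offsets (their
  net contribution cancels), but heavy organ-level heteroscedasticity could
  still distort the null — the FDR-control test runs under the generator's
  organ-structured baselines precisely to check this regime.
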