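#' Stack organs as replicates per time point
#'
#' For every gene, the group at ZT t holds the organ values at that time
#' point; organ order is fixed and identical across genes. This is the pooled
#' series the global-cycling test runs on.
#'
#' @param atlas an `ExpressionAtlas` (filtered, so no organ-specific gaps).
#' @return object of class `StackedSeries`: matrix `X` (genes x observations),
#'   `groups` (time-group index per observation), `zt_times`, `organ_ids`.
#' @export
stack_by_time <- function(atlas) {
  ng <- length(atlas$gene_ids); no <- length(atlas$organ_ids)
  nt <- length(atlas$zt_times)
  # columns ordered time-major: all organs at ZT1, then ZT2, ...
  X <- matrix(aperm(atlas$values, c(1, 2, 3)), nrow = ng)  # organ fastest
  dim(X) <- c(ng, no * nt)
  rownames(X) <- atlas$gene_ids
  structure(list(X = X, groups = rep(seq_len(nt), each = no),
                 zt_times = atlas$zt_times, organ_ids = atlas$organ_ids),
            class = "StackedSeries")
}

#' Extract one gene's stacked series as a `GroupedSeries`
#' @param stacked a `StackedSeries`.
#' @param gene gene identifier or row index.
#' @export
as_grouped_series <- function(stacked, gene) {
  x <- stacked$X[gene, ]
  grouped_series(split(x, stacked$groups), stacked$zt_times)
}

#' Detect global cycling genes
#'
#' Runs the rhythm test on every gene's organ-stacked series, adjusts across
#' genes by Benjamini-Hochberg, and calls genes with adjusted p below `alpha`.
#' Optionally also tests each gene within each organ (needed for phase
#' concordance summaries and peak-organ counts).
#'
#' @param atlas an `ExpressionAtlas` with >= 2 organs.
#' @param alpha BH-adjusted significance threshold.
#' @param references optional `ReferenceSet` (default: standard grid).
#' @param per_organ also compute per-organ rhythm results.
#' @param multiplicity passed to [rhythm_scan()].
#' @return object of class `GlobalCyclingTable`: `table` (per-gene results
#'   with `p_adj`, `is_global_cycler`), optional `per_organ` (p_adj and phase
#'   matrices, gene x organ), `n_organs_peaking` (gene x ZT counts of organs
#'   whose fitted peak falls at that ZT), `alpha`.
#' @export
detect_global_cycling <- function(atlas, alpha = 0.05, references = NULL,
                                  per_organ = FALSE,
                                  multiplicity = "patterns") {
  if (length(atlas$organ_ids) < 2) stop("need >= 2 organs")
  if (is.null(references)) references <- build_references(atlas$zt_times)
  st <- stack_by_time(atlas)
  res <- rhythm_scan(st$X, st$groups, references, multiplicity = multiplicity)
  res$p_adj <- adjust_bh(res$p_raw)
  res$is_global_cycler <- res$p_adj < alpha
  tab <- cbind(data.frame(gene = atlas$gene_ids, stringsAsFactors = FALSE),
               res)
  out <- list(table = tab, alpha = alpha, per_organ = NULL,
              n_organs_peaking = NULL)
  if (per_organ) {
    ng <- length(atlas$gene_ids); no <- length(atlas$organ_ids)
    nt <- length(atlas$zt_times)
    p_adj <- phase_m <- matrix(NA_real_, ng, no,
                               dimnames = list(atlas$gene_ids,
                                               atlas$organ_ids))
    for (oi in seq_len(no)) {
      r <- rhythm_scan(atlas$values[, oi, , drop = TRUE], seq_len(nt),
                       references, multiplicity = multiplicity)
      p_adj[, oi] <- adjust_bh(r$p_raw)   # per-organ BH across genes
      phase_m[, oi] <- r$phase
    }
    peaks <- matrix(0L, ng, nt, dimnames = list(atlas$gene_ids,
                                                paste0("ZT", atlas$zt_times)))
    for (oi in seq_len(no)) {
      ti <- match(phase_m[, oi], atlas$zt_times)
      ok <- !is.na(ti) & p_adj[, oi] < alpha
      idx <- cbind(which(ok), ti[ok])
      peaks[idx] <- peaks[idx] + 1L
    }
    out$per_organ <- list(p_adj = p_adj, phase = phase_m)
    out$n_organs_peaking <- peaks
  }
  class(out) <- "GlobalCyclingTable"
  out
}

#' Leave-one-organ-out robustness of global cycling calls
#'
#' Reruns the global-cycling detection with each organ removed in turn and
#' reports, per gene, the number of runs in which it is called, plus the
#' fractions of full-data cyclers reproduced in at least half of the runs and
#' in all runs.
#'
#' @param atlas an `ExpressionAtlas` with >= 3 organs.
#' @param alpha BH threshold.
#' @param references optional `ReferenceSet`.
#' @return list: `counts` (gene, n_called, n_runs), `summary` (frac_half,
#'   frac_all over full-data cyclers), `full` (the full-data
#'   `GlobalCyclingTable`).
#' @export
leave_one_out <- function(atlas, alpha = 0.05, references = NULL) {
  no <- length(atlas$organ_ids)
  if (no < 3) stop("need >= 3 organs for leave-one-out")
  if (is.null(references)) references <- build_references(atlas$zt_times)
  full <- detect_global_cycling(atlas, alpha, references)
  n_called <- integer(length(atlas$gene_ids))
  for (oi in seq_len(no)) {
    sub <- subset_atlas(atlas, organs = atlas$organ_ids[-oi])
    res <- detect_global_cycling(sub, alpha, references)
    n_called <- n_called + res$table$is_global_cycler
  }
  cyc <- full$table$is_global_cycler
  summary <- c(frac_half = mean(n_called[cyc] >= no / 2),
               frac_all = mean(n_called[cyc] == no))
  list(counts = data.frame(gene = atlas$gene_ids, n_called = n_called,
                           n_runs = no, stringsAsFactors = FALSE),
       summary = summary, full = full)
}

#' Phase concordance between global and per-organ rhythms
#'
#' For each global cycler, the circular median of its fitted phases over the
#' organs where it is per-organ rhythmic (per-organ BH at the same alpha), and
#' the Pearson correlation between global phase and median organ phase on the
#' linear ZT scale (the field's convention; phases are circular, so the
#' correlation is reported with that caveat).
#'
#' @param cycling a `GlobalCyclingTable` computed with `per_organ = TRUE`.
#' @param period cycle length in hours.
#' @return list: `table` (gene, global_phase, median_organ_phase,
#'   n_rhythmic_organs), `r` (Pearson concordance), `n_excluded` (cyclers
#'   rhythmic in zero organs).
#' @export
phase_summary <- function(cycling, period = 24) {
  if (is.null(cycling$per_organ))
    stop("per-organ results missing; rerun detect_global_cycling(per_organ = TRUE)")
  tab <- cycling$table[cycling$table$is_global_cycler, ]
  med <- n_org <- rep(NA_real_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene[i]
    ok <- cycling$per_organ$p_adj[g, ] < cycling$alpha &
      !is.na(cycling$per_organ$phase[g, ])
    n_org[i] <- sum(ok)
    if (any(ok))
      med[i] <- circular_median(cycling$per_organ$phase[g, ok], period)
  }
  keep <- n_org > 0
  r <- if (sum(keep) >= 3)
    stats::cor(tab$phase[keep], med[keep]) else NA_real_
  list(table = data.frame(gene = tab$gene, global_phase = tab$phase,
                          median_organ_phase = med,
                          n_rhythmic_organs = n_org,
                          stringsAsFactors = FALSE),
       r = r, n_excluded = sum(!keep))
}

#' Fisher's exact enrichment of a gene set among called genes
#'
#' Two-sided Fisher's exact test on the 2x2 table (in set x called) over the
#' given background; the conditional-MLE odds ratio is reported.
#'
#' @param calls named logical vector (names = genes, TRUE = called).
#' @param gene_set character vector of set members.
#' @param background gene universe (default: names of `calls`).
#' @return one-row data.frame: counts, `odds_ratio`, `p`.
#' @export
enrichment_fisher <- function(calls, gene_set, background = names(calls)) {
  stopifnot(!is.null(names(calls)))
  gene_set <- intersect(unique(gene_set), background)
  if (length(gene_set) == 0)
    stop("gene set does not intersect the background")
  calls <- calls[background]
  in_set <- background %in% gene_set
  tab <- table(factor(in_set, c(TRUE, FALSE)),
               factor(calls, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(data.frame(n_set_called = tab[1, 1], n_set = sum(tab[1, ]),
                      n_called = sum(tab[, 1]), n_background = sum(tab),
                      odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  data.frame(n_set_called = tab[1, 1], n_set = sum(tab[1, ]),
             n_called = sum(tab[, 1]), n_background = sum(tab),
             odds_ratio = unname(ft$estimate), p = ft$p.value,
             degenerate = FALSE)
}

#' Batch enrichment with BH correction across sets
#' @param calls named logical vector of calls.
#' @param sets named list of gene sets (e.g. a `GeneSetList`).
#' @param background gene universe.
#' @return data.frame with one row per set, plus BH-adjusted `q`.
#' @export
enrichment_fisher_batch <- function(calls, sets, background = names(calls)) {
  rows <- lapply(names(sets), function(nm)
    cbind(set = nm, enrichment_fisher(calls, sets[[nm]], background)))
  out <- do.call(rbind, rows)
  out$q <- adjust_bh(out$p)
  out
}
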