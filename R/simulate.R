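#' Simulation configuration for a synthetic multi-organ circadian atlas
#'
#' Defaults emulate a body-wide diurnal atlas in miniature: 63 organs sampled
#' every 2 h over one 24 h cycle, non-negative FPKM-like baselines that vary
#' by gene (log-normal) with mild organ-specific variation, a planted fraction
#' of body-wide cyclers whose shared phases follow a bimodal von Mises mixture
#' peaked at ZT06/ZT18, organ-restricted cyclers with organ-specific phases,
#' coupled gene pairs whose cross-organ correlation oscillates over the day,
#' optional correlated modules, and an optional organ-level factor whose
#' coupling is amplified at night.
#'
#' @param seed integer seed (mandatory; no implicit entropy).
#' @param n_genes,n_organs,zt_times atlas dimensions.
#' @param fraction_global_cyclers,fraction_organ_cyclers planted class
#'   fractions (sum must be <= 1; the rest are arrhythmic).
#' @param amplitude cosine half peak-to-trough, expression units.
#' @param noise_sd i.i.d. Gaussian noise sd.
#' @param baseline_meanlog,baseline_sdlog log-normal per-gene baseline.
#' @param organ_sdlog sd of the per-(gene, organ) log-scale baseline wobble.
#' @param phase_kappa von Mises concentration of the bimodal phase mixture.
#' @param n_coupled_pairs pairs with time-modulated coupling.
#' @param coupling_strength loading of the pair-level organ latent factor,
#'   in units of expression (detectability is governed by
#'   coupling_strength / noise_sd).
#' @param coupling_class_mix how planted pairs distribute over cycling strata
#'   (both members cyclers / one / neither).
#' @param modules NULL or list with `sizes`, `rhythmic` (logical per module),
#'   `phases` (hours per module), `within_cor` (target member correlation).
#' @param night_factor list(loading_sd, night_gain): a shared organ factor
#'   whose gene couplings are multiplied by `night_gain` at night ZTs
#'   (loading_sd = 0 disables it).
#' @param period_hours cycle length.
#' @return validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       n_genes = 2000, n_organs = 63,
                       zt_times = seq(0, 22, by = 2),
                       fraction_global_cyclers = 0.2,
                       fraction_organ_cyclers = 0.2,
                       amplitude = 2, noise_sd = 1,
                       baseline_meanlog = log(5), baseline_sdlog = 0.4,
                       organ_sdlog = 0.1, phase_kappa = 2,
                       n_coupled_pairs = 0, coupling_strength = 2,
                       coupling_class_mix = c(both = 0.5, one = 0.3,
                                              neither = 0.2),
                       modules = NULL,
                       night_factor = list(loading_sd = 0, night_gain = 1),
                       period_hours = 24) {
  if (missing(seed)) stop("seed is mandatory")
  fr <- c(fraction_global_cyclers, fraction_organ_cyclers)
  stopifnot(all(fr >= 0), all(fr <= 1), sum(fr) <= 1,
            n_genes >= 1, n_organs >= 2, length(zt_times) >= 4,
            amplitude >= 0, noise_sd >= 0, n_coupled_pairs >= 0,
            coupling_strength >= 0)
  if (!is.null(modules)) {
    stopifnot(is.list(modules), !is.null(modules$sizes))
    if (sum(modules$sizes) > n_genes)
      stop("infeasible config: module sizes exceed gene count")
    if (is.null(modules$within_cor)) modules$within_cor <- 0.9
    if (is.null(modules$rhythmic))
      modules$rhythmic <- rep(TRUE, length(modules$sizes))
    if (is.null(modules$phases))
      modules$phases <- rep(c(6, 18), length.out = length(modules$sizes))
  }
  if (2 * n_coupled_pairs > n_genes)
    stop("infeasible config: coupled pairs exceed gene count")
  structure(as.list(environment()), class = "SimulationConfig")
}

# von Mises sampler (Best & Fisher 1979 rejection); mu in radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Simulate a multi-organ circadian expression atlas with known ground truth
#'
#' Global cyclers receive `baseline(g,o) + amplitude * cos(2*pi*(t - phi_g)/T)
#' + noise` with one phase per gene shared across organs (bimodal von Mises
#' mixture at ZT06/ZT18); organ cyclers apply the rhythm only in a random
#' organ subset with organ-specific phases; coupled pairs share an organ-level
#' latent factor whose loading on the second member is cosine-modulated in
#' time, so the pair's cross-organ correlation oscillates over the day with
#' maximum at the coupling phase; negative values are clipped to 0 (clip rate
#' reported).
#'
#' @param config a `SimulationConfig` from [sim_config()].
#' @return list with `atlas` (an `ExpressionAtlas`) and `truth` (per-gene
#'   classes/phases, planted pairs, module membership, clip rate).
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, "atlas"))
  ng <- config$n_genes; no <- config$n_organs
  zt <- config$zt_times; nt <- length(zt)
  period_h <- config$period_hours
  genes <- sprintf("g%04d", seq_len(ng))
  organs <- sprintf("organ%02d", seq_len(no))

  # class assignment; module genes are carved out first and labelled by their
  # module's rhythmicity so the ground-truth covers every gene exactly once
  class <- rep("flat", ng)
  phase <- rep(NA_real_, ng)
  amp <- rep(0, ng)
  module <- rep(0L, ng)
  idx_free <- seq_len(ng)
  mod_plan <- config$modules
  if (!is.null(mod_plan)) {
    pos <- 1L
    for (mi in seq_along(mod_plan$sizes)) {
      take <- idx_free[pos:(pos + mod_plan$sizes[mi] - 1L)]
      module[take] <- mi
      pos <- pos + mod_plan$sizes[mi]
    }
    idx_free <- idx_free[module[idx_free] == 0L]
  }
  n_gc <- round(config$fraction_global_cyclers * ng)
  n_oc <- round(config$fraction_organ_cyclers * ng)
  if (n_gc + n_oc > length(idx_free))
    stop("infeasible config: cycler fractions exceed genes left after modules")
  gc_idx <- idx_free[seq_len(n_gc)]
  oc_idx <- idx_free[n_gc + seq_len(n_oc)]
  class[gc_idx] <- "global_cycler"
  class[oc_idx] <- "organ_cycler"

  # bimodal body-wide phases at ZT06 / ZT18
  comp <- sample(c(6, 18), n_gc, replace = TRUE)
  phase[gc_idx] <- (rvonmises(n_gc, 0, config$phase_kappa) / (2 * pi) * period_h +
                      comp) %% period_h
  amp[gc_idx] <- config$amplitude

  base_gene <- stats::rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
  baseline <- base_gene * exp(matrix(stats::rnorm(ng * no, 0, config$organ_sdlog),
                                     ng, no))
  vals <- array(stats::rnorm(ng * no * nt, 0, config$noise_sd),
                dim = c(ng, no, nt))
  vals <- vals + as.vector(baseline)   # recycles over the time dimension

  for (g in gc_idx)
    vals[g, , ] <- vals[g, , ] +
      config$amplitude * matrix(cos(2 * pi * (zt - phase[g]) / period_h),
                                no, nt, byrow = TRUE)

  organ_sets <- vector("list", ng)
  for (g in oc_idx) {
    k <- sample(2:max(2, floor(no / 2)), 1)
    os <- sort(sample.int(no, k))
    organ_sets[[g]] <- organs[os]
    for (o in os) {
      ph <- stats::runif(1, 0, period_h)
      vals[g, o, ] <- vals[g, o, ] + config$amplitude *
        cos(2 * pi * (zt - ph) / period_h)
    }
    phase[g] <- NA_real_
    amp[g] <- config$amplitude
  }

  # planted modules: members share a standardized latent profile scaled so the
  # target within-module correlation holds against the noise floor
  if (!is.null(mod_plan)) {
    rw <- mod_plan$within_cor
    s_share <- config$noise_sd * sqrt(rw / (1 - rw))
    # members need headroom above zero, as for coupled pairs below
    floor_m <- 3 * s_share + 2 * config$noise_sd
    for (mi in seq_along(mod_plan$sizes)) {
      members <- which(module == mi)
      for (g in members) {
        # organ-flat baseline at or above the floor: the module latent M_o
        # carries the organ structure, and static per-organ wobble would
        # otherwise dilute the realized within-module correlation below the
        # configured target
        nb <- max(base_gene[g], floor_m)
        vals[g, , ] <- vals[g, , ] + (nb - as.vector(baseline[g, ]))
        baseline[g, ] <- nb
      }
      M_o <- stats::rnorm(no)
      if (mod_plan$rhythmic[mi]) {
        Z <- outer(M_o * 0.5, rep(1, nt)) +
          matrix(cos(2 * pi * (zt - mod_plan$phases[mi]) / period_h), no, nt,
                 byrow = TRUE)
        class[members] <- "global_cycler"
        phase[members] <- mod_plan$phases[mi]
      } else {
        Z <- outer(M_o * 0.8, rep(1, nt)) +
          matrix(stats::rnorm(no * nt, 0, 0.6), no, nt)
        class[members] <- "flat"
      }
      Z <- (Z - mean(Z)) / pop_sd(as.vector(Z))
      for (g in members) vals[g, , ] <- vals[g, , ] + s_share * Z
      if (mod_plan$rhythmic[mi])
        amp[members] <- s_share * pop_sd(cos(2 * pi * (zt - mod_plan$phases[mi]) / period_h)) * sqrt(2)
    }
  }

  # coupled pairs: member 1 carries a constant loading on a pair-specific
  # organ factor, member 2 a cosine-modulated loading, so the cross-organ
  # correlation oscillates with 24 h period and peaks at psi
  pairs <- NULL
  if (config$n_coupled_pairs > 0) {
    mix <- config$coupling_class_mix / sum(config$coupling_class_mix)
    n_both <- round(config$n_coupled_pairs * mix[["both"]])
    n_one <- round(config$n_coupled_pairs * mix[["one"]])
    n_neither <- config$n_coupled_pairs - n_both - n_one
    pool_c <- setdiff(gc_idx, integer(0))
    pool_f <- setdiff(which(class == "flat" & module == 0L), integer(0))
    need_c <- 2 * n_both + n_one
    need_f <- n_one + 2 * n_neither
    if (need_c > length(pool_c) || need_f > length(pool_f))
      stop("infeasible config: not enough genes for the coupled-pair strata")
    take_c <- sample(pool_c, need_c)
    take_f <- sample(pool_f, need_f)
    g1 <- integer(0); g2 <- integer(0); stratum <- character(0)
    ci <- 1L; fi <- 1L
    for (i in seq_len(n_both)) {
      g1 <- c(g1, take_c[ci]); g2 <- c(g2, take_c[ci + 1L]); ci <- ci + 2L
      stratum <- c(stratum, "both")
    }
    for (i in seq_len(n_one)) {
      g1 <- c(g1, take_c[ci]); ci <- ci + 1L
      g2 <- c(g2, take_f[fi]); fi <- fi + 1L
      stratum <- c(stratum, "one")
    }
    for (i in seq_len(n_neither)) {
      g1 <- c(g1, take_f[fi]); g2 <- c(g2, take_f[fi + 1L]); fi <- fi + 2L
      stratum <- c(stratum, "neither")
    }
    psi <- sample(zt, config$n_coupled_pairs, replace = TRUE)
    # pair members need headroom above zero so the latent-factor swings are
    # not erased by non-negativity clipping (which would destroy the planted
    # correlation signal and drop the genes at the expression filter)
    floor_b <- 3 * config$coupling_strength + 2 * config$noise_sd
    for (g in unique(c(g1, g2))) {
      bump <- pmax(floor_b - min(baseline[g, ]), 0)
      vals[g, , ] <- vals[g, , ] + bump
      baseline[g, ] <- baseline[g, ] + bump
    }
    for (i in seq_len(config$n_coupled_pairs)) {
      L <- stats::rnorm(no)
      modt <- cos(2 * pi * (zt - psi[i]) / period_h)
      vals[g1[i], , ] <- vals[g1[i], , ] + config$coupling_strength * L
      vals[g2[i], , ] <- vals[g2[i], , ] + config$coupling_strength *
        outer(L, modt)
    }
    pairs <- data.frame(gene1 = genes[g1], gene2 = genes[g2],
                        psi = psi, strength = config$coupling_strength,
                        stratum = stratum, stringsAsFactors = FALSE)
  }

  # shared organ factor with night-amplified coupling
  nf <- config$night_factor
  if (nf$loading_sd > 0) {
    F_o <- stats::rnorm(no)
    w_g <- stats::rnorm(ng, 0, nf$loading_sd)
    gain <- ifelse(assign_day_night(zt, period = period_h) == "night",
                   nf$night_gain, 1)
    for (ti in seq_len(nt))
      vals[, , ti] <- vals[, , ti] + outer(w_g, F_o) * gain[ti]
  }

  n_clip <- sum(vals < 0)
  vals[vals < 0] <- 0

  atlas <- expression_atlas(vals, genes, organs, zt, period_h)
  truth_genes <- data.frame(
    gene = genes, class = class, phase = phase, amplitude = amp,
    module = module,
    organ_set = vapply(organ_sets, function(s)
      if (is.null(s)) "" else paste(s, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  list(atlas = atlas,
       truth = list(genes = truth_genes, pairs = pairs,
                    clip_rate = n_clip / length(vals)))
}

#' Simulate an interactome with planted disease modules and proximal set pairs
#'
#' Generates a connected undirected graph (scale-free preferential attachment
#' or Erdos-Renyi), plants disease modules whose induced subgraph is connected
#' (BFS-prefix construction), and plants pairs of gene sets at a controlled
#' hop distance for proximity analyses.
#'
#' @param n_nodes number of nodes.
#' @param model `"scale_free"` (default) or `"er"`.
#' @param er_p edge probability for the ER model.
#' @param pa_m edges per step for preferential attachment.
#' @param planted_module_sizes integer vector of connected module sizes.
#' @param n_proximal_pairs number of planted proximal set pairs.
#' @param proximal_size size of each set in a planted pair.
#' @param proximal_hops hop budget: every member of the first set has a
#'   second-set node within this distance (and vice versa by construction).
#' @param seed integer seed.
#' @return list with `edges` (two-column data.frame), `graph` (igraph), and
#'   `truth` (planted modules, planted proximal pairs, augment count).
#' @export
simulate_interactome <- function(n_nodes, model = c("scale_free", "er"),
                                 er_p = 0.02, pa_m = 3,
                                 planted_module_sizes = integer(0),
                                 n_proximal_pairs = 0, proximal_size = 10,
                                 proximal_hops = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  model <- match.arg(model)
  if (length(planted_module_sizes) && max(planted_module_sizes) >= n_nodes)
    stop("contradictory constraints: planted module at least as large as graph")
  set.seed(derive_seed(seed, "interactome"))
  g <- if (model == "er") igraph::sample_gnp(n_nodes, er_p)
       else igraph::sample_pa(n_nodes, m = pa_m, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%05d", seq_len(n_nodes))
  # guarantee one connected component (augmenting edges logged)
  comp <- igraph::components(g)
  n_augment <- 0L
  while (comp$no > 1) {
    a <- which(comp$membership == 1)[1]
    b <- which(comp$membership == 2)[1]
    g <- igraph::add_edges(g, c(a, b))
    n_augment <- n_augment + 1L
    comp <- igraph::components(g)
  }
  nodes <- igraph::V(g)$name

  modules <- list()
  for (mi in seq_along(planted_module_sizes)) {
    k <- planted_module_sizes[mi]
    root <- sample.int(n_nodes, 1)
    ord <- igraph::bfs(g, root = root, order = TRUE)$order
    members <- nodes[as.integer(ord)[seq_len(k)]]  # BFS prefix: connected
    modules[[mi]] <- members
  }

  proximal <- list()
  if (n_proximal_pairs > 0) {
    for (pi in seq_len(n_proximal_pairs)) {
      root <- sample.int(n_nodes, 1)
      ord <- as.integer(igraph::bfs(g, root = root, order = TRUE)$order)
      A <- nodes[ord[seq_len(proximal_size)]]
      dA <- suppressWarnings(igraph::distances(g, v = A, to = igraph::V(g)))
      # cover every member of A: one node within the hop budget per member,
      # so both directional terms of the proximity are controlled
      B <- character(0)
      for (a in seq_along(A)) {
        cand <- setdiff(nodes[dA[a, ] >= 1 & dA[a, ] <= proximal_hops], A)
        cand <- setdiff(cand, B)
        if (length(cand)) B <- c(B, sample(cand, 1))
      }
      extra <- setdiff(nodes[apply(dA, 2, min) >= 1 &
                               apply(dA, 2, min) <= proximal_hops],
                       c(A, B))
      if (length(B) < proximal_size) {
        if (length(extra) < proximal_size - length(B))
          stop("contradictory constraints: not enough nodes within hop distance")
        B <- c(B, sample(extra, proximal_size - length(B)))
      } else if (length(B) > proximal_size) {
        B <- B[seq_len(proximal_size)]
      }
      proximal[[pi]] <- list(A = A, B = B)
    }
  }

  em <- igraph::as_edgelist(g)
  edges <- canonical_edges(data.frame(from = em[, 1], to = em[, 2],
                                      stringsAsFactors = FALSE))
  list(edges = edges, graph = g,
       truth = list(modules = modules, proximal_pairs = proximal,
                    n_augment = n_augment))
}
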