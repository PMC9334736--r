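#' Flatten an atlas to a genes x samples matrix
#'
#' Samples are (organ, ZT) combinations, time-major (all organs at ZT1, then
#' ZT2, ...), matching [stack_by_time()]. Sample metadata is attached.
#'
#' @param atlas an `ExpressionAtlas` (or `StandardizedAtlas`).
#' @return matrix with attribute `samples`: data.frame(organ, zt).
#' @export
flatten_atlas <- function(atlas) {
  ng <- length(atlas$gene_ids); no <- length(atlas$organ_ids)
  nt <- length(atlas$zt_times)
  X <- atlas$values
  dim(X) <- c(ng, no * nt)
  rownames(X) <- atlas$gene_ids
  meta <- data.frame(organ = rep(atlas$organ_ids, nt),
                     zt = rep(atlas$zt_times, each = no),
                     stringsAsFactors = FALSE)
  colnames(X) <- paste0(meta$organ, "_ZT", formatC(meta$zt, width = 2,
                                                   flag = "0"))
  attr(X, "samples") <- meta
  X
}

#' Build a soft-thresholded weighted co-expression network
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` (Pearson by default) with
#' zero diagonal. Genes with zero variance over the selected samples are
#' excluded and reported.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param beta soft power (>= 1; the default 16 is the conventional choice
#'   for unsigned body-wide networks).
#' @param scope free-text label (`"all-samples"`, `"ZT06"`, ...).
#' @return object of class `WeightedNetwork`: `adjacency`, `nodes`, `beta`,
#'   `scope`, `dropped` (zero-variance genes).
#' @export
build_network <- function(expr, beta = 16, scope = "all-samples") {
  if (beta < 1) stop("beta must be >= 1")
  if (ncol(expr) < 3) stop("need >= 3 samples in scope")
  v <- apply(expr, 1, stats::var)
  dropped <- rownames(expr)[v == 0]
  expr <- expr[v > 0, , drop = FALSE]
  A <- abs(stats::cor(t(expr)))^beta
  diag(A) <- 0
  structure(list(adjacency = A, nodes = rownames(expr), beta = beta,
                 scope = scope, dropped = dropped),
            class = "WeightedNetwork")
}

#' The six fundamental network concepts
#'
#' Node level: connectivity `k_i = sum_j a_ij`; cluster coefficient
#' `(sum_{j,k} a_ij a_jk a_ki) / (k_i^2 - sum_j a_ij^2)`; maximum adjacency
#' ratio `MAR_i = sum_j a_ij^2 / sum_j a_ij`. Network level: density
#' `sum_i k_i / (n (n-1))`; centralization `n/(n-2) (max k/(n-1) - density)`;
#' heterogeneity `sd(k)/mean(k)` (population sd). Isolated nodes get
#' MAR and cluster coefficient 0, flagged.
#'
#' @param net a `WeightedNetwork` (or a symmetric adjacency matrix with zero
#'   diagonal).
#' @return object of class `NetworkConcepts`: `node` (data.frame),
#'   `network` (one-row data.frame), `isolated` (flagged nodes).
#' @export
fundamental_concepts <- function(net) {
  A <- if (inherits(net, "WeightedNetwork")) net$adjacency else net
  n <- nrow(A)
  if (n < 3) stop("need >= 3 nodes")
  k <- rowSums(A)
  sq <- rowSums(A^2)
  tri <- diag(A %*% A %*% A)
  denom <- k^2 - sq
  cc <- ifelse(denom > 0, tri / denom, 0)
  mar <- ifelse(k > 0, sq / k, 0)
  density <- sum(k) / (n * (n - 1))
  centralization <- n / (n - 2) * (max(k) / (n - 1) - density)
  heterogeneity <- if (mean(k) > 0)
    sqrt(mean(k^2) / mean(k)^2 - 1) else 0
  structure(list(
    node = data.frame(node = if (is.null(rownames(A))) as.character(seq_len(n))
                      else rownames(A),
                      connectivity = k, cluster_coef = cc, mar = mar,
                      stringsAsFactors = FALSE, row.names = NULL),
    network = data.frame(density = density, centralization = centralization,
                         heterogeneity = heterogeneity,
                         median_connectivity = stats::median(k),
                         mean_connectivity = mean(k)),
    isolated = which(k == 0)),
    class = "NetworkConcepts")
}

#' Unsigned topological overlap matrix
#'
#' `omega_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L = A %*% A`; diagonal 1.
#'
#' @param net a `WeightedNetwork` or adjacency matrix.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(net) {
  A <- if (inherits(net, "WeightedNetwork")) net$adjacency else net
  k <- rowSums(A)
  L <- A %*% A
  omega <- (L + A) / (outer(k, k, pmin) + 1 - A)
  diag(omega) <- 1
  omega
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with a
#' deterministic fixed-height cut (a simplified stand-in for dynamic tree
#' cutting); clusters below `min_module_size` become unassigned (module 0).
#' Module labels are ordered by decreasing size. Eigengenes (unit-norm first
#' principal component of the standardized member rows, sign-oriented so the
#' average correlation with members is positive) and module mean expression
#' are computed per sample.
#'
#' @param net a `WeightedNetwork`.
#' @param expr the genes x samples matrix the network was built on.
#' @param min_module_size minimum module size.
#' @param cut_height fixed cut height on the 1 - TOM scale.
#' @return object of class `ModuleAssignment`: `membership` (named integer, 0
#'   = unassigned), `eigengenes` (modules x samples), `means` (modules x
#'   samples), `sizes`.
#' @export
detect_modules <- function(net, expr, min_module_size = 30,
                           cut_height = 0.95) {
  expr <- expr[net$nodes, , drop = FALSE]
  d <- 1 - tom_similarity(net)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  if (length(big) == 0) {
    warning("no module reaches min_module_size; all genes unassigned")
    membership <- stats::setNames(rep(0L, length(cl)), net$nodes)
    return(structure(list(membership = membership,
                          eigengenes = NULL, means = NULL,
                          sizes = integer(0)),
                     class = "ModuleAssignment"))
  }
  ord <- big[order(-sizes[big], as.integer(big))]  # deterministic labels
  membership <- stats::setNames(rep(0L, length(cl)), net$nodes)
  for (m in seq_along(ord)) membership[cl == as.integer(ord[m])] <- m
  nmod <- length(ord)
  eig <- means <- matrix(NA_real_, nmod, ncol(expr),
                         dimnames = list(paste0("M", seq_len(nmod)),
                                         colnames(expr)))
  for (m in seq_len(nmod)) {
    sub <- expr[membership == m, , drop = FALSE]
    Z <- (sub - rowMeans(sub)) /
      apply(sub, 1, function(x) max(pop_sd(x), .Machine$double.eps))
    sv <- svd(Z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(e, t(sub))) < 0) e <- -e
    eig[m, ] <- e
    means[m, ] <- colMeans(sub)
  }
  structure(list(membership = membership, eigengenes = eig, means = means,
                 sizes = stats::setNames(as.integer(table(
                   factor(membership, seq_len(nmod)))), paste0("M", seq_len(nmod)))),
            class = "ModuleAssignment")
}

#' Module-level rhythmicity
#'
#' The eigengene and the module mean expression each have one value per
#' (organ, ZT) sample; both are grouped by ZT (organs as replicates, mirroring
#' the global-cycling design) and tested for rhythmicity, with BH across
#' modules. A module is rhythmic when either variant passes.
#'
#' @param assign a `ModuleAssignment`.
#' @param samples sample metadata data.frame(organ, zt) as produced by
#'   [flatten_atlas()] (attribute `samples`).
#' @param alpha BH threshold.
#' @param references optional `ReferenceSet`.
#' @param multiplicity passed to [rhythm_scan()].
#' @return data.frame per module: eigengene and mean-expression p/p_adj and
#'   phases, `rhythmic`.
#' @export
module_rhythmicity <- function(assign, samples, alpha = 0.05,
                               references = NULL, multiplicity = "patterns") {
  if (is.null(assign$eigengenes)) stop("no modules in assignment")
  zt <- sort(unique(samples$zt))
  if (is.null(references)) references <- build_references(zt)
  groups <- match(samples$zt, zt)
  re <- rhythm_scan(assign$eigengenes, groups, references,
                    multiplicity = multiplicity)
  rm_ <- rhythm_scan(assign$means, groups, references,
                     multiplicity = multiplicity)
  data.frame(module = rownames(assign$eigengenes),
             p_eigen = re$p_raw, p_adj_eigen = adjust_bh(re$p_raw),
             phase_eigen = re$phase, amplitude_eigen = re$amplitude,
             p_mean = rm_$p_raw, p_adj_mean = adjust_bh(rm_$p_raw),
             phase_mean = rm_$phase,
             rhythmic = adjust_bh(re$p_raw) < alpha |
               adjust_bh(rm_$p_raw) < alpha,
             stringsAsFactors = FALSE)
}

#' Per-module gene-set enrichment
#'
#' Fisher's exact test of set membership against module membership over the
#' full universe (assigned + unassigned genes), BH across modules.
#'
#' @param assign a `ModuleAssignment`.
#' @param gene_set character vector.
#' @return data.frame with one row per module.
#' @export
module_set_enrichment <- function(assign, gene_set) {
  universe <- names(assign$membership)
  mods <- sort(unique(assign$membership[assign$membership > 0]))
  rows <- lapply(mods, function(m) {
    calls <- stats::setNames(assign$membership == m, universe)
    cbind(module = paste0("M", m),
          enrichment_fisher(calls, gene_set, universe))
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_bh(out$p)
  out
}

#' Build the co-expression network at one time point
#'
#' @param atlas an `ExpressionAtlas`.
#' @param zt which ZT (hours).
#' @param beta soft power.
#' @return a `WeightedNetwork` over the genes x organs matrix at that ZT.
#' @export
network_at_zt <- function(atlas, zt, beta = 16) {
  ti <- match(zt, atlas$zt_times)
  if (is.na(ti)) stop("ZT", zt, " not in atlas")
  build_network(atlas$values[, , ti],
                beta = beta, scope = paste0("ZT", formatC(zt, width = 2,
                                                          flag = "0")))
}

#' Day-vs-night network topology comparison
#'
#' Builds one network per ZT from the genes x organs matrix at that time
#' point, computes the six fundamental concepts, and compares day-ZT against
#' night-ZT values of each index with a two-sided Wilcoxon rank-sum test
#' (node-level indices are summarized by their per-ZT median).
#'
#' @param atlas an `ExpressionAtlas`.
#' @param beta soft power.
#' @param day_start,day_end day window (see [assign_day_night()]).
#' @return list: `per_zt` (one row per ZT with the six indices and phase
#'   class), `tests` (Wilcoxon p per index + direction), `concepts` (list of
#'   per-ZT `NetworkConcepts`).
#' @export
day_night_topology <- function(atlas, beta = 16, day_start = 0, day_end = 12) {
  zt <- atlas$zt_times
  phase_class <- assign_day_night(zt, day_start, day_end, atlas$period_hours)
  concepts <- vector("list", length(zt))
  rows <- vector("list", length(zt))
  for (ti in seq_along(zt)) {
    net <- network_at_zt(atlas, zt[ti], beta)
    fc <- fundamental_concepts(net)
    concepts[[ti]] <- fc
    rows[[ti]] <- data.frame(
      zt = zt[ti], phase_class = phase_class[ti],
      median_connectivity = stats::median(fc$node$connectivity),
      median_cluster_coef = stats::median(fc$node$cluster_coef),
      median_mar = stats::median(fc$node$mar),
      density = fc$network$density,
      centralization = fc$network$centralization,
      heterogeneity = fc$network$heterogeneity,
      stringsAsFactors = FALSE)
  }
  per_zt <- do.call(rbind, rows)
  idx <- c("median_connectivity", "median_cluster_coef", "median_mar",
           "density", "centralization", "heterogeneity")
  day <- per_zt$phase_class == "day"
  if (sum(day) < 2 || sum(!day) < 2) {
    warning("fewer than 2 ZTs in a phase class; comparison skipped")
    tests <- NULL
  } else {
    tests <- do.call(rbind, lapply(idx, function(v) {
      w <- suppressWarnings(stats::wilcox.test(per_zt[[v]][!day],
                                               per_zt[[v]][day],
                                               exact = TRUE))
      data.frame(index = v,
                 median_day = stats::median(per_zt[[v]][day]),
                 median_night = stats::median(per_zt[[v]][!day]),
                 night_higher = stats::median(per_zt[[v]][!day]) >
                   stats::median(per_zt[[v]][day]),
                 p = w$p.value, stringsAsFactors = FALSE)
    }))
  }
  list(per_zt = per_zt, tests = tests, concepts = concepts)
}
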