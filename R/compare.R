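# Intersect two weighted networks on their common gene universe.
common_universe <- function(netA, netB) {
  common <- intersect(netA$nodes, netB$nodes)
  if (length(common) == 0) stop("disjoint gene universes")
  list(common = common,
       A = netA$adjacency[common, common],
       B = netB$adjacency[common, common],
       n_dropped = length(union(netA$nodes, netB$nodes)) - length(common))
}

#' Differentially connected genes between two networks
#'
#' Flags genes whose connectivity changes more than `fold`-fold between the
#' two networks (computed on the common gene universe). When exactly one side
#' has zero connectivity a machine-scale pseudo-count keeps the fold finite
#' and the gene is flagged separately.
#'
#' @param netA,netB `WeightedNetwork`s.
#' @param fold fold-change threshold (strict >).
#' @return data.frame: gene, `k_A`, `k_B`, `fold`, `direction`,
#'   `differential`, `zero_flag`; attribute `n_dropped` (genes outside the
#'   common universe).
#' @export
differential_connectivity <- function(netA, netB, fold = 2) {
  u <- common_universe(netA, netB)
  kA <- rowSums(u$A); kB <- rowSums(u$B)
  eps <- .Machine$double.eps
  hi <- pmax(kA, kB); lo <- pmin(kA, kB)
  zero_flag <- (lo == 0) & (hi > 0)
  fc <- ifelse(hi == 0, 1, (hi + ifelse(zero_flag, eps, 0)) /
                 (lo + ifelse(zero_flag, eps, 0)))
  out <- data.frame(gene = u$common, k_A = kA, k_B = kB, fold = fc,
                    direction = ifelse(kA > kB, "A", ifelse(kB > kA, "B",
                                                            "equal")),
                    differential = fc > fold, zero_flag = zero_flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_dropped") <- u$n_dropped
  out
}

#' Per-gene Euclidean distance between two networks
#'
#' `d(g) = sqrt(sum_j (a^A_gj - a^B_gj)^2)` over the common partners j != g:
#' how much a gene's weighted neighbourhood changes between the two networks.
#'
#' @param netA,netB `WeightedNetwork`s.
#' @return named numeric vector of distances.
#' @export
node_euclidean_distance <- function(netA, netB) {
  u <- common_universe(netA, netB)
  sqrt(rowSums((u$A - u$B)^2))
}

#' Pairwise co-expression weight differences, stratified by cycling status
#'
#' `|w_A - w_B|` for every gene pair of the common universe (raw `|cor|`
#' scale by default, i.e. the adjacency de-powered by `1/beta`; set
#' `use_power = TRUE` to compare the soft-powered weights), with medians per
#' stratum (both / one / neither member a global cycler) and rank-sum tests
#' between strata.
#'
#' @param netA,netB `WeightedNetwork`s.
#' @param cycling_calls named logical vector of global-cycling calls.
#' @param use_power compare powered weights instead of raw |cor|.
#' @return list: `summary` (per-stratum n, median), `tests` (pairwise
#'   Wilcoxon p), `delta` (vector of |dw| with stratum labels as names kept
#'   compact: a data.frame).
#' @export
pair_weight_difference <- function(netA, netB, cycling_calls,
                                   use_power = FALSE) {
  u <- common_universe(netA, netB)
  A <- u$A; B <- u$B
  if (!use_power) {
    A <- A^(1 / netA$beta)
    B <- B^(1 / netB$beta)
  }
  iu <- upper.tri(A)
  dw <- abs(A - B)[iu]
  ij <- which(iu, arr.ind = TRUE)
  cyc <- cycling_calls[u$common]
  n_cyc <- cyc[ij[, 1]] + cyc[ij[, 2]]
  stratum <- factor(c("neither", "one", "both")[n_cyc + 1],
                    levels = c("both", "one", "neither"))
  med <- tapply(dw, stratum, stats::median)
  n <- table(stratum)
  combos <- utils::combn(levels(stratum), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    p <- if (n[a] > 0 && n[b] > 0)
      suppressWarnings(stats::wilcox.test(dw[stratum == a],
                                          dw[stratum == b])$p.value)
    else NA_real_
    data.frame(stratum_a = a, stratum_b = b, p = p, stringsAsFactors = FALSE)
  }))
  list(summary = data.frame(stratum = names(med), n_pairs = as.vector(n),
                            median_delta = as.vector(med),
                            stringsAsFactors = FALSE),
       tests = tests,
       delta = data.frame(stratum = stratum, delta = dw))
}

#' Jaccard similarity between two module assignments
#'
#' `J(M_a, M_b) = |intersection| / |union|` for every module pair; consensus
#' modules are mutual best matches with J at or above the threshold.
#'
#' @param assignA,assignB `ModuleAssignment`s.
#' @param consensus_threshold minimum Jaccard for a consensus pair.
#' @return list: `jaccard` (matrix modules_A x modules_B), `consensus`
#'   (data.frame of mutual-best pairs).
#' @export
module_jaccard <- function(assignA, assignB, consensus_threshold = 0.3) {
  modsA <- sort(unique(assignA$membership[assignA$membership > 0]))
  modsB <- sort(unique(assignB$membership[assignB$membership > 0]))
  if (length(modsA) == 0 || length(modsB) == 0)
    stop("empty module assignment")
  J <- matrix(0, length(modsA), length(modsB),
              dimnames = list(paste0("A.M", modsA), paste0("B.M", modsB)))
  setsA <- lapply(modsA, function(m)
    names(assignA$membership)[assignA$membership == m])
  setsB <- lapply(modsB, function(m)
    names(assignB$membership)[assignB$membership == m])
  for (i in seq_along(modsA)) for (j in seq_along(modsB))
    J[i, j] <- length(intersect(setsA[[i]], setsB[[j]])) /
      length(union(setsA[[i]], setsB[[j]]))
  cons <- list()
  for (i in seq_along(modsA)) {
    j <- which.max(J[i, ])
    if (J[i, j] >= consensus_threshold && which.max(J[, j]) == i)
      cons[[length(cons) + 1L]] <- data.frame(
        module_A = rownames(J)[i], module_B = colnames(J)[j],
        jaccard = J[i, j], stringsAsFactors = FALSE)
  }
  list(jaccard = J,
       consensus = if (length(cons)) do.call(rbind, cons) else
         data.frame(module_A = character(0), module_B = character(0),
                    jaccard = numeric(0)))
}

#' Hub subnetwork of a module
#'
#' Ranks module members by intramodular connectivity (sum of weights to
#' same-module genes), takes the top `top_n` (ties broken lexicographically),
#' and returns the induced weighted subgraph.
#'
#' @param net a `WeightedNetwork`.
#' @param module character vector of module member genes.
#' @param top_n number of hubs to keep (clamped to the module size).
#' @return list: `hubs` (data.frame gene, intramodular_connectivity),
#'   `adjacency` (induced submatrix).
#' @export
hub_subnetwork <- function(net, module, top_n = 50) {
  module <- intersect(module, net$nodes)
  if (length(module) == 0) stop("empty module")
  sub <- net$adjacency[module, module, drop = FALSE]
  kin <- rowSums(sub)
  ord <- order(-kin, module)          # lexicographic tie-break
  keep <- module[ord][seq_len(min(top_n, length(module)))]
  list(hubs = data.frame(gene = keep,
                         intramodular_connectivity = kin[keep],
                         stringsAsFactors = FALSE, row.names = NULL),
       adjacency = net$adjacency[keep, keep, drop = FALSE])
}
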