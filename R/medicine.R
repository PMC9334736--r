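#' Build an unweighted co-expression graph at one time point
#'
#' Edge between two genes iff their Pearson correlation across organs at the
#' given ZT exceeds `r_threshold` (strict, signed by default; `use_abs`
#' thresholds |cor| instead). Zero-variance genes are dropped.
#'
#' @param atlas an `ExpressionAtlas` with >= 3 organs.
#' @param zt time point (hours).
#' @param r_threshold correlation threshold (default 0.8).
#' @param use_abs threshold |cor| instead of signed cor.
#' @return object of class `UnweightedGraph`: `graph` (igraph, all retained
#'   genes as vertices), `nodes`, `degree`, `components`, `lcc` (names of the
#'   largest-connected-component nodes).
#' @export
build_unweighted_network <- function(atlas, zt, r_threshold = 0.8,
                                     use_abs = FALSE) {
  if (length(atlas$organ_ids) < 3) stop("need >= 3 organs")
  ti <- match(zt, atlas$zt_times)
  if (is.na(ti)) stop("ZT", zt, " not in atlas")
  expr <- atlas$values[, , ti]
  v <- apply(expr, 1, stats::var)
  expr <- expr[v > 0, , drop = FALSE]
  C <- stats::cor(t(expr))
  if (use_abs) C <- abs(C)
  adj <- C > r_threshold
  diag(adj) <- FALSE
  if (!any(adj))
    stop("empty graph at ZT", zt, "; consider lowering r_threshold")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  graph_object(g)
}

#' Build an unweighted graph from an edge list (e.g. an interactome)
#' @param edges data.frame with columns from, to (or a two-column matrix).
#' @return an `UnweightedGraph`.
#' @export
graph_from_edges <- function(edges) {
  edges <- canonical_edges(as.data.frame(stats::setNames(
    as.data.frame(as.matrix(edges)[, 1:2]), c("from", "to")),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  graph_object(g)
}

graph_object <- function(g) {
  comp <- igraph::components(g)
  lcc <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
  structure(list(graph = g, nodes = igraph::V(g)$name,
                 degree = stats::setNames(igraph::degree(g),
                                          igraph::V(g)$name),
                 components = comp, lcc = lcc),
            class = "UnweightedGraph")
}

#' Shortest-path hop distances between node sets
#'
#' @param graph an `UnweightedGraph`.
#' @param sources,targets node identifiers.
#' @return matrix of hop counts (Inf = unreachable, flagged via attribute
#'   `n_unreachable`).
#' @export
shortest_distances <- function(graph, sources, targets = sources) {
  unknown <- setdiff(c(sources, targets), graph$nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  D <- igraph::distances(graph$graph, v = sources, to = targets)
  attr(D, "n_unreachable") <- sum(is.infinite(D))
  D
}

#' Distance matrix over the largest connected component
#'
#' Computed once and passed to the permutation routines so null draws are
#' matrix lookups rather than repeated BFS runs.
#'
#' @param graph an `UnweightedGraph`.
#' @return symmetric hop-count matrix over the LCC nodes.
#' @export
lcc_distance_matrix <- function(graph) {
  D <- igraph::distances(graph$graph, v = graph$lcc, to = graph$lcc)
  dimnames(D) <- list(graph$lcc, graph$lcc)
  D
}

# Randomized-tie-break ("smoothed") empirical p: exactly uniform under the
# null even when the test statistic is discrete; the conventional add-one
# estimator (reported as p_empirical) is conservative in that case. Uses the
# current RNG stream, so it is reproducible given the seed.
smoothed_p <- function(null, obs) {
  n_lt <- sum(null < obs)
  n_eq <- sum(null == obs)
  (n_lt + stats::runif(1) * (n_eq + 1)) / (length(null) + 1)
}

# d_s for a node-index set on a precomputed distance matrix.
ds_from_D <- function(D, idx) {
  sub <- D[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

#' Disease-module distance d_s
#'
#' Mean, over the mapped disease genes, of the shortest-path distance to the
#' nearest other disease gene. Computation is restricted to the graph's
#' largest connected component (the common network-medicine convention);
#' dropped genes are reported.
#'
#' @param graph an `UnweightedGraph`.
#' @param genes disease gene identifiers.
#' @param D optional precomputed [lcc_distance_matrix()].
#' @return scalar d_s with attributes `n_mapped`, `dropped`; NA (flagged)
#'   when fewer than 2 genes map.
#' @export
disease_module_distance <- function(graph, genes, D = NULL) {
  genes <- unique(genes)
  mapped <- intersect(genes, graph$lcc)
  if (length(mapped) < 2)
    return(structure(NA_real_, n_mapped = length(mapped),
                     dropped = setdiff(genes, mapped)))
  if (is.null(D)) D <- lcc_distance_matrix(graph)
  structure(ds_from_D(D, match(mapped, rownames(D))),
            n_mapped = length(mapped), dropped = setdiff(genes, mapped))
}

#' Permutation significance of a disease module
#'
#' Null d_s from uniformly random same-size node sets of the largest
#' connected component; empirical p with the add-one (permutation-inclusive)
#' estimator `p = (1 + #{null <= observed}) / (n_perm + 1)` and z from the
#' null mean/sd.
#'
#' @param graph an `UnweightedGraph`.
#' @param genes disease gene identifiers (>= 2 must map).
#' @param n_perm number of permutations (> 0).
#' @param seed integer seed.
#' @param D optional precomputed [lcc_distance_matrix()].
#' @return one-row data.frame: `n_mapped`, `d_s`, `null_mean`, `null_sd`,
#'   `z`, `p_empirical`.
#' @export
disease_module_significance <- function(graph, genes, n_perm = 10000, seed,
                                        D = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_perm < 1) stop("n_perm must be positive")
  if (is.null(D)) D <- lcc_distance_matrix(graph)
  obs <- disease_module_distance(graph, genes, D)
  if (is.na(obs)) stop("fewer than 2 disease genes map into the graph")
  k <- attr(obs, "n_mapped")
  set.seed(derive_seed(seed, "disease_module"))
  n_lcc <- nrow(D)
  null <- vapply(seq_len(n_perm), function(i)
    ds_from_D(D, sample.int(n_lcc, k)), numeric(1))
  data.frame(n_mapped = k, d_s = as.numeric(obs),
             null_mean = mean(null), null_sd = stats::sd(null),
             z = (as.numeric(obs) - mean(null)) / stats::sd(null),
             p_empirical = (1 + sum(null <= obs)) / (n_perm + 1),
             p_smoothed = smoothed_p(null, as.numeric(obs)))
}

#' Day-night difference of a disease module's distance
#'
#' Observed `delta = d_s(A) - d_s(B)` against a null of same-size random sets
#' (drawn from the intersection of the two largest components and evaluated
#' in both graphs); two-sided empirical p.
#'
#' @param graphA,graphB `UnweightedGraph`s (e.g. ZT06 and ZT18).
#' @param genes disease gene identifiers.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param DA,DB optional precomputed distance matrices.
#' @return one-row data.frame: `d_s_A`, `d_s_B`, `delta`, `p_two_sided`,
#'   `n_mapped`.
#' @export
day_night_module_difference <- function(graphA, graphB, genes, n_perm = 10000,
                                        seed, DA = NULL, DB = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(DA)) DA <- lcc_distance_matrix(graphA)
  if (is.null(DB)) DB <- lcc_distance_matrix(graphB)
  common <- sort(intersect(rownames(DA), rownames(DB)))  # order-independent
  mapped <- intersect(unique(genes), common)
  if (length(mapped) < 2) stop("fewer than 2 genes map into both graphs")
  iA <- match(mapped, rownames(DA)); iB <- match(mapped, rownames(DB))
  delta_obs <- ds_from_D(DA, iA) - ds_from_D(DB, iB)
  set.seed(derive_seed(seed, "day_night_module"))
  k <- length(mapped)
  null <- vapply(seq_len(n_perm), function(i) {
    s <- sample(common, k)
    ds_from_D(DA, match(s, rownames(DA))) -
      ds_from_D(DB, match(s, rownames(DB)))
  }, numeric(1))
  data.frame(d_s_A = ds_from_D(DA, iA), d_s_B = ds_from_D(DB, iB),
             delta = delta_obs, n_mapped = k,
             p_two_sided = (1 + sum(abs(null) >= abs(delta_obs))) /
               (n_perm + 1))
}

#' Network proximity d_AB between two gene sets
#'
#' `d_AB = (1/(||A|| + ||B||)) * (sum_{a in A} min_{b in B} d(a,b) +
#' sum_{b in B} min_{a in A} d(a,b))`, on the largest connected component;
#' shared nodes contribute zero terms. Symmetric in A and B; 0 iff the mapped
#' sets coincide.
#'
#' @param graph an `UnweightedGraph`.
#' @param A,B gene identifier vectors.
#' @param D optional precomputed [lcc_distance_matrix()].
#' @return scalar d_AB with attributes `n_mapped_A`, `n_mapped_B`.
#' @export
proximity_dAB <- function(graph, A, B, D = NULL) {
  if (is.null(D)) D <- lcc_distance_matrix(graph)
  mA <- intersect(unique(A), rownames(D))
  mB <- intersect(unique(B), rownames(D))
  if (length(mA) == 0 || length(mB) == 0)
    stop("a gene set maps to no graph node")
  sub <- D[mA, mB, drop = FALSE]
  val <- (sum(apply(sub, 1, min)) + sum(apply(sub, 2, min))) /
    (length(mA) + length(mB))
  structure(val, n_mapped_A = length(mA), n_mapped_B = length(mB))
}

# Degree bins (log2) over the LCC with a minimum occupancy, widened until
# satisfiable; returns a factor over LCC nodes.
degree_bins <- function(graph, min_occupancy = 10) {
  deg <- graph$degree[graph$lcc]
  b <- floor(log2(pmax(deg, 1)))
  repeat {
    tab <- table(b)
    small <- names(tab)[tab < min_occupancy]
    if (length(small) == 0 || length(tab) == 1) break
    s <- as.integer(small[1])
    lv <- sort(as.integer(names(tab)))
    near <- lv[lv != s][which.min(abs(lv[lv != s] - s))]
    b[b == s] <- near
  }
  stats::setNames(as.character(b), names(deg))
}

# Sample a degree- and size-matched random set for a template set.
degree_matched_sample <- function(bins, template) {
  need <- table(bins[template])
  out <- character(0)
  for (bn in names(need)) {
    pool <- names(bins)[bins == bn]
    out <- c(out, sample(pool, need[[bn]]))
  }
  out
}

#' Permutation significance of network proximity
#'
#' Null d_AB from random set pairs matched to A and B in size and degree
#' distribution (logarithmic degree bins with a minimum occupancy, widened
#' until satisfiable); `z = (d_obs - mean_null)/sd_null` and add-one
#' empirical p (one-sided, closer than expected).
#'
#' @param graph an `UnweightedGraph`.
#' @param A,B gene identifier vectors.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param D optional precomputed distance matrix.
#' @param min_occupancy minimum nodes per degree bin.
#' @return one-row data.frame: `d_AB`, `null_mean`, `null_sd`, `z`,
#'   `p_empirical`, `n_mapped_A`, `n_mapped_B`.
#' @export
proximity_significance <- function(graph, A, B, n_perm = 1000, seed,
                                   D = NULL, min_occupancy = 10) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(D)) D <- lcc_distance_matrix(graph)
  obs <- proximity_dAB(graph, A, B, D)
  mA <- intersect(unique(A), rownames(D))
  mB <- intersect(unique(B), rownames(D))
  bins <- degree_bins(graph, min_occupancy)
  set.seed(derive_seed(seed, "proximity"))
  null <- vapply(seq_len(n_perm), function(i) {
    rA <- degree_matched_sample(bins, mA)
    rB <- degree_matched_sample(bins, mB)
    as.numeric(proximity_dAB(graph, rA, rB, D))
  }, numeric(1))
  data.frame(d_AB = as.numeric(obs), null_mean = mean(null),
             null_sd = stats::sd(null),
             z = (as.numeric(obs) - mean(null)) / stats::sd(null),
             p_empirical = (1 + sum(null <= obs)) / (n_perm + 1),
             p_smoothed = smoothed_p(null, as.numeric(obs)),
             n_mapped_A = length(mA), n_mapped_B = length(mB))
}
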