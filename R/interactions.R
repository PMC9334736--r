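# unrank the k-th pair (1-based) of m items in lexicographic order
unrank_pair <- function(k, m) {
  k0 <- k - 1
  i <- floor(((2 * m - 1) - sqrt((2 * m - 1)^2 - 8 * k0)) / 2) + 1
  # guard against floating-point edge cases
  repeat {
    lo <- (i - 1) * (2 * m - i) / 2
    hi <- i * (2 * m - i - 1) / 2
    if (k0 < lo) i <- i - 1 else if (k0 >= hi) i <- i + 1 else break
  }
  j <- i + 1 + (k0 - (i - 1) * (2 * m - i) / 2)
  c(i, j)
}

#' Randomly sample gene-pair batches
#'
#' Uniform sampling of unordered pairs without replacement within a batch (no
#' duplicates, no self-pairs); batches are independent and fully reproducible
#' from the seed. When `n_pairs` equals the number of possible pairs the batch
#' is exhaustive.
#'
#' @param genes character vector of gene identifiers.
#' @param n_pairs pairs per batch.
#' @param n_repeats number of independent batches.
#' @param seed integer seed.
#' @return list of `n_repeats` two-column character matrices.
#' @export
sample_pairs <- function(genes, n_pairs = 10000, n_repeats = 100, seed) {
  if (missing(seed)) stop("seed is mandatory")
  m <- length(genes)
  if (m < 2) stop("need >= 2 genes")
  total <- choose(m, 2)
  if (n_pairs > total) stop("n_pairs exceeds the number of distinct pairs")
  set.seed(derive_seed(seed, "pairs"))
  lapply(seq_len(n_repeats), function(b) {
    ks <- sample(total, n_pairs)
    ij <- t(vapply(ks, unrank_pair, numeric(2), m = m))
    cbind(gene1 = genes[ij[, 1]], gene2 = genes[ij[, 2]])
  })
}

#' Per-time-point cross-organ correlation series for gene pairs
#'
#' For every pair and every ZT, the Spearman correlation between the two
#' genes' organ vectors at that time point (average ranks for ties). Time
#' points where either gene has zero variance across organs yield a flagged
#' missing coefficient; pairs with more than `max_missing_frac` missing time
#' points are excluded (with reason).
#'
#' @param atlas an `ExpressionAtlas` (both genes present in all organs).
#' @param pairs two-column matrix or data.frame of gene identifiers.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param max_missing_frac exclusion threshold for flagged time points.
#' @return object of class `CorrelationSeries`: `rho` (pairs x ZT matrix),
#'   `pairs`, `zt_times`, `excluded` (data.frame of dropped pairs).
#' @export
correlation_series <- function(atlas, pairs, method = c("spearman", "pearson"),
                               max_missing_frac = 0.25) {
  method <- match.arg(method)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  stopifnot(all(pairs %in% atlas$gene_ids))
  nt <- length(atlas$zt_times)
  no <- length(atlas$organ_ids)
  rho <- matrix(NA_real_, nrow(pairs), nt)
  for (ti in seq_len(nt)) {
    V <- atlas$values[, , ti]
    R <- if (method == "spearman")
      t(apply(V, 1, rank, ties.method = "average")) else V
    Rc <- R - rowMeans(R)
    ss <- sqrt(rowSums(Rc^2))
    ok <- ss > 0
    Rn <- Rc / ifelse(ok, ss, 1)
    r <- rowSums(Rn[pairs[, 1], , drop = FALSE] *
                   Rn[pairs[, 2], , drop = FALSE])
    r[!ok[pairs[, 1]] | !ok[pairs[, 2]]] <- NA_real_
    rho[, ti] <- pmin(1, pmax(-1, r))
  }
  n_miss <- rowSums(is.na(rho))
  drop <- n_miss / nt > max_missing_frac
  excluded <- data.frame(gene1 = pairs[drop, 1], gene2 = pairs[drop, 2],
                         n_missing = n_miss[drop],
                         reason = rep("zero-variance time points", sum(drop)),
                         stringsAsFactors = FALSE)
  structure(list(rho = rho[!drop, , drop = FALSE],
                 pairs = pairs[!drop, , drop = FALSE],
                 zt_times = atlas$zt_times, excluded = excluded),
            class = "CorrelationSeries")
}

#' Detect rhythmic interactions in a batch of correlation series
#'
#' Each pair's correlation series (one value per ZT) is tested for
#' rhythmicity; BH adjustment is applied within the batch and pairs with
#' adjusted p below `alpha` are called rhythmic interactions.
#'
#' @param series a `CorrelationSeries`.
#' @param alpha BH threshold.
#' @param references optional `ReferenceSet`.
#' @param multiplicity passed to [rhythm_scan()].
#' @return data.frame: pair, rhythm statistics, `p_adj`, `is_rhythmic`.
#' @export
detect_rhythmic_interactions <- function(series, alpha = 0.05,
                                         references = NULL,
                                         multiplicity = "patterns") {
  if (is.null(references)) references <- build_references(series$zt_times)
  rho <- series$rho
  nt <- ncol(rho)
  complete <- !apply(is.na(rho), 1, any)
  res <- data.frame(S = rep(NA_real_, nrow(rho)), tau = NA_real_,
                    p_raw = NA_real_, period = NA_real_, phase = NA_real_,
                    amplitude = NA_real_, regime = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(complete))
    res[complete, ] <- rhythm_scan(rho[complete, , drop = FALSE],
                                   seq_len(nt), references,
                                   multiplicity = multiplicity)
  if (any(!complete)) {   # series with flagged (but tolerated) gaps
    for (i in which(!complete)) {
      keep <- !is.na(rho[i, ])
      if (sum(keep) < 4) next
      refs_i <- build_references(series$zt_times[keep])
      res[i, ] <- rhythm_scan(matrix(rho[i, keep], 1), seq_len(sum(keep)),
                              refs_i, multiplicity = multiplicity)
    }
  }
  tested <- !is.na(res$p_raw)
  res$p_adj <- NA_real_
  res$p_adj[tested] <- adjust_bh(res$p_raw[tested])
  res$is_rhythmic <- !is.na(res$p_adj) & res$p_adj < alpha
  cbind(data.frame(gene1 = series$pairs[, 1], gene2 = series$pairs[, 2],
                   stringsAsFactors = FALSE), res)
}

#' Rhythmic-interaction proportion over repeated pair batches
#'
#' Applies the pair-sampling + correlation + rhythm pipeline to each batch and
#' reports the rhythmic proportion per batch with its across-batch mean and
#' sd (the repeated-sampling design that gives an unbiased assessment of the
#' body-wide rhythmic co-expression rate).
#'
#' @param atlas an `ExpressionAtlas`.
#' @param batches list of pair matrices from [sample_pairs()].
#' @param alpha BH threshold (within batch).
#' @param references optional `ReferenceSet`.
#' @return list: `per_batch` (proportion per batch), `mean`, `sd`,
#'   `results` (list of per-batch data.frames).
#' @export
interaction_batches <- function(atlas, batches, alpha = 0.05,
                                references = NULL) {
  if (is.null(references)) references <- build_references(atlas$zt_times)
  results <- lapply(batches, function(b) {
    cs <- correlation_series(atlas, b)
    detect_rhythmic_interactions(cs, alpha, references)
  })
  prop <- vapply(results, function(r) mean(r$is_rhythmic), numeric(1))
  list(per_batch = prop, mean = mean(prop), sd = stats::sd(prop),
       results = results)
}

#' Z-score a correlation series
#'
#' Standardizes the raw per-ZT coefficients to mean 0 and population sd 1
#' (the divide-by-n sd over the fixed set of time points); a zero-variance
#' series returns flagged zeros.
#'
#' @param rho numeric vector (or pairs x ZT matrix) of coefficients.
#' @return standardized vector/matrix; attribute `degenerate` flags
#'   zero-variance rows.
#' @export
zscore_series <- function(rho) {
  if (is.null(dim(rho))) {
    s <- pop_sd(rho)
    if (s == 0) return(structure(rho * 0, degenerate = TRUE))
    return(structure((rho - mean(rho)) / s, degenerate = FALSE))
  }
  m <- rowMeans(rho)
  s <- sqrt(rowMeans((rho - m)^2))
  degen <- s == 0
  out <- (rho - m) / ifelse(degen, 1, s)
  out[degen, ] <- 0
  structure(out, degenerate = degen)
}

#' Stratify rhythmic-interaction calls by global-cycling membership
#'
#' Splits pairs by whether both, one, or neither member is a global cycler and
#' reports the rhythmic proportion per stratum with a chi-square trend test of
#' the ordering.
#'
#' @param results data.frame from [detect_rhythmic_interactions()].
#' @param cycling_calls named logical vector of global-cycling calls.
#' @return list: `strata` (data.frame both/one/neither with counts and
#'   proportions), `trend_p`.
#' @export
stratify_by_cycling <- function(results, cycling_calls) {
  miss <- setdiff(unique(c(results$gene1, results$gene2)),
                  names(cycling_calls))
  if (length(miss))
    stop("cycling calls missing for: ", paste(utils::head(miss, 5),
                                              collapse = ", "))
  n_cyc <- cycling_calls[results$gene1] + cycling_calls[results$gene2]
  cat3 <- factor(c("neither", "one", "both")[n_cyc + 1],
                 levels = c("both", "one", "neither"))
  n <- as.vector(table(cat3))
  k <- as.vector(tapply(results$is_rhythmic, cat3, sum))
  k[is.na(k)] <- 0
  prop <- ifelse(n > 0, k / n, NA_real_)
  trend_p <- if (all(n > 0))
    tryCatch(suppressWarnings(
      stats::prop.trend.test(k, n, score = c(2, 1, 0))$p.value),
      error = function(e) NA_real_)   # degenerate (e.g. no calls at all)
  else NA_real_
  list(strata = data.frame(stratum = levels(cat3), n_pairs = n,
                           n_rhythmic = k, proportion = prop,
                           stringsAsFactors = FALSE),
       trend_p = trend_p)
}

#' Rhythmic co-expression proportion of an external edge list
#'
#' Restricts the edges to genes present in the atlas (restriction count
#' reported), de-duplicates them, and runs the rhythmic-interaction pipeline
#' with BH within the edge set.
#'
#' @param atlas an `ExpressionAtlas`.
#' @param edges data.frame with columns from/to (e.g. [read_edge_list()]).
#' @param alpha BH threshold.
#' @param references optional `ReferenceSet`.
#' @return list: `proportion`, `n_edges_used`, `n_edges_dropped`, `results`.
#' @export
edge_list_rhythmicity <- function(atlas, edges, alpha = 0.05,
                                  references = NULL) {
  edges <- canonical_edges(edges)
  keep <- edges$from %in% atlas$gene_ids & edges$to %in% atlas$gene_ids
  if (!any(keep)) stop("no edges overlap the atlas genes")
  cs <- correlation_series(atlas, cbind(edges$from[keep], edges$to[keep]))
  res <- detect_rhythmic_interactions(cs, alpha, references)
  list(proportion = mean(res$is_rhythmic), n_edges_used = sum(keep),
       n_edges_dropped = sum(!keep), results = res)
}
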