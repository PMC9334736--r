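#' Grouped circadian time series
#'
#' An observed series arranged as ordered time groups (one per ZT), each group
#' holding one or more replicate values — e.g. the 63 organ values at a given
#' time point when organs are stacked as replicates.
#'
#' @param groups list of numeric vectors, one per time point, each non-empty.
#' @param zt_times numeric ZT hours, one per group, strictly increasing.
#' @return object of class `GroupedSeries`.
#' @export
grouped_series <- function(groups, zt_times) {
  stopifnot(is.list(groups), length(groups) == length(zt_times),
            all(lengths(groups) >= 1))
  if (length(groups) < 4) stop("need >= 4 time groups")
  if (sum(lengths(groups)) < 6) stop("need >= 6 total observations")
  structure(list(groups = lapply(groups, as.numeric),
                 zt_times = as.numeric(zt_times)),
            class = "GroupedSeries")
}

#' Build cosine reference waveforms
#'
#' One reference per (period, phase lag) pair, evaluated at the group times;
#' references whose group rank pattern duplicates an earlier one are dropped
#' (the count is reported). For within-gene multiplicity handling the number
#' of distinct patterns after additionally collapsing a pattern with its
#' reversal is recorded (`m_eff`): a reference and its half-period shift give
#' identical two-sided tests, so they count once.
#'
#' @param zt_times numeric ZT sampling times (equally spaced).
#' @param periods candidate periods in hours (default: the 24 h cycle only).
#' @param phase_step phase-lag grid step in hours (default: the sampling
#'   interval).
#' @return list of references (class `ReferenceSet`), each with `period`,
#'   `phase`, `ref` (cosine value per group); attributes `n_dropped`, `m_eff`.
#' @export
build_references <- function(zt_times, periods = 24, phase_step = NULL) {
  stopifnot(length(zt_times) >= 4)
  interval <- diff(zt_times)[1]
  if (is.null(phase_step)) phase_step <- interval
  if (any(periods < 2 * interval))
    stop("period below twice the sampling interval (sub-Nyquist)")
  refs <- list()
  seen <- character(0)
  n_dropped <- 0L
  for (p in periods) {
    for (lag in seq(0, p - phase_step, by = phase_step)) {
      r <- round(cos(2 * pi * (zt_times - lag) / p), 10)
      sig <- paste(rank(r, ties.method = "min"), collapse = ",")
      if (sig %in% seen) { n_dropped <- n_dropped + 1L; next }
      seen <- c(seen, sig)
      refs[[length(refs) + 1L]] <- list(period = p, phase = lag, ref = r,
                                        signature = sig)
    }
  }
  rev_sig <- vapply(refs, function(rf)
    paste(rank(-rf$ref, ties.method = "min"), collapse = ","), character(1))
  cls <- vapply(seq_along(refs), function(i)
    min(refs[[i]]$signature, rev_sig[i]), character(1))
  structure(refs, n_dropped = n_dropped, m_eff = length(unique(cls)),
            zt_times = zt_times, class = "ReferenceSet")
}

#' Kendall concordance statistic between a series and a reference
#'
#' `S` is the concordant-minus-discordant count over all observation pairs
#' with distinct reference values; pairs tied in the data contribute 0 and
#' also reduce the attainable maximum (tau-b-like normalization); pairs tied
#' in the reference are excluded from the pair universe.
#'
#' @param series a `GroupedSeries` (any list with a `groups` field of
#'   per-time-point replicate vectors is accepted).
#' @param ref a reference from [build_references()] (or a numeric vector of
#'   reference values, one per group).
#' @return list with `S`, `tau`, `max_S`.
#' @export
kendall_statistic <- function(series, ref) {
  rv <- if (is.list(ref)) ref$ref else ref
  stopifnot(length(rv) == length(series$groups))
  x <- unlist(series$groups, use.names = FALSE)
  g <- rep(seq_along(series$groups), lengths(series$groups))
  r <- rv[g]
  sx <- sign(outer(x, x, "-"))
  sr <- sign(outer(r, r, "-"))
  S <- sum(sx * sr) / 2
  max_S <- sum(sx != 0 & sr != 0) / 2
  list(S = S, tau = if (max_S > 0) S / max_S else 0, max_S = max_S)
}

# ---- exact null distribution ------------------------------------------------

# Dense polynomial product (exact in doubles for positive counts).
polymul <- function(x, y) {
  res <- numeric(length(x) + length(y) - 1L)
  for (i in seq_along(y)) {
    idx <- i:(i + length(x) - 1L)
    res[idx] <- res[idx] + x * y[i]
  }
  res
}

# Coefficients of the Gaussian binomial [a+b choose b]_q: the null counting
# generating function of the Mann-Whitney count U between samples of sizes a
# and b (Harding's construction). Degree a*b.
gauss_binom_poly <- function(a, b) {
  prev <- rep(list(1), b + 1L)               # row a = 0: all polys are 1
  for (ai in seq_len(a)) {
    cur <- vector("list", b + 1L)
    cur[[1L]] <- 1
    for (bi in seq_len(b)) {
      p1 <- cur[[bi]]                        # F(ai, bi - 1)
      p2 <- c(numeric(bi), prev[[bi + 1L]])  # q^bi * F(ai - 1, bi)
      n <- max(length(p1), length(p2))
      cur[[bi + 1L]] <- c(p1, numeric(n - length(p1))) +
                        c(p2, numeric(n - length(p2)))
    }
    prev <- cur
  }
  prev[[b + 1L]]
}

# Exact null pmf of S for untied data: convolution over reference blocks
# (groups merged by equal reference value), Harding-style. Returns support/pmf.
harding_null <- function(block_sizes) {
  B <- length(block_sizes)
  P <- (sum(block_sizes)^2 - sum(block_sizes^2)) / 2
  poly <- 1
  cum <- block_sizes[1]
  if (B >= 2) for (b in 2:B) {
    poly <- polymul(poly, gauss_binom_poly(cum, block_sizes[b]))
    cum <- cum + block_sizes[b]
  }
  pmf <- poly / sum(poly)
  list(support = 2 * (seq_along(pmf) - 1L) - P, pmf = pmf)
}

# Enumerate compositions of `total` into length(caps) parts with part v <= caps[v].
compositions_capped <- function(total, caps) {
  if (length(caps) == 1L) {
    if (total <= caps) return(matrix(total, 1L, 1L)) else
      return(matrix(numeric(0), 0L, 1L))
  }
  out <- list()
  for (a in 0:min(total, caps[1])) {
    rest <- compositions_capped(total - a, caps[-1])
    if (nrow(rest)) out[[length(out) + 1L]] <- cbind(a, rest)
  }
  if (!length(out)) return(matrix(numeric(0), 0L, length(caps)))
  do.call(rbind, out)
}

# Exact null pmf of S for tied data: dynamic programme over reference blocks
# (ascending reference value); state = counts of each distinct data value
# already placed in lower blocks. Weights are multiset-arrangement counts.
tied_null <- function(x, block_sizes) {
  m <- as.integer(table(x))            # multiplicities, ascending value order
  d <- length(m)
  N <- sum(block_sizes)
  P <- (N^2 - sum(block_sizes^2)) / 2
  width <- as.integer(2 * P + 1)       # S in -P..P, offset P + 1
  states <- new.env(hash = TRUE, parent = emptyenv())
  key0 <- paste(integer(d), collapse = ",")
  w0 <- numeric(width); w0[P + 1] <- 1
  assign(key0, list(c = integer(d), w = w0), envir = states)
  for (b in seq_along(block_sizes)) {
    nb <- block_sizes[b]
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    for (key in ls(states)) {
      st <- get(key, envir = states)
      comps <- compositions_capped(nb, m - st$c)
      lower <- cumsum(c(0, st$c))[seq_len(d)]        # placed values < v
      higher <- sum(st$c) - lower - st$c             # placed values > v
      for (ci in seq_len(nrow(comps))) {
        a <- comps[ci, ]
        mult <- prod(choose(m - st$c, a))
        dS <- sum(a * (lower - higher))
        newc <- st$c + as.integer(a)
        w <- numeric(width)
        src <- seq_len(width)
        dst <- src + dS
        ok <- dst >= 1 & dst <= width
        w[dst[ok]] <- st$w[src[ok]] * mult
        nk <- paste(newc, collapse = ",")
        if (exists(nk, envir = nxt)) {
          prevst <- get(nk, envir = nxt)
          prevst$w <- prevst$w + w
          assign(nk, prevst, envir = nxt)
        } else assign(nk, list(c = newc, w = w), envir = nxt)
      }
    }
    states <- nxt
  }
  final <- get(paste(m, collapse = ","), envir = states)
  pmf <- final$w / sum(final$w)
  keep <- pmf > 0 | seq_len(width) == P + 1
  list(support = (seq_len(width) - (P + 1))[keep], pmf = pmf[keep])
}

#' Exact null distribution of the concordance statistic S
#'
#' Probability mass function of S under random orderings of the observed data
#' over the reference's tie blocks. Untied data use Harding-style convolution
#' of Mann-Whitney generating functions; tied data use an exact dynamic
#' programme over block assignments (feasible for small series; the run path
#' falls back to a tie-corrected normal approximation otherwise).
#'
#' @param x observed data values (their tie structure is what matters).
#' @param block_sizes sizes of the reference tie blocks (groups merged by
#'   equal reference value), in ascending reference order. For untied data
#'   the null depends only on the size multiset; with tied data the block
#'   ORDER matters (which block a tied pair can share determines the
#'   achievable extremes of S), so the order must be preserved.
#' @return list with `support`, `pmf` (symmetric about 0 for untied data;
#'   data ties at asymmetric positions skew the null); or NULL when the tied
#'   dynamic programme would be infeasible.
#' @export
exact_null <- function(x, block_sizes) {
  m <- as.integer(table(x))
  if (all(m == 1L)) return(c(harding_null(block_sizes), method = "harding"))
  if (prod(m + 1) <= 5e4 && sum(block_sizes) <= 30)
    return(c(tied_null(x, block_sizes), method = "tied_dp"))
  NULL
}

# Two-sided tail probability from an exact pmf.
pmf_two_sided_p <- function(null, S_obs) {
  min(1, sum(null$pmf[abs(null$support) >= abs(S_obs) - 1e-9]))
}

# Tie-corrected permutation variance of Kendall's S (classic formula; `u` are
# reference block sizes, `v` data tie sizes). Validated against exact pmfs in
# the test suite.
var_S_ties <- function(N, u, v) {
  t1 <- (N * (N - 1) * (2 * N + 5) - sum(u * (u - 1) * (2 * u + 5)) -
           sum(v * (v - 1) * (2 * v + 5))) / 18
  t2 <- sum(u * (u - 1) * (u - 2)) * sum(v * (v - 1) * (v - 2)) /
    (9 * N * (N - 1) * (N - 2))
  t3 <- sum(u * (u - 1)) * sum(v * (v - 1)) / (2 * N * (N - 1))
  t1 + t2 + t3
}

# Two-sided p for one (S, ref blocks, data ties) combination.
s_p_value <- function(S, x, block_sizes, exact_limit = 50) {
  N <- sum(block_sizes)
  if (N <= exact_limit) {
    null <- exact_null(x, block_sizes)
    if (!is.null(null))
      return(list(p = pmf_two_sided_p(null, S), regime = null$method))
  }
  v <- as.integer(table(x))
  V <- var_S_ties(N, block_sizes, v)
  if (V <= 0) return(list(p = 1, regime = "degenerate"))
  z <- (abs(S) - 1) / sqrt(V)        # continuity correction
  list(p = min(1, max(2 * stats::pnorm(-max(z, 0)), 1e-300)),
       regime = "normal_approx")
}

# Reference tie-block sizes given per-group replicate counts.
ref_block_sizes <- function(ref_values, group_sizes) {
  as.integer(tapply(group_sizes, factor(ref_values), sum))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement; output order matches
#' input order. Inputs must lie in (0, 1].
#'
#' @param p numeric p-values.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# ---- scanning many series against one reference set -------------------------

#' Rhythmicity scan of many series against a reference set
#'
#' The engine behind every rhythm test in the pipeline. Each row of `X` is one
#' series; `groups` maps observations (columns) to time groups. For every
#' reference the concordance statistic and its two-sided p are computed (exact
#' null when the series is small enough, tie-corrected normal approximation
#' otherwise); the best reference gives period and phase; the reported p is
#' Bonferroni-adjusted by the number of reversal-collapsed distinct rank
#' patterns (`multiplicity = "patterns"`, the default) or taken as the raw
#' minimum (`"minp"`).
#'
#' @param X numeric matrix, series x observations.
#' @param groups integer vector mapping columns of `X` to time groups
#'   (1..length(zt_times) of the reference set).
#' @param references a `ReferenceSet` from [build_references()].
#' @param exact_limit maximum total observations for the exact null.
#' @param multiplicity within-series multiple-phase handling.
#' @return data.frame with one row per series: `S`, `tau`, `p_raw`, `period`,
#'   `phase`, `amplitude`, `regime`.
#' @export
rhythm_scan <- function(X, groups, references, exact_limit = 50,
                        multiplicity = c("patterns", "minp")) {
  multiplicity <- match.arg(multiplicity)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  N <- ncol(X)
  stopifnot(length(groups) == N)
  zt <- attr(references, "zt_times")
  m_eff <- attr(references, "m_eff")
  nref <- length(references)
  group_sizes <- tabulate(groups, nbins = length(zt))

  # observation-level sign matrices per reference, flattened
  SrMat <- matrix(0, N * N, nref)
  blocks <- vector("list", nref)
  for (k in seq_len(nref)) {
    r <- references[[k]]$ref[groups]
    SrMat[, k] <- as.vector(sign(outer(r, r, "-")))
    # ascending-reference order; with tied data the exact null depends on the
    # block ORDER, not just the size multiset, so it must not be sorted
    blocks[[k]] <- ref_block_sizes(references[[k]]$ref, group_sizes)
  }
  AbsSr <- abs(SrMat)

  # cache exact nulls / variance terms by block signature
  null_cache <- new.env(hash = TRUE, parent = emptyenv())
  u_terms <- lapply(blocks, function(u)
    list(u = u, a = sum(u * (u - 1) * (2 * u + 5)),
         b = sum(u * (u - 1) * (u - 2)), c = sum(u * (u - 1))))

  n_series <- nrow(X)
  out <- data.frame(S = numeric(n_series), tau = numeric(n_series),
                    p_raw = numeric(n_series), period = numeric(n_series),
                    phase = numeric(n_series), amplitude = numeric(n_series),
                    regime = character(n_series), stringsAsFactors = FALSE)
  periods <- vapply(references, `[[`, numeric(1), "period")
  phases <- vapply(references, `[[`, numeric(1), "phase")

  for (i in seq_len(n_series)) {
    x <- X[i, ]
    sx <- as.vector(sign(outer(x, x, "-")))
    Svec <- as.vector(crossprod(sx, SrMat)) / 2
    maxSvec <- as.vector(crossprod(abs(sx), AbsSr)) / 2
    v <- as.integer(table(x))
    untied <- all(v == 1L)
    pvec <- numeric(nref)
    regvec <- character(nref)
    for (k in seq_len(nref)) {
      if (maxSvec[k] == 0) { pvec[k] <- 1; regvec[k] <- "degenerate"; next }
      u <- blocks[[k]]
      if (N <= exact_limit && untied) {
        key <- paste(sort(u), collapse = ",")   # order-invariant when untied
        null <- if (exists(key, envir = null_cache))
          get(key, envir = null_cache) else {
            nl <- harding_null(u); assign(key, nl, envir = null_cache); nl
          }
        pvec[k] <- pmf_two_sided_p(null, Svec[k])
        regvec[k] <- "harding"
      } else if (N <= exact_limit) {
        key <- paste(paste(u, collapse = ","), paste(sort(v), collapse = "."),
                     sep = "|")
        null <- if (exists(key, envir = null_cache))
          get(key, envir = null_cache) else {
            nl <- exact_null(x, u)
            assign(key, if (is.null(nl)) list(NULL) else nl, envir = null_cache)
            nl
          }
        if (is.null(null) || is.null(null$support)) {
          res <- normal_p(Svec[k], N, u_terms[[k]], v)
          pvec[k] <- res$p; regvec[k] <- res$regime
        } else {
          pvec[k] <- pmf_two_sided_p(null, Svec[k])
          regvec[k] <- null$method
        }
      } else {
        res <- normal_p(Svec[k], N, u_terms[[k]], v)
        pvec[k] <- res$p; regvec[k] <- res$regime
      }
    }
    # best reference: min p, then max S, then smallest phase lag
    best <- order(pvec, -Svec, phases)[1]
    p_raw <- if (multiplicity == "patterns") min(1, pvec[best] * m_eff)
             else pvec[best]
    if (maxSvec[best] == 0) {           # constant series
      out[i, ] <- list(0, 0, 1, periods[best], NA_real_, 0, "degenerate")
      next
    }
    gm <- as.vector(rowsum(x, groups)) / group_sizes
    cg <- cos(2 * pi * (zt - phases[best]) / periods[best])
    b_amp <- if (stats::var(cg) > 0)
      sum((gm - mean(gm)) * (cg - mean(cg))) / sum((cg - mean(cg))^2) else 0
    out[i, ] <- list(Svec[best], Svec[best] / maxSvec[best], p_raw,
                     periods[best], phases[best], abs(b_amp), regvec[best])
  }
  out
}

normal_p <- function(S, N, ut, v) {
  t1 <- (N * (N - 1) * (2 * N + 5) - ut$a - sum(v * (v - 1) * (2 * v + 5))) / 18
  t2 <- ut$b * sum(v * (v - 1) * (v - 2)) / (9 * N * (N - 1) * (N - 2))
  t3 <- ut$c * sum(v * (v - 1)) / (2 * N * (N - 1))
  V <- t1 + t2 + t3
  if (V <= 0) return(list(p = 1, regime = "degenerate"))
  z <- (abs(S) - 1) / sqrt(V)
  # floor keeps extreme signals representable and BH-adjustable
  list(p = min(1, max(2 * stats::pnorm(-max(z, 0)), 1e-300)),
       regime = "normal_approx")
}

#' Rhythm test of one grouped series
#'
#' Runs the full reference scan on a single series and reports the best
#' (period, phase) with the concordance statistic, two-sided p, and the
#' least-squares cosine amplitude (half peak-to-trough) fitted on group means.
#'
#' @param series a `GroupedSeries`.
#' @param references a `ReferenceSet`; defaults to the standard grid on the
#'   series' own time points.
#' @inheritParams rhythm_scan
#' @return one-row data.frame as in [rhythm_scan()].
#' @export
run_rhythm_test <- function(series, references = NULL, exact_limit = 50,
                            multiplicity = c("patterns", "minp")) {
  if (is.null(references)) references <- build_references(series$zt_times)
  x <- unlist(series$groups, use.names = FALSE)
  g <- rep(seq_along(series$groups), lengths(series$groups))
  rhythm_scan(matrix(x, nrow = 1), g, references, exact_limit,
              match.arg(multiplicity))
}
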