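test_that("reference waveforms evaluate the cosine grid with expected ties", {
  zt <- c(0, 6, 12, 18)
  refs <- build_references(zt)
  r0 <- refs[[1]]
  expect_equal(r0$phase, 0)
  expect_equal(r0$ref, c(1, 0, -1, 0))          # tie between ZT06 and ZT18
  zt12 <- seq(0, 22, 2)
  refs12 <- build_references(zt12)
  expect_length(refs12, 12)                      # one lag per sampling interval
  expect_equal(attr(refs12, "m_eff"), 6)         # reversal pairs collapse
  expect_error(build_references(zt12, periods = 3), "Nyquist")
})

test_that("duplicate rank patterns are deduplicated", {
  # 4 ZT, phase step 1 h: 24 lags collapse onto few distinct rank patterns
  refs <- build_references(c(0, 6, 12, 18), phase_step = 1)
  sigs <- vapply(refs, function(r) r$signature, character(1))
  expect_false(any(duplicated(sigs)))
  expect_gt(attr(refs, "n_dropped"), 0)
})

test_that("kendall statistic matches hand values and a brute-force oracle", {
  gs <- list(groups = as.list(1:4))     # one replicate per group
  ref <- list(ref = c(1, 2, 3, 4))
  ks <- kendall_statistic(gs, ref)
  expect_equal(ks$S, 6)                # C(4,2) concordant pairs
  expect_equal(ks$tau, 1)
  ks_rev <- kendall_statistic(list(groups = as.list(4:1)), ref)
  expect_equal(ks_rev$S, -6)
  expect_equal(ks_rev$tau, -1)
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(8)
    r <- sample(8)
    gs <- grouped_series(as.list(x), seq(0, 21, 3))
    ks <- kendall_statistic(gs, list(ref = r))
    expect_equal(ks$S, brute_S(x, r))
  }
})

test_that("exact null pmf equals full-permutation enumeration (<= 8 obs)", {
  configs <- list(
    list(x = 1:4, blocks = c(1, 1, 1, 1)),
    list(x = 1:6, blocks = c(2, 2, 2)),
    list(x = 1:6, blocks = c(1, 2, 3)),
    list(x = 1:7, blocks = c(1, 2, 2, 2)),
    list(x = 1:8, blocks = c(2, 2, 2, 2)),
    list(x = 1:8, blocks = c(4, 4)),
    list(x = c(1, 1, 2, 3, 4, 5), blocks = c(2, 2, 2)),      # data ties
    list(x = c(1, 1, 2, 2, 3), blocks = c(2, 1, 2)),
    list(x = c(1, 2, 2, 2, 3, 4, 4), blocks = c(3, 2, 2)),
    list(x = c(0, 0, 0, 1, 1, 2), blocks = c(1, 1, 2, 2)),
    list(x = c(1, 1, 1, 1, 2, 2, 3), blocks = c(2, 2, 3)),
    # same size multisets, different block order: tied nulls must differ
    # correctly (the cosine block structure is not monotone in size)
    list(x = c(1, 1, 2, 3, 4, 5), blocks = c(1, 2, 2, 1)),
    list(x = c(1, 1, 2, 3, 4, 5), blocks = c(2, 1, 1, 2)),
    list(x = c(1, 2, 2, 3, 4), blocks = c(1, 3, 1)))
  for (cfg in configs) {
    nl <- exact_null(cfg$x, cfg$blocks)
    or <- enum_null(cfg$x, cfg$blocks)
    th <- tapply(nl$pmf, nl$support, sum)
    th <- th[th > 1e-15]
    expect_setequal(as.numeric(names(th)), or$support)
    expect_equal(as.numeric(th[as.character(or$support)]), or$pmf,
                 tolerance = 1e-12)
    # two-sided p agreement at every achievable S
    for (S in or$support)
      expect_equal(chronet:::pmf_two_sided_p(nl, S),
                   enum_two_sided_p(or, S), tolerance = 1e-12)
    # total mass; symmetry about 0 (untied data only: tie position skews
    # the null, which the enumeration oracle confirms)
    expect_equal(chronet:::pmf_two_sided_p(nl, 0), 1)
    expect_equal(sum(nl$pmf), 1, tolerance = 1e-12)
    if (!any(duplicated(cfg$x))) {
      sup <- nl$support[nl$pmf > 1e-15]
      pm <- nl$pmf[nl$pmf > 1e-15]
      expect_equal(pm[order(sup)], rev(pm[order(sup)]), tolerance = 1e-12)
    }
  }
})

test_that("tie-corrected variance formula matches the exact pmf variance", {
  configs <- list(list(x = 1:8, blocks = c(2, 2, 2, 2)),
                  list(x = c(1, 1, 2, 3, 4, 5), blocks = c(2, 2, 2)),
                  list(x = c(1, 2, 2, 3, 3, 3), blocks = c(3, 3)))
  for (cfg in configs) {
    nl <- exact_null(cfg$x, cfg$blocks)
    v_pmf <- sum(nl$pmf * nl$support^2)
    v_f <- chronet:::var_S_ties(length(cfg$x), cfg$blocks,
                                as.integer(table(cfg$x)))
    expect_equal(v_pmf, v_f, tolerance = 1e-9)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 0)), "0, 1")
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("rhythm test recovers noiseless phases exactly and handles degenerates", {
  zt <- seq(0, 22, 2)
  refs <- build_references(zt)
  for (ph in c(0, 4, 10, 16, 22)) {
    x <- rep(cos(2 * pi * (zt - ph) / 24), each = 5)
    r <- rhythm_scan(matrix(x, 1), rep(1:12, each = 5), refs)
    expect_equal(r$phase, ph)
    expect_lt(r$p_raw, 1e-4)
    expect_equal(r$amplitude, 1, tolerance = 1e-9)
  }
  const <- run_rhythm_test(grouped_series(as.list(rep(3, 12)), zt))
  expect_equal(const$p_raw, 1)
  expect_equal(const$tau, 0)
  expect_equal(const$amplitude, 0)
})

test_that("circular time reversal maps phase to (period - phase) mod period", {
  zt <- seq(0, 22, 2)
  refs <- build_references(zt)
  set.seed(3)
  for (i in 1:4) {
    x <- cos(2 * pi * (zt - sample(zt, 1)) / 24) + rnorm(12, 0, 0.05)
    fwd <- rhythm_scan(matrix(x, 1), 1:12, refs)
    rev_x <- x[c(1, 12:2)]             # x(-t) on the circular grid
    bwd <- rhythm_scan(matrix(rev_x, 1), 1:12, refs)
    expect_equal(bwd$phase, (24 - fwd$phase) %% 24)
  }
})

test_that("p-values are invariant under strictly monotone transforms", {
  zt <- seq(0, 22, 2)
  refs <- build_references(zt)
  set.seed(7)
  x <- cos(2 * pi * (zt - 8) / 24) + rnorm(12, 0, 0.4)
  r1 <- rhythm_scan(matrix(x, 1), 1:12, refs)
  r2 <- rhythm_scan(matrix(exp(2 * x), 1), 1:12, refs)
  expect_equal(r1$p_raw, r2$p_raw)
  expect_equal(r1$S, r2$S)
  expect_equal(r1$phase, r2$phase)
})

test_that("pure-noise p-values are not anti-conservative", {
  zt <- seq(0, 22, 2)
  refs <- build_references(zt)
  set.seed(11)
  X <- matrix(rnorm(800 * 36), 800)      # 12 ZT x 3 replicates
  res <- rhythm_scan(X, rep(1:12, each = 3), refs)
  # one-sided check: ECDF of p must not exceed uniform beyond binomial noise
  for (q in c(0.01, 0.05, 0.1, 0.25)) {
    slack <- 3 * sqrt(q * (1 - q) / 800)
    expect_lte(mean(res$p_raw <= q), q + slack)
  }
})
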