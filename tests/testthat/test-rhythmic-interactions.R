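test_that("pair sampling is exhaustive, duplicate-free and reproducible", {
  b <- sample_pairs(letters[1:5], n_pairs = 10, n_repeats = 1, seed = 1)[[1]]
  expect_equal(nrow(b), 10)
  key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  expect_equal(sort(key), sort(apply(combn(letters[1:5], 2), 2, paste,
                                     collapse = " ")))
  b2 <- sample_pairs(letters[1:10], 20, 3, seed = 5)
  b3 <- sample_pairs(letters[1:10], 20, 3, seed = 5)
  expect_identical(b2, b3)
  expect_false(identical(b2[[1]], b2[[2]]))       # batches independent
  for (bb in b2) {
    expect_false(any(bb[, 1] == bb[, 2]))
    expect_false(any(duplicated(paste(pmin(bb[, 1], bb[, 2]),
                                      pmax(bb[, 1], bb[, 2])))))
  }
  expect_error(sample_pairs(letters[1:4], 7, 1, seed = 1), "exceeds")
})

test_that("pair sampling frequencies are approximately uniform", {
  batches <- sample_pairs(letters[1:6], 5, 400, seed = 2)
  key <- unlist(lapply(batches, function(b)
    paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))))
  counts <- table(key)
  expect_length(counts, 15)
  cs <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(cs$p.value, 1e-4)
})

test_that("correlation series reproduces monotone and hand-ranked cases", {
  atlas <- toy_atlas(n_genes = 2, n_organs = 6, zt = c(0, 6, 12, 18))
  # B = 2A: perfect monotone relation at every ZT
  v <- atlas$values
  v[2, , ] <- 2 * v[1, , ]
  a2 <- expression_atlas(v, c("a", "b"), atlas$organ_ids, atlas$zt_times)
  cs <- correlation_series(a2, cbind("a", "b"))
  expect_equal(as.vector(cs$rho), rep(1, 4))
  # B = max - A: reversal
  v[2, , ] <- max(v[1, , ]) + 1 - v[1, , ]
  a3 <- expression_atlas(v, c("a", "b"), atlas$organ_ids, atlas$zt_times)
  expect_equal(as.vector(correlation_series(a3, cbind("a", "b"))$rho),
               rep(-1, 4))
  # 4-organ toy: hand-ranked Spearman
  vals <- array(0, dim = c(2, 4, 4))
  vals[1, , ] <- c(1, 2, 3, 4)
  vals[2, , 1] <- c(10, 30, 20, 40)     # ranks 1,3,2,4 vs 1,2,3,4
  vals[2, , 2:4] <- c(5, 6, 7, 8)
  a4 <- expression_atlas(vals, c("x", "y"), paste0("o", 1:4), c(0, 6, 12, 18))
  cs4 <- correlation_series(a4, cbind("x", "y"))
  expect_equal(cs4$rho[1, 1], 0.8)      # 1 - 6*2/(4*15)
  expect_equal(cs4$rho[1, 2], 1)
})

test_that("correlation series is invariant to monotone per-gene transforms", {
  atlas <- toy_atlas(n_genes = 6, n_organs = 8, zt = seq(0, 18, 6))
  pairs <- cbind(c("g1", "g3"), c("g2", "g5"))
  cs1 <- correlation_series(atlas, pairs)
  ae <- expression_atlas(exp(atlas$values / 3), atlas$gene_ids,
                         atlas$organ_ids, atlas$zt_times)
  cs2 <- correlation_series(ae, pairs)
  expect_equal(cs1$rho, cs2$rho)
})

test_that("z-scoring matches the population-sd formula", {
  z <- zscore_series(c(0.2, 0.4, 0.6))
  expect_equal(as.vector(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  zc <- zscore_series(rep(0.5, 6))
  expect_equal(as.vector(zc), rep(0, 6))
  expect_true(attr(zc, "degenerate"))
  set.seed(1)
  M <- matrix(rnorm(40), 4)
  zm <- zscore_series(M)
  expect_equal(rowMeans(zm), rep(0, 4), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(zm^2)), rep(1, 4), tolerance = 1e-12)
})

test_that("flat correlation series are never called rhythmic", {
  zt <- seq(0, 22, 2)
  rho <- matrix(rep(0.4, 12), 1)
  series <- structure(list(rho = rho, pairs = cbind("a", "b"),
                           zt_times = zt,
                           excluded = data.frame()),
                      class = "CorrelationSeries")
  res <- detect_rhythmic_interactions(series)
  expect_equal(res$p_raw, 1)
  expect_false(res$is_rhythmic)
})

test_that("strata partition all pairs and cover degenerate cases", {
  res <- data.frame(gene1 = c("a", "a", "c"), gene2 = c("b", "c", "d"),
                    is_rhythmic = c(TRUE, FALSE, TRUE))
  calls <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  st <- stratify_by_cycling(res, calls)
  expect_equal(sum(st$strata$n_pairs), 3)
  expect_equal(st$strata$n_pairs,
               c(1L, 1L, 1L))   # both(a,b), one(a,c), neither(c,d)
  expect_error(stratify_by_cycling(res, calls[1:2]), "missing")
})

test_that("edge-list rhythmicity restricts to atlas genes and de-duplicates", {
  cfg <- sim_config(seed = 31, n_genes = 60, n_organs = 20,
                    n_coupled_pairs = 8, fraction_global_cyclers = 0.3)
  sim <- simulate_atlas(cfg)
  atlas <- sim$atlas
  planted <- sim$truth$pairs
  edges <- data.frame(from = c(planted$gene1, "zzz", planted$gene1[1]),
                      to = c(planted$gene2, "zzz2", planted$gene2[1]))
  r <- edge_list_rhythmicity(atlas, edges)
  expect_equal(r$n_edges_used, 8)            # duplicate collapsed
  expect_equal(r$n_edges_dropped, 1)
  expect_gt(r$proportion, 0.5)               # planted coupling is detectable
  only_out <- data.frame(from = "q1", to = "q2")
  expect_error(edge_list_rhythmicity(atlas, only_out), "no edges")
})

test_that("pipeline is invariant to organ relabeling", {
  cfg <- sim_config(seed = 17, n_genes = 30, n_organs = 10,
                    n_coupled_pairs = 4)
  atlas <- simulate_atlas(cfg)$atlas
  pairs <- cbind(c("g0001", "g0003"), c("g0002", "g0004"))
  r1 <- detect_rhythmic_interactions(correlation_series(atlas, pairs))
  shuffled <- subset_atlas(atlas, organs = rev(atlas$organ_ids))
  r2 <- detect_rhythmic_interactions(correlation_series(shuffled, pairs))
  expect_equal(r1$p_raw, r2$p_raw)
  expect_equal(r1$phase, r2$phase)
})
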