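test_that("soft-threshold adjacency follows |cor|^beta", {
  set.seed(2)
  base <- rnorm(10)
  expr <- rbind(g1 = base, g2 = 2 * base + 3, g3 = rnorm(10))
  net <- build_network(expr, beta = 16)
  expect_equal(net$adjacency["g1", "g2"], 1)              # |1|^beta
  r13 <- abs(cor(expr["g1", ], expr["g3", ]))
  expect_equal(net$adjacency["g1", "g3"], r13^16)
  expect_equal(net$adjacency, t(net$adjacency))
  expect_equal(diag(net$adjacency), rep(0, 3), ignore_attr = TRUE)
  expect_equal(0.5^16, 1.52587890625e-05)                 # the scale at work
  expect_error(build_network(expr, beta = 0.5), "beta")
  expr0 <- rbind(expr, g4 = rep(1, 10))
  net0 <- build_network(expr0, 16)
  expect_identical(net0$dropped, "g4")
})

test_that("the six network concepts match closed forms and brute force", {
  # complete unit-weight graph
  A <- matrix(1, 5, 5); diag(A) <- 0
  fc <- fundamental_concepts(A)
  expect_equal(fc$node$connectivity, rep(4, 5))
  expect_equal(fc$node$cluster_coef, rep(1, 5))
  expect_equal(fc$node$mar, rep(1, 5))
  expect_equal(fc$network$density, 1)
  expect_equal(fc$network$centralization, 0)
  expect_equal(fc$network$heterogeneity, 0)
  # star graph
  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- 1
  fs <- fundamental_concepts(S)
  expect_equal(fs$node$connectivity, c(4, 1, 1, 1, 1))
  expect_equal(fs$network$density, 0.4)
  expect_equal(fs$network$centralization, 5 / 3 * (1 - 0.4))
  # random weighted graphs vs brute force
  set.seed(5)
  for (i in 1:5) {
    A <- random_adjacency(50)
    fc <- fundamental_concepts(A)
    b <- brute_concepts(A)
    expect_equal(fc$node$connectivity, b$k, tolerance = 1e-10)
    expect_equal(fc$node$cluster_coef, b$cc, tolerance = 1e-10)
    expect_equal(fc$node$mar, b$mar, tolerance = 1e-10)
    expect_equal(fc$network$density, b$density, tolerance = 1e-10)
    expect_equal(fc$network$centralization, b$centralization,
                 tolerance = 1e-10)
    expect_equal(fc$network$heterogeneity, b$heterogeneity,
                 tolerance = 1e-10)
    # MAR lower bound with equality iff incident weights equal
    expect_true(all(fc$node$mar >= fc$node$connectivity / 49 - 1e-12))
  }
})

test_that("module detection recovers planted blocks and rejects noise", {
  set.seed(8)
  n_per <- 40; n_noise <- 40; n_samp <- 60
  shared1 <- rnorm(n_samp); shared2 <- rnorm(n_samp)
  mk <- function(shared, n) t(vapply(seq_len(n), function(i)
    3 * shared + rnorm(n_samp), numeric(n_samp)))
  expr <- rbind(mk(shared1, n_per), mk(shared2, n_per),
                matrix(rnorm(n_noise * n_samp), n_noise))
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  net <- build_network(expr, 16)
  asg <- detect_modules(net, expr, min_module_size = 30)
  truth <- rep(c(1, 2, 0), c(n_per, n_per, n_noise))
  expect_equal(length(asg$sizes), 2)
  for (m in 1:2) {
    found <- asg$membership[truth == m]
    expect_gte(max(table(found[found > 0])) / n_per, 0.95)
  }
  # pure noise: nearly everything unassigned
  noise <- matrix(rnorm(100 * n_samp), 100)
  rownames(noise) <- sprintf("n%03d", 1:100)
  nn <- build_network(noise, 16)
  an <- suppressWarnings(detect_modules(nn, noise, min_module_size = 30))
  expect_gte(mean(an$membership == 0), 0.95)
})

test_that("module detection is invariant to gene input order", {
  set.seed(12)
  shared <- rnorm(40)
  expr <- rbind(t(sapply(1:35, function(i) 3 * shared + rnorm(40))),
                matrix(rnorm(15 * 40), 15))
  rownames(expr) <- sprintf("g%03d", 1:50)
  net1 <- build_network(expr, 16)
  a1 <- detect_modules(net1, expr, min_module_size = 20)
  perm <- sample(nrow(expr))
  net2 <- build_network(expr[perm, ], 16)
  a2 <- detect_modules(net2, expr[perm, ], min_module_size = 20)
  m2 <- a2$membership[names(a1$membership)]
  # same partition up to label renaming
  expect_equal(a1$membership == 0, m2 == 0)
  tab <- table(a1$membership[a1$membership > 0], m2[a1$membership > 0])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("eigengene of identical genes is their standardized profile", {
  prof <- c(1, 4, 2, 8, 5, 7, 3, 6)
  expr <- matrix(rep(prof, each = 35), 35, byrow = FALSE)
  rownames(expr) <- sprintf("g%03d", 1:35)
  colnames(expr) <- paste0("s", 1:8)
  net <- build_network(expr + 1e-9 * matrix(rnorm(280), 35), beta = 2)
  asg <- detect_modules(net, expr, min_module_size = 10)
  expect_equal(length(asg$sizes), 1)
  e <- asg$eigengenes[1, ]
  zs <- (prof - mean(prof)) / sd(prof)
  expect_gt(cor(e, zs), 0.9999)
})

test_that("module enrichment flags perfect containment and sums cells", {
  membership <- stats::setNames(rep(c(1L, 2L, 0L), each = 20),
                                sprintf("g%03d", 1:60))
  asg <- structure(list(membership = membership), class = "ModuleAssignment")
  set1 <- names(membership)[membership == 1]
  r <- module_set_enrichment(asg, set1)
  expect_lt(r$p[r$module == "M1"], 1e-6)
  expect_gt(r$odds_ratio[r$module == "M1"], 1)
  # the other module is significantly depleted of the set
  expect_lt(r$odds_ratio[r$module == "M2"], 1)
  expect_lt(r$p[r$module == "M2"], 0.05)
  expect_equal(unique(r$n_background), 60)
})

test_that("module rhythmicity separates planted rhythmic from flat modules", {
  cfg <- sim_config(seed = 3, n_genes = 200, n_organs = 20,
                    fraction_global_cyclers = 0.1,
                    fraction_organ_cyclers = 0,
                    modules = list(sizes = c(40, 40),
                                   rhythmic = c(TRUE, FALSE),
                                   phases = c(6, 0)))
  sim <- simulate_atlas(cfg)
  atlas <- filter_expressed(sim$atlas)
  flat <- flatten_atlas(atlas)
  net <- build_network(flat, 16)
  asg <- detect_modules(net, flat)
  mr <- module_rhythmicity(asg, attr(flat, "samples"))
  truth_mod <- sim$truth$genes$module[match(names(asg$membership),
                                            sim$truth$genes$gene)]
  # map detected modules to planted ones by majority membership
  for (mi in seq_along(asg$sizes)) {
    members <- names(asg$membership)[asg$membership == mi]
    planted <- as.integer(names(which.max(table(
      truth_mod[match(members, names(asg$membership))]))))
    row <- mr[mr$module == paste0("M", mi), ]
    if (planted == 1) {
      expect_true(row$rhythmic)
      expect_lte(chronet:::circ_dist(row$phase_eigen, 6, 24), 2)
    } else if (planted == 2) {
      expect_false(row$rhythmic)
    }
  }
})

test_that("per-ZT networks are independent and the day/night split needs 2+ ZTs", {
  atlas <- toy_atlas(n_genes = 12, n_organs = 8, zt = c(0, 6, 12, 18))
  n1 <- network_at_zt(atlas, 6)
  sub <- subset_atlas(atlas, genes = atlas$gene_ids)   # identity copy
  n2 <- network_at_zt(sub, 6)
  expect_equal(n1$adjacency, n2$adjacency)
  topo <- day_night_topology(atlas, beta = 4)
  expect_equal(nrow(topo$per_zt), 4)
  expect_s3_class(topo$tests, "data.frame")
  a2 <- expression_atlas(atlas$values[, , c(1, 3), drop = FALSE],
                         atlas$gene_ids, atlas$organ_ids, c(0, 12))
  expect_warning(day_night_topology(a2, beta = 4), "skipped")
})
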