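path_graph <- function(n) {
  graph_from_edges(data.frame(from = letters[1:(n - 1)], to = letters[2:n]))
}

test_that("thresholded graphs and shortest distances behave on toy cases", {
  zt <- c(0, 6, 12, 18)
  set.seed(1)
  vals <- array(runif(4 * 6 * 4, 1, 5), dim = c(4, 6, 4))
  vals[2, , 1] <- vals[1, , 1]                 # identical at ZT0 -> cor 1
  atlas <- expression_atlas(vals, paste0("g", 1:4), paste0("o", 1:6), zt)
  g <- build_unweighted_network(atlas, 0, r_threshold = 0.8)
  expect_true(igraph::are_adjacent(g$graph, "g1", "g2"))
  pg <- path_graph(3)
  D <- shortest_distances(pg, c("a", "c"))
  expect_equal(D["a", "c"], 2)
  expect_equal(D["a", "a"], 0)
  expect_error(shortest_distances(pg, "zz"), "unknown node")
})

test_that("BFS distances equal a matrix-power reachability oracle", {
  si <- simulate_interactome(60, model = "er", er_p = 0.06, seed = 5)
  g <- graph_from_edges(si$edges)
  D <- shortest_distances(g, g$nodes)
  Adj <- matrix(0, length(g$nodes), length(g$nodes),
                dimnames = list(g$nodes, g$nodes))
  Adj[as.matrix(si$edges)] <- 1
  Adj[as.matrix(si$edges)[, 2:1]] <- 1
  # first matrix power with a nonzero entry = hop distance
  reach <- Adj
  Dref <- matrix(Inf, nrow(Adj), ncol(Adj), dimnames = dimnames(Adj))
  diag(Dref) <- 0
  Dref[Adj > 0] <- 1
  pow <- Adj
  for (h in 2:10) {
    pow <- pow %*% Adj
    newly <- pow > 0 & is.infinite(Dref)
    Dref[newly] <- h
  }
  expect_equal(D[rownames(Dref), colnames(Dref)], Dref)
})

test_that("d_s matches hand computations and a brute-force oracle", {
  pg5 <- path_graph(5)
  expect_equal(as.numeric(disease_module_distance(pg5, c("a", "b"))), 1)
  expect_equal(as.numeric(disease_module_distance(pg5, c("a", "e"))), 4)
  nm <- disease_module_distance(pg5, c("a", "zz"))
  expect_true(is.na(nm))
  expect_equal(attr(nm, "n_mapped"), 1)
  si <- simulate_interactome(150, model = "er", er_p = 0.04, seed = 8)
  g <- graph_from_edges(si$edges)
  D <- lcc_distance_matrix(g)
  set.seed(2)
  for (i in 1:5) {
    s <- sample(g$lcc, 8)
    expect_equal(as.numeric(disease_module_distance(g, s, D)),
                 brute_ds(D, s))
  }
})

test_that("proximity d_AB matches Eq.-1 hand computations and brute force", {
  pg3 <- path_graph(3)
  D3 <- lcc_distance_matrix(pg3)
  expect_equal(as.numeric(proximity_dAB(pg3, "a", "c", D3)), 2)
  expect_equal(as.numeric(proximity_dAB(pg3, c("a", "b"), c("a", "b"), D3)), 0)
  si <- simulate_interactome(200, seed = 10)
  g <- graph_from_edges(si$edges)
  D <- lcc_distance_matrix(g)
  set.seed(3)
  for (i in 1:10) {
    A <- sample(g$lcc, sample(3:10, 1))
    B <- sample(g$lcc, sample(3:10, 1))
    dab <- as.numeric(proximity_dAB(g, A, B, D))
    expect_equal(dab, brute_dAB(D, A, B))
    expect_equal(dab, as.numeric(proximity_dAB(g, B, A, D)))  # symmetry
  }
})

test_that("adding an edge never increases d_s or d_AB (monotonicity)", {
  si <- simulate_interactome(80, model = "er", er_p = 0.05, seed = 21)
  g <- graph_from_edges(si$edges)
  D <- lcc_distance_matrix(g)
  set.seed(4)
  s <- sample(g$lcc, 8)
  A <- sample(g$lcc, 6); B <- sample(g$lcc, 6)
  nonedges <- t(combn(sample(g$lcc, 12), 2))
  present <- paste(si$edges$from, si$edges$to)
  for (i in seq_len(nrow(nonedges))) {
    e <- sort(nonedges[i, ])
    if (paste(e[1], e[2]) %in% present) next
    g2 <- graph_from_edges(rbind(si$edges,
                                 data.frame(from = e[1], to = e[2])))
    D2 <- lcc_distance_matrix(g2)
    expect_lte(brute_ds(D2, s), brute_ds(D, s) + 1e-12)
    expect_lte(brute_dAB(D2, A, B), brute_dAB(D, A, B) + 1e-12)
  }
})

test_that("permutation tests validate preconditions and reproduce from seed", {
  si <- simulate_interactome(150, seed = 17, planted_module_sizes = 10)
  g <- graph_from_edges(si$edges)
  D <- lcc_distance_matrix(g)
  expect_error(disease_module_significance(g, si$truth$modules[[1]],
                                           n_perm = 0, seed = 1), "positive")
  r1 <- disease_module_significance(g, si$truth$modules[[1]], 200, seed = 9,
                                    D = D)
  r2 <- disease_module_significance(g, si$truth$modules[[1]], 200, seed = 9,
                                    D = D)
  expect_identical(r1, r2)
  expect_gte(r1$p_empirical, 1 / 201)
  set.seed(6)
  A <- sample(g$lcc, 6); B <- sample(g$lcc, 6)
  pr1 <- proximity_significance(g, A, B, n_perm = 50, seed = 2, D = D)
  pr2 <- proximity_significance(g, A, B, n_perm = 50, seed = 2, D = D)
  expect_identical(pr1, pr2)
})

test_that("degree-matched null sets preserve size and degree bins", {
  si <- simulate_interactome(400, seed = 30)
  g <- graph_from_edges(si$edges)
  bins <- chronet:::degree_bins(g, min_occupancy = 10)
  expect_true(all(table(bins) >= 10))
  set.seed(5)
  template <- sample(g$lcc, 15)
  for (i in 1:10) {
    s <- chronet:::degree_matched_sample(bins, template)
    expect_length(s, 15)
    expect_equal(table(bins[s]), table(bins[template]))
  }
})

test_that("day/night module difference is antisymmetric and null on identical graphs", {
  si <- simulate_interactome(120, model = "er", er_p = 0.05, seed = 19,
                             planted_module_sizes = 8)
  g <- graph_from_edges(si$edges)
  D <- lcc_distance_matrix(g)
  mod <- si$truth$modules[[1]]
  same <- day_night_module_difference(g, g, mod, n_perm = 100, seed = 3,
                                      DA = D, DB = D)
  expect_equal(same$delta, 0)
  expect_equal(same$p_two_sided, 1)
  si2 <- simulate_interactome(120, model = "er", er_p = 0.05, seed = 23)
  g2 <- graph_from_edges(si2$edges)
  D2 <- lcc_distance_matrix(g2)
  common_mod <- intersect(intersect(mod, g2$lcc), g$lcc)
  if (length(common_mod) >= 2) {
    ab <- day_night_module_difference(g, g2, common_mod, 100, seed = 4,
                                      DA = D, DB = D2)
    ba <- day_night_module_difference(g2, g, common_mod, 100, seed = 4,
                                      DA = D2, DB = D)
    expect_equal(ab$delta, -ba$delta)
    expect_equal(ab$p_two_sided, ba$p_two_sided)
  }
})
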