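test_that("atlas round-trips through the wide-TSV format value-identically", {
  atlas <- toy_atlas()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_identical(back$gene_ids, atlas$gene_ids)
  expect_identical(back$organ_ids, atlas$organ_ids)
  expect_equal(back$zt_times, atlas$zt_times)
  expect_equal(back$values, atlas$values)
})

test_that("toy 2x2x2 file parses to the expected atlas", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tliver_ZT00\tliver_ZT12\tlung_ZT00\tlung_ZT12",
               "gA\t1\t2\t3\t4", "gB\t5\t6\t7\t8"), path)
  atlas <- read_atlas(path)
  expect_equal(dim(atlas$values), c(2, 2, 2))
  expect_equal(atlas$zt_times, c(0, 12))
  expect_equal(atlas$values["gA", "liver", "ZT12"], 2)
  expect_equal(atlas$values["gB", "lung", "ZT0"], 7)
})

test_that("reader rejects malformed input with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tliver_ZT00", "gA\t1"), path)
  expect_error(read_atlas(path), "missing gene column")
  writeLines(c("gene\tliver_ZT00\tweird", "gA\t1\t2"), path)
  expect_error(read_atlas(path), "unparseable")
  writeLines(c("gene\tliver_ZT00\tliver_ZT12", "gA\t1\t-3"), path)
  expect_error(read_atlas(path), "negative expression.*gA.*liver",
               ignore.case = TRUE)
  writeLines(c("gene\tliver_ZT00\tliver_ZT12", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_atlas(path), "duplicate gene")
})

test_that("expression filter applies the per-organ half-of-timepoints rule", {
  zt <- seq(0, 22, 2)
  vals <- array(1, dim = c(3, 3, 12))
  vals[1, , 7:12] <- 0      # >0 at exactly 6 of 12 ZT in every organ: retained
  vals[2, 1, ] <- 0         # all-zero in one organ
  vals[3, , 1:7] <- 0       # >0 at only 5 of 12: fails everywhere
  atlas <- expression_atlas(vals, paste0("g", 1:3), paste0("o", 1:3), zt)
  f_all <- filter_expressed(atlas, "all")
  expect_identical(f_all$gene_ids, "g1")
  f_any <- filter_expressed(atlas, "any")
  expect_setequal(f_any$gene_ids, c("g1", "g2"))
  audit <- attr(f_all, "audit")
  expect_equal(audit$n_organs_expressed, c(3L, 2L, 0L))
  # idempotent, never increases gene count
  expect_identical(filter_expressed(f_all, "all")$gene_ids, f_all$gene_ids)
  vals0 <- array(0, dim = c(2, 2, 12))
  a0 <- expression_atlas(vals0, c("a", "b"), c("x", "y"), zt)
  expect_error(filter_expressed(a0), "no genes pass")
})

test_that("per-organ standardization is exact, idempotent, rank-preserving", {
  zt <- c(0, 6, 12, 18)
  vals <- array(0, dim = c(2, 1, 4))
  vals[1, 1, ] <- c(1, 2, 3, 2)
  vals[2, 1, ] <- c(5, 5, 5, 5)
  atlas <- expression_atlas(vals, c("a", "b"), "o1", zt)
  st <- standardize_per_organ(atlas)
  expect_equal(mean(st$values[1, 1, ]), 0)
  expect_equal(sqrt(mean(st$values[1, 1, ]^2)), 1)
  expect_equal(st$values[2, 1, ], rep(0, 4), ignore_attr = TRUE)
  expect_true(st$degenerate[2, 1])
  # closed-form z-scores for (1,2,3)
  v3 <- array(rep(1:3, each = 1), dim = c(1, 1, 3))
  a3 <- expression_atlas(v3, "g", "o", c(0, 8, 16))
  expect_equal(as.vector(standardize_per_organ(a3)$values),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # idempotence
  st2 <- standardize_per_organ(st)
  expect_equal(st2$values, st$values)
  # Spearman correlations within organ unchanged
  big <- toy_atlas(n_genes = 5)
  sb <- standardize_per_organ(big)
  for (o in 1:2) {
    c1 <- cor(t(big$values[, o, ]), method = "spearman")
    c2 <- cor(t(sb$values[, o, ]), method = "spearman")
    expect_equal(c1, c2)
  }
})

test_that("day/night assignment uses the half-open [0,12) day window", {
  expect_identical(assign_day_night(6), "day")
  expect_identical(assign_day_night(18), "night")
  expect_identical(assign_day_night(12), "night")
  expect_identical(assign_day_night(0), "day")
  expect_error(assign_day_night(24), "out of")
  expect_identical(assign_day_night(20, day_start = 20, day_end = 23), "day")
})

test_that("gene-set and edge-list readers de-duplicate and validate", {
  gs <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "TP53", "BMAL1", "TP53", ""), gs)
  sets <- read_gene_sets(gs)
  expect_length(sets, 1)
  expect_setequal(sets[[1]], c("TP53", "BMAL1"))
  multi <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("set_label\tgene", "d1\ta", "d1\tb", "d1\ta", "d2\tc"), multi)
  ms <- read_gene_sets(multi)
  expect_setequal(names(ms), c("d1", "d2"))
  expect_setequal(ms$d1, c("a", "b"))
  el <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta", "c\tc", "a\tc"), el)
  ed <- read_edge_list(el)
  expect_equal(nrow(ed), 2)            # duplicate collapsed, self-loop dropped
  expect_true(all(ed$from <= ed$to))
})

test_that("atlas constructor enforces its invariants", {
  vals <- array(1, dim = c(2, 2, 4))
  expect_error(expression_atlas(vals, c("a", "a"), c("x", "y"),
                                c(0, 6, 12, 18)), "duplicate gene")
  expect_error(expression_atlas(vals, c("a", "b"), c("x", "y"),
                                c(0, 6, 18, 12)), "increasing")
  expect_error(expression_atlas(vals, c("a", "b"), c("x", "y"),
                                c(0, 8, 16, 24)), "\\[0, period")
  expect_error(expression_atlas(vals, c("a", "b"), c("x", "y"),
                                c(0, 4, 12, 18)), "equally spaced")
  vals[1, 1, 1] <- NA
  expect_error(expression_atlas(vals, c("a", "b"), c("x", "y"),
                                c(0, 6, 12, 18)), "missing")
})
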