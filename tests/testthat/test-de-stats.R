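test_that("depth strata split ranked cells into near-equal blocks", {
  expect_equal(depth_quartiles(1:8), c(1, 1, 2, 2, 3, 3, 4, 4))
  s9 <- depth_quartiles(c(10, 20, 30, 40, 50, 60, 70, 80, 90))
  expect_equal(as.vector(table(s9)), c(3, 2, 2, 2))
  expect_equal(s9, c(1, 1, 1, 2, 2, 3, 3, 4, 4))
  # ties broken by stable input order; rerunning is deterministic
  tied <- rep(100, 8)
  expect_equal(depth_quartiles(tied), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_identical(depth_quartiles(tied), depth_quartiles(tied))
  # stratification uses ranks, not values: any monotone transform agrees
  set.seed(2)
  d <- rpois(37, 5000)
  expect_equal(depth_quartiles(d), depth_quartiles(sqrt(d)))
  expect_error(depth_quartiles(1:3), class = "envcci_degenerate_error")
})

test_that("rank-sum Z matches the closed-form normal approximation", {
  # separated groups: W = 15, mean = 10.5, var = 5.25
  expect_equal(wilcoxon_z(c(4, 5, 6), c(1, 2, 3)), 4.5 / sqrt(5.25),
               tolerance = 1e-12)
  expect_equal(wilcoxon_z(c(4, 5, 6), c(1, 2, 3)), 1.964, tolerance = 1e-3)
  # antisymmetry and symmetry
  expect_equal(wilcoxon_z(c(1, 2, 3), c(4, 5, 6)), -wilcoxon_z(c(4, 5, 6),
                                                               c(1, 2, 3)))
  expect_equal(wilcoxon_z(c(1, 2, 3), c(1, 2, 3)), 0)
  # all-tied input carries no information
  expect_equal(wilcoxon_z(rep(2, 5), rep(2, 7)), 0)
  # agrees with the tie-corrected normal approximation of wilcox.test
  set.seed(4)
  x <- rpois(20, 2); y <- rpois(30, 3)
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE,
                                            exact = FALSE))
  z <- wilcoxon_z(x, y)
  expect_equal(2 * stats::pnorm(-abs(z)), wt$p.value, tolerance = 1e-10)
  expect_error(wilcoxon_z(numeric(0), 1:3),
               class = "envcci_degenerate_error")
})

test_that("Stouffer combination behaves as the weighted formula", {
  expect_equal(combine_z(c(2, 2, 2, 2)), 4)
  expect_equal(combine_z(c(0, 0, 0, 0)), 0)
  expect_equal(combine_z(c(1, -1, 2, 0)), 1)
  # reduces to the single contributing stratum's z
  expect_equal(combine_z(c(NA, 1.7, NA, NA), weights = c(2, 3, 1, 1)), 1.7)
  expect_true(is.na(combine_z(c(NA_real_, NA_real_))))
  # weighted form
  expect_equal(combine_z(c(1, 2), weights = c(1, 2)),
               (1 + 4) / sqrt(5))
  expect_error(combine_z(c(1, 2), weights = c(1, -1)),
               class = "envcci_degenerate_error")
})

test_that("stratified DE recovers a planted marker at the published thresholds", {
  sim <- simulate_dataset(sim_config(
    n_clusters = 2, cells_per_cluster = c(200, 600), n_genes = 300,
    baseline_mean = 1, seed = 21,
    markers = data.frame(gene = "g0007", cluster = "C1", fold = 4)))
  annot <- align_annotation(sim$counts, sim$annot)
  de <- stratified_de(normalize_counts(sim$counts), annot, "C1")
  hit <- de[de$gene == "g0007", ]
  expect_lt(hit$q_value, 0.005)
  expect_gt(hit$log2_fc, 0.02)
  expect_gt(hit$z_combined, 0)
  expect_equal(hit$n_in, 200)
  expect_equal(hit$n_out, 600)
})

test_that("null genes show nominal type-I error and a single flat gene gets q = 1", {
  sim <- simulate_dataset(sim_config(
    n_clusters = 2, cells_per_cluster = 150, n_genes = 800,
    baseline_mean = 1.5, seed = 8))
  annot <- align_annotation(sim$counts, sim$annot)
  de <- stratified_de(normalize_counts(sim$counts), annot, "C1")
  fpr <- mean(de$p_value < 0.05)
  mc <- 3 * sqrt(0.05 * 0.95 / nrow(de))
  expect_gt(fpr, 0.05 - mc - 0.01)
  expect_lt(fpr, 0.05 + mc + 0.01)
  # BH monotonicity: q non-decreasing in p rank
  o <- order(de$p_value)
  expect_true(all(diff(de$q_value[o]) >= -1e-12))
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  # single identical-distribution gene: p ~ 1 after BH of one test
  x <- matrix(rep(c(1, 2, 3, 4), 5), ncol = 1,
              dimnames = list(sprintf("c%02d", 1:20), "flat"))
  a1 <- data.frame(cell = rownames(x), cluster = rep(c("A", "B"), 10),
                   total_counts = rep(c(1, 2, 3, 4), 5))
  de1 <- stratified_de(x, a1, "A")
  expect_equal(de1$q_value, 1, tolerance = 1e-6)
})

test_that("swapping in- and out-groups negates the combined Z", {
  sim <- simulate_dataset(sim_config(n_clusters = 2, cells_per_cluster = 60,
                                     n_genes = 50, seed = 13))
  annot <- align_annotation(sim$counts, sim$annot)
  norm <- normalize_counts(sim$counts)
  de_a <- stratified_de(norm, annot, "C1")
  de_b <- stratified_de(norm, annot, "C2")
  expect_equal(de_a$z_combined, -de_b$z_combined, tolerance = 1e-10)
  expect_equal(de_a$p_value, de_b$p_value, tolerance = 1e-10)
})

test_that("stratification absorbs a depth confound that breaks the naive test", {
  sim <- depth_confounded_null(n_genes = 1200, cells_per_cluster = 250,
                               depth_ratio = 2, seed = 31)
  annot <- align_annotation(sim$counts, sim$annot)
  norm <- normalize_counts(sim$counts)
  fpr_strat <- mean(stratified_de(norm, annot, "C1")$p_value < 0.05)
  fpr_naive <- mean(stratified_de(norm, annot, "C1",
                                  n_strata = 1)$p_value < 0.05)
  expect_gte(fpr_strat, 0.03)
  expect_lte(fpr_strat, 0.07)
  expect_lte(fpr_strat, fpr_naive)
  expect_gt(fpr_naive, 0.10)  # the confound is real on this data
})

test_that("unweighted Stouffer mode changes the combination as documented", {
  sim <- simulate_dataset(sim_config(n_clusters = 2,
                                     cells_per_cluster = c(40, 80),
                                     n_genes = 40, seed = 17))
  annot <- align_annotation(sim$counts, sim$annot)
  norm <- normalize_counts(sim$counts)
  strata <- depth_quartiles(annot$total_counts)
  de_w <- stratified_de(norm, annot, "C1", strata = strata)
  de_u <- stratified_de(norm, annot, "C1", strata = strata,
                        weighting = "unweighted")
  # recompute both combinations from per-stratum z for one gene
  g <- "g0005"
  in_mask <- annot$cluster == "C1"
  zs <- ws <- rep(NA_real_, 4)
  for (s in 1:4) {
    sel <- strata == s
    if (sum(in_mask & sel) && sum(!in_mask & sel)) {
      zs[s] <- wilcoxon_z(norm[sel & in_mask, g], norm[sel & !in_mask, g])
      if (zs[s] == 0 && length(unique(norm[sel, g])) == 1L) zs[s] <- NA
      ws[s] <- sqrt(sum(sel))
    }
  }
  expect_equal(de_w$z_combined[de_w$gene == g],
               combine_z(zs, ws), tolerance = 1e-10)
  expect_equal(de_u$z_combined[de_u$gene == g],
               combine_z(zs), tolerance = 1e-10)
})
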