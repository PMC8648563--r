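test_that("interaction scores are min-then-mean compositions", {
  db <- toy_db()
  mean_expr <- matrix(0, nrow = 2, ncol = 6,
                      dimnames = list(c("K1", "K2"),
                                      c("WNT7A", "FZD5", "LRP6", "JAG1",
                                        "NOTCH1", "DLL1")))
  s <- structure(list(mean_expr = mean_expr, frac_expr = mean_expr * 0 + 1,
                      n_cells = c(K1 = 10L, K2 = 10L)),
                 class = "cluster_summary")
  # both partners zero
  expect_equal(interaction_score(s, db, "I_NOTCH", "K1", "K2"), 0)
  # simple arithmetic mean
  s$mean_expr["K1", "JAG1"] <- 4; s$mean_expr["K2", "NOTCH1"] <- 2
  expect_equal(interaction_score(s, db, "I_NOTCH", "K1", "K2"), 3)
  # complex partner through the min rule: min(5, 1) then mean with 3
  s$mean_expr["K1", "WNT7A"] <- 3
  s$mean_expr["K2", "FZD5"] <- 5; s$mean_expr["K2", "LRP6"] <- 1
  expect_equal(interaction_score(s, db, "I_WNT", "K1", "K2"), 2)
})

test_that("a constant expression matrix gives p = 1 everywhere", {
  genes <- toy_db()$genes
  counts <- matrix(3, nrow = 24, ncol = length(genes),
                   dimnames = list(sprintf("c%02d", 1:24), genes))
  annot <- data.frame(cell = rownames(counts),
                      cluster = rep(c("K1", "K2"), 12),
                      total_counts = rowSums(counts))
  envs <- load_microenvironments(data.frame(cell_type = c("K1", "K2"),
                                            microenvironment = "env"))
  pairs <- eligible_pairs(envs, clusters = c("K1", "K2"))
  pv <- permutation_pvalues(normalize_counts(counts), annot, toy_db(), pairs,
                            cfg = permutation_config(n_permutations = 50,
                                                     seed = 1))
  expect_true(all(pv$p_value == 1))
})

test_that("p-values respect the add-one bounds and a fixed seed reproduces them", {
  fx <- random_fixture(120)
  annot <- align_annotation(fx$counts, fx$annot)
  norm <- normalize_counts(fx$counts)
  pairs <- suppressWarnings(eligible_pairs(fx$envs,
                                           clusters = unique(annot$cluster)))
  cfg <- permutation_config(n_permutations = 99, seed = 7)
  pv1 <- suppressWarnings(permutation_pvalues(norm, annot, fx$db, pairs, cfg))
  pv2 <- suppressWarnings(permutation_pvalues(norm, annot, fx$db, pairs, cfg))
  expect_identical(pv1, pv2)
  expect_true(all(pv1$p_value >= 1 / 100 & pv1$p_value <= 1))
  # a different seed moves at least something
  pv3 <- suppressWarnings(permutation_pvalues(
    norm, annot, fx$db, pairs, permutation_config(n_permutations = 99,
                                                  seed = 8)))
  expect_false(identical(pv1$p_value, pv3$p_value))
})

test_that("a strongly planted pair reaches the estimator floor", {
  sim <- simulate_dataset(sim_config(
    n_clusters = 2, cells_per_cluster = 100, n_genes = 120, seed = 5,
    interactions = data.frame(ligand = "g0001", receptor = "g0002",
                              source = "C1", target = "C2", fold = 8)))
  annot <- align_annotation(sim$counts, sim$annot)
  norm <- normalize_counts(sim$counts)
  envs <- load_microenvironments(data.frame(cell_type = c("C1", "C2"),
                                            microenvironment = "env"))
  pairs <- eligible_pairs(envs, clusters = c("C1", "C2"))
  pv <- permutation_pvalues(norm, annot, sim$db, pairs,
                            cfg = permutation_config(n_permutations = 200,
                                                     seed = 3))
  hit <- pv[pv$interaction_id == "planted_01" & pv$cluster_a == "C1" &
            pv$cluster_b == "C2", ]
  expect_equal(hit$p_value, 1 / 201)
})

test_that("restriction to microenvironments never scores a cross-environment pair", {
  fx <- random_fixture(130)
  annot <- align_annotation(fx$counts, fx$annot)
  norm <- normalize_counts(fx$counts)
  pairs <- suppressWarnings(eligible_pairs(fx$envs,
                                           clusters = unique(annot$cluster)))
  pv <- suppressWarnings(permutation_pvalues(
    norm, annot, fx$db, pairs,
    permutation_config(n_permutations = 20, seed = 2)))
  key_pv <- unique(paste(pv$cluster_a, pv$cluster_b, pv$microenvironment))
  key_el <- paste(pairs$cluster_a, pairs$cluster_b, pairs$microenvironment)
  expect_true(all(key_pv %in% key_el))
  # single-cluster data is degenerate
  one <- annot; one$cluster <- "K1"
  expect_error(permutation_pvalues(norm, one, fx$db, pairs,
                                   permutation_config(n_permutations = 5)),
               class = "envcci_degenerate_error")
})

test_that("expression masking blanks low-fraction records when requested", {
  fx <- random_fixture(140)
  annot <- align_annotation(fx$counts, fx$annot)
  norm <- normalize_counts(fx$counts)
  s <- summarize_clusters(norm, fx$counts, annot)
  pairs <- suppressWarnings(eligible_pairs(fx$envs,
                                           clusters = unique(annot$cluster)))
  cfg <- permutation_config(n_permutations = 20, seed = 4, min_frac = 0.5)
  pv <- suppressWarnings(permutation_pvalues(norm, annot, fx$db, pairs, cfg,
                                             counts = fx$counts))
  masked <- is.na(pv$p_value)
  # cross-check a few records against partner_summary
  idx <- utils::head(seq_len(nrow(pv)), 25)
  for (i in idx) {
    rec <- get_interaction(fx$db, pv$interaction_id[i])
    fa <- partner_summary(s, fx$db, rec$partner_a, pv$cluster_a[i])["frac_expr"]
    fb <- partner_summary(s, fx$db, rec$partner_b, pv$cluster_b[i])["frac_expr"]
    expect_equal(unname(masked[i]), unname(fa < 0.5 || fb < 0.5))
  }
})
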