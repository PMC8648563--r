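# Independent brute-force implementation of the two relevance criteria,
# written as plain double loops over pairs x interactions x orientations.
# It shares only the inputs of the checked path (raw counts, annotation,
# database tables, DE table, pair table) and recomputes cluster fractions
# and means from scratch.

oracle_members <- function(db, id) {
  if (id %in% names(db$complexes)) db$complexes[[id]] else id
}

oracle_call_interactions <- function(counts, annot, db, de, pairs, th,
                                     scale = 1e4) {
  norm <- sweep(counts, 1, rowSums(counts), "/") * scale
  clusters <- sort(unique(annot$cluster))
  cells_of <- split(annot$cell, annot$cluster)
  frac_of <- function(cluster, gene) {
    cc <- cells_of[[cluster]]
    mean(counts[cc, gene] > 0)
  }
  mean_of <- function(cluster, gene) {
    cc <- cells_of[[cluster]]
    mean(norm[cc, gene])
  }
  de_is_hit <- function(cluster, gene) {
    rows <- de$cluster == cluster & de$gene == gene
    any(de$q_value[rows] < th$max_fdr & de$log2_fc[rows] > th$min_log2_fc)
  }
  out <- list()
  r <- 0L
  for (i in seq_len(nrow(db$interactions))) {
    ma <- oracle_members(db, db$interactions$partner_a[i])
    mb <- oracle_members(db, db$interactions$partner_b[i])
    if (!all(c(ma, mb) %in% colnames(counts))) next  # skipped interaction
    for (p in seq_len(nrow(pairs))) {
      ca <- pairs$cluster_a[p]; cb <- pairs$cluster_b[p]
      de_flag <- FALSE
      for (g in unique(c(ma, mb))) {
        for (cc in unique(c(ca, cb))) {
          if (de_is_hit(cc, g)) de_flag <- TRUE
        }
      }
      for (orient in c("a|b", "b|a")) {
        ga <- if (orient == "a|b") ma else mb
        gb <- if (orient == "a|b") mb else ma
        fr_a <- min(vapply(ga, function(g) frac_of(ca, g), numeric(1)))
        fr_b <- min(vapply(gb, function(g) frac_of(cb, g), numeric(1)))
        mn_a <- min(vapply(ga, function(g) mean_of(ca, g), numeric(1)))
        mn_b <- min(vapply(gb, function(g) mean_of(cb, g), numeric(1)))
        expressed <- fr_a >= th$min_frac && fr_b >= th$min_frac
        r <- r + 1L
        out[[r]] <- data.frame(
          interaction_id = db$interactions$interaction_id[i],
          cluster_a = ca, cluster_b = cb,
          microenvironment = pairs$microenvironment[p],
          orientation = orient,
          frac_a = fr_a, frac_b = fr_b, mean_a = mn_a, mean_b = mn_b,
          relevant = expressed && de_flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(interaction_id = character(), cluster_a = character(),
                      cluster_b = character(), microenvironment = character(),
                      orientation = character(), frac_a = numeric(),
                      frac_b = numeric(), mean_a = numeric(),
                      mean_b = numeric(), relevant = logical()))
  }
  res[order(res$microenvironment, res$cluster_a, res$cluster_b,
            res$interaction_id, res$orientation, method = "radix"), ,
      drop = FALSE]
}

# Run the package path and the oracle on one fixture and compare.
expect_oracle_equivalence <- function(fx, th = relevance_thresholds()) {
  annot <- align_annotation(fx$counts, fx$annot)
  norm <- normalize_counts(fx$counts)
  s <- summarize_clusters(norm, fx$counts, annot)
  pairs <- suppressWarnings(eligible_pairs(fx$envs,
                                           clusters = rownames(s$mean_expr)))
  de <- de_all_clusters(norm, annot,
                        clusters = unique(c(pairs$cluster_a, pairs$cluster_b)))
  got <- suppressWarnings(call_interactions(s, fx$db, de, pairs,
                                            thresholds = th))
  want <- oracle_call_interactions(fx$counts, annot, fx$db, de, pairs, th)
  expect_equal(nrow(got), nrow(want))
  cols <- c("interaction_id", "cluster_a", "cluster_b", "microenvironment",
            "orientation")
  got_df <- as.data.frame(got)[, c(cols, "frac_a", "frac_b", "mean_a",
                                   "mean_b", "relevant")]
  rownames(got_df) <- rownames(want) <- NULL
  expect_equal(got_df, want, tolerance = 1e-10)
  invisible(got)
}
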