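# Optional cluster-label permutation null for interaction scores, restricted
# to microenvironment-eligible cluster pairs. The score of an interaction on
# an ordered pair is the mean of the two partner-level mean expressions
# (complex partners via the min rule); its p-value is the add-one
# Monte-Carlo estimate against scores recomputed under uniform reshuffling
# of the cluster labels.

#' Permutation test configuration
#'
#' @param n_permutations number of label permutations (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param restrict_to_envs when TRUE (default) only microenvironment-eligible
#'   pairs are scored; when FALSE all ordered cluster pairs are used.
#' @param min_frac optional fraction-expressing mask: records where either
#'   partner falls below it get `p_value = NA`. `NULL` disables masking.
#' @return A named list of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000L, seed = NULL,
                               restrict_to_envs = TRUE, min_frac = NULL) {
  if (n_permutations < 1L) {
    abort("n_permutations must be >= 1", "envcci_config_error")
  }
  structure(list(n_permutations = as.integer(n_permutations), seed = seed,
                 restrict_to_envs = restrict_to_envs, min_frac = min_frac),
            class = "permutation_config")
}

#' Interaction score on one cluster pair
#'
#' `(partner_a mean in cluster_a + partner_b mean in cluster_b) / 2`, with
#' complex partner means taken as the minimum over subunits.
#'
#' @param summary a `cluster_summary`.
#' @param db an `lr_database`.
#' @param interaction_id interaction to score.
#' @param cluster_a,cluster_b ordered cluster pair.
#' @return Numeric score.
#' @export
interaction_score <- function(summary, db, interaction_id,
                              cluster_a, cluster_b) {
  rec <- get_interaction(db, interaction_id)
  ma <- partner_summary(summary, db, rec$partner_a, cluster_a)["mean_expr"]
  mb <- partner_summary(summary, db, rec$partner_b, cluster_b)["mean_expr"]
  unname((ma + mb) / 2)
}

# Vectorized scores for all (interaction, pair) records given a clusters x
# genes mean matrix. rec: list with gene index vectors per partner.
scores_from_means <- function(M, rec) {
  pa <- rep(NA_real_, length(rec$a_idx))
  # partner mean = min over member columns at the hosting cluster's row
  pick <- function(cl_idx, members_idx) {
    v <- M[cbind(cl_idx, members_idx[[1]])]
    if (length(members_idx) > 1L) {
      for (j in 2:length(members_idx)) {
        v <- pmin(v, M[cbind(cl_idx, members_idx[[j]])])
      }
    }
    v
  }
  (pick(rec$ca_idx, rec$a_idx) + pick(rec$cb_idx, rec$b_idx)) / 2
}

#' Permutation p-values for interaction scores
#'
#' Observed scores are computed on the true cluster labels; the null
#' reshuffles the labels of all analyzed cells uniformly (cluster sizes
#' preserved) `n_permutations` times and recomputes every score. The
#' p-value is the add-one estimator `(1 + #(null >= observed)) / (n + 1)`,
#' so `p` always lies in `[1/(n+1), 1]` and a fixed seed makes the whole
#' table reproducible bit for bit.
#'
#' @param norm normalized matrix (cells x genes).
#' @param annot aligned annotation with `cluster`.
#' @param db an `lr_database`.
#' @param pairs eligible pair table (used when `restrict_to_envs`); when
#'   permutation is unrestricted all ordered cluster pairs are generated.
#' @param cfg a [permutation_config()].
#' @param counts raw counts, required only when `cfg$min_frac` masking is on.
#' @return Data frame with columns `interaction_id, cluster_a, cluster_b,
#'   microenvironment, score, p_value`.
#' @export
permutation_pvalues <- function(norm, annot, db, pairs,
                                cfg = permutation_config(), counts = NULL) {
  stopifnot(inherits(cfg, "permutation_config"))
  labels <- as.character(annot$cluster)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) {
    abort("permutation null needs at least 2 clusters",
          "envcci_degenerate_error")
  }
  if (!cfg$restrict_to_envs) {
    pairs <- expand.grid(cluster_a = clusters, cluster_b = clusters,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs$microenvironment <- "all"
  }
  if (nrow(pairs) == 0L || nrow(db$interactions) == 0L) {
    return(data.frame(interaction_id = character(), cluster_a = character(),
                      cluster_b = character(), microenvironment = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  ia <- db$interactions
  genes_present <- colnames(norm)
  member_list <- lapply(seq_len(nrow(ia)), function(i) {
    list(a = members_of(db, ia$partner_a[i]),
         b = members_of(db, ia$partner_b[i]))
  })
  ok <- vapply(member_list, function(m) all(c(m$a, m$b) %in% genes_present),
               logical(1))
  if (any(!ok)) {
    warning(sprintf("skipping %d interaction(s) with members absent from the matrix",
                    sum(!ok)))
    ia <- ia[ok, , drop = FALSE]
    member_list <- member_list[ok]
  }
  if (nrow(ia) == 0L) {
    return(data.frame(interaction_id = character(), cluster_a = character(),
                      cluster_b = character(), microenvironment = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  genes_used <- unique(unlist(lapply(member_list, function(m) c(m$a, m$b))))
  x <- norm[, genes_used, drop = FALSE]
  n_by_cluster <- as.vector(table(labels)[clusters])

  grid <- expand.grid(pair = seq_len(nrow(pairs)), ia = seq_len(nrow(ia)),
                      KEEP.OUT.ATTRS = FALSE)
  gidx <- function(g) match(g, genes_used)
  max_sub <- max(vapply(member_list, function(m) max(length(m$a), length(m$b)),
                        integer(1)))
  # member index matrices padded by repeating the first member (harmless
  # under min)
  pad <- function(side) {
    lapply(seq_len(max_sub), function(j) {
      vapply(member_list, function(m) {
        g <- m[[side]]
        gidx(if (length(g) >= j) g[j] else g[1])
      }, integer(1))[grid$ia]
    })
  }
  rec <- list(ca_idx = match(pairs$cluster_a[grid$pair], clusters),
              cb_idx = match(pairs$cluster_b[grid$pair], clusters),
              a_idx = pad("a"), b_idx = pad("b"))

  cluster_means <- function(lab) {
    rowsum(x, lab)[clusters, , drop = FALSE] / n_by_cluster
  }
  obs <- scores_from_means(cluster_means(labels), rec)

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ge <- integer(length(obs))
  for (b in seq_len(cfg$n_permutations)) {
    Mb <- cluster_means(sample(labels))
    ge <- ge + (scores_from_means(Mb, rec) >= obs)
  }
  p <- (1 + ge) / (cfg$n_permutations + 1)

  if (!is.null(cfg$min_frac)) {
    if (is.null(counts)) {
      abort("min_frac masking requires the raw counts", "envcci_config_error")
    }
    frac <- rowsum((counts[, genes_used, drop = FALSE] > 0) + 0,
                   labels)[clusters, , drop = FALSE] / n_by_cluster
    fr <- scores_from_means(frac, rec)  # reuse: min rule per partner
    # scores_from_means averages the two partner fractions; recompute the
    # two sides separately for masking
    fa <- scores_from_means(frac, list(ca_idx = rec$ca_idx, cb_idx = rec$ca_idx,
                                       a_idx = rec$a_idx, b_idx = rec$a_idx))
    fb <- scores_from_means(frac, list(ca_idx = rec$cb_idx, cb_idx = rec$cb_idx,
                                       a_idx = rec$b_idx, b_idx = rec$b_idx))
    p[fa < cfg$min_frac | fb < cfg$min_frac] <- NA_real_
  }

  data.frame(interaction_id = ia$interaction_id[grid$ia],
             cluster_a = pairs$cluster_a[grid$pair],
             cluster_b = pairs$cluster_b[grid$pair],
             microenvironment = pairs$microenvironment[grid$pair],
             score = obs,
             p_value = p,
             stringsAsFactors = FALSE)
}
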