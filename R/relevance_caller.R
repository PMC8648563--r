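# Relevance calling: an interaction is relevant for an eligible cluster pair
# when (1) every member of each partner is expressed in at least min_frac of
# the cells of the cluster hosting that partner, and (2) at least one member
# gene (ligand or receptor side) is differentially expressed, with positive
# fold change above min_log2_fc and FDR below max_fdr, in at least one of
# the two clusters of the pair.

#' Relevance thresholds
#'
#' Defaults follow the main analysis: a member is "expressed" in a cluster
#' when at least 10% of its cells have a nonzero raw count (inclusive
#' threshold), and the DE criterion requires log2 fold change > 0.02 with
#' FDR < 0.005. The `"strict_fdr"` preset is the published binary-table
#' variant: any positive log fold change with FDR < 0.001.
#'
#' @param min_frac minimum fraction of cells expressing, in `[0, 1]`.
#' @param min_log2_fc DE members must exceed this log2 fold change.
#' @param max_fdr DE members must fall below this BH-adjusted q-value.
#' @param preset `"main"` (default) or `"strict_fdr"`; explicit arguments
#'   override the preset.
#' @return A named list of class `relevance_thresholds`.
#' @export
relevance_thresholds <- function(min_frac = NULL, min_log2_fc = NULL,
                                 max_fdr = NULL,
                                 preset = c("main", "strict_fdr")) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 main = list(min_frac = 0.10, min_log2_fc = 0.02,
                             max_fdr = 0.005),
                 strict_fdr = list(min_frac = 0.10, min_log2_fc = 0,
                                   max_fdr = 0.001))
  th <- list(min_frac = min_frac %||% base$min_frac,
             min_log2_fc = min_log2_fc %||% base$min_log2_fc,
             max_fdr = max_fdr %||% base$max_fdr)
  if (th$min_frac < 0 || th$min_frac > 1) {
    abort("min_frac must lie in [0, 1]", "envcci_config_error")
  }
  if (th$max_fdr <= 0 || th$max_fdr >= 1) {
    abort("max_fdr must lie in (0, 1)", "envcci_config_error")
  }
  structure(th, class = "relevance_thresholds")
}

#' Is a partner expressed in a cluster?
#'
#' TRUE iff every member gene of the partner has `frac_expr >= min_frac` in
#' the cluster — equivalently, under the min rule, iff the partner-level
#' fraction is at least `min_frac`. The threshold is inclusive ("at least").
#'
#' @param summary a `cluster_summary`.
#' @param db an `lr_database`.
#' @param partner gene or complex id.
#' @param cluster cluster label.
#' @param min_frac inclusive expression threshold.
#' @return Logical scalar.
#' @export
is_expressed <- function(summary, db, partner, cluster, min_frac = 0.10) {
  ps <- partner_summary(summary, db, partner, cluster)
  unname(ps["frac_expr"] >= min_frac)
}

# Per-partner min-rule stats for all clusters at once: clusters x partners.
partner_stat_matrix <- function(stat_matrix, db, partners) {
  out <- matrix(NA_real_, nrow = nrow(stat_matrix), ncol = length(partners),
                dimnames = list(rownames(stat_matrix), partners))
  for (p in partners) {
    members <- members_of(db, p)
    sub <- stat_matrix[, members, drop = FALSE]
    out[, p] <- do.call(pmin, c(asplit(sub, 2), list(na.rm = FALSE)))
  }
  out
}

#' Call relevant interactions over eligible cluster pairs
#'
#' Evaluates the two relevance criteria for every interaction, eligible
#' ordered cluster pair, and orientation. Orientation `"a|b"` places
#' `partner_a` in `cluster_a` and `partner_b` in `cluster_b`; `"b|a"` is the
#' reverse. Interactions with member genes absent from the expression matrix
#' are skipped with a warning and listed in the `"skipped"` attribute.
#'
#' @param summary a `cluster_summary` covering all clusters in `pairs`.
#' @param db an `lr_database`.
#' @param de DE table from [de_all_clusters()] covering all clusters in
#'   `pairs`.
#' @param pairs eligible pair table from [eligible_pairs()].
#' @param thresholds a [relevance_thresholds()] object.
#' @return Data frame (class `relevance_table`) with one row per
#'   (interaction, pair, orientation): partner ids and expression stats as
#'   placed on `cluster_a` / `cluster_b`, the DE members supporting the call
#'   (`"gene:cluster"` entries, `;`-separated), and the `relevant` flag.
#' @export
call_interactions <- function(summary, db, de, pairs,
                              thresholds = relevance_thresholds()) {
  stopifnot(inherits(thresholds, "relevance_thresholds"))
  empty <- data.frame(interaction_id = character(), cluster_a = character(),
                      cluster_b = character(), microenvironment = character(),
                      orientation = character(), partner_to_a = character(),
                      partner_to_b = character(), frac_a = numeric(),
                      frac_b = numeric(), mean_a = numeric(),
                      mean_b = numeric(), de_members = character(),
                      relevant = logical(), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L || nrow(db$interactions) == 0L) {
    return(structure(empty, class = c("relevance_table", "data.frame"),
                     skipped = character()))
  }
  clusters_needed <- unique(c(pairs$cluster_a, pairs$cluster_b))
  missing_cl <- setdiff(clusters_needed, rownames(summary$frac_expr))
  if (length(missing_cl)) {
    abort(sprintf("cluster(s) in pair table not summarized: %s",
                  paste(missing_cl, collapse = ", ")),
          "envcci_lookup_error")
  }
  missing_de <- setdiff(clusters_needed, unique(de$cluster))
  if (length(missing_de)) {
    abort(sprintf("cluster(s) in pair table missing from DE table: %s",
                  paste(missing_de, collapse = ", ")),
          "envcci_lookup_error")
  }

  ia <- db$interactions
  genes_present <- colnames(summary$frac_expr)
  member_list <- lapply(seq_len(nrow(ia)), function(i) {
    list(a = members_of(db, ia$partner_a[i]),
         b = members_of(db, ia$partner_b[i]))
  })
  ok <- vapply(member_list, function(m) {
    all(c(m$a, m$b) %in% genes_present)
  }, logical(1))
  skipped <- ia$interaction_id[!ok]
  if (length(skipped)) {
    warning(sprintf("skipping %d interaction(s) with member genes absent from the matrix: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  ia <- ia[ok, , drop = FALSE]
  member_list <- member_list[ok]
  if (nrow(ia) == 0L) {
    return(structure(empty, class = c("relevance_table", "data.frame"),
                     skipped = skipped))
  }

  partners <- unique(c(ia$partner_a, ia$partner_b))
  pf <- partner_stat_matrix(summary$frac_expr, db, partners)
  pm <- partner_stat_matrix(summary$mean_expr, db, partners)

  # DE membership lookup: clusters x genes logical matrix of "is a DE gene
  # at these thresholds", built once from the DE table.
  de_cl <- unique(de$cluster)
  de_ok <- matrix(FALSE, nrow = length(de_cl), ncol = length(genes_present),
                  dimnames = list(de_cl, genes_present))
  hit <- de$q_value < thresholds$max_fdr & de$log2_fc > thresholds$min_log2_fc
  hit[is.na(hit)] <- FALSE
  in_frame <- de$gene %in% genes_present
  de_ok[cbind(de$cluster[hit & in_frame], de$gene[hit & in_frame])] <- TRUE

  # Any DE member (ligand or receptor side) per (cluster, interaction).
  union_members <- lapply(member_list, function(m) unique(c(m$a, m$b)))
  de_any <- vapply(union_members, function(g) {
    rowSums(de_ok[clusters_needed, g, drop = FALSE]) > 0
  }, logical(length(clusters_needed)))
  if (length(clusters_needed) == 1L) {
    de_any <- matrix(de_any, nrow = 1L,
                     dimnames = list(clusters_needed, NULL))
  }

  n_pair <- nrow(pairs)
  n_ia <- nrow(ia)
  grid <- expand.grid(pair = seq_len(n_pair), ia = seq_len(n_ia),
                      orient = c("a|b", "b|a"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ca <- pairs$cluster_a[grid$pair]
  cb <- pairs$cluster_b[grid$pair]
  env <- pairs$microenvironment[grid$pair]
  fwd <- grid$orient == "a|b"
  p_to_a <- ifelse(fwd, ia$partner_a[grid$ia], ia$partner_b[grid$ia])
  p_to_b <- ifelse(fwd, ia$partner_b[grid$ia], ia$partner_a[grid$ia])
  frac_a <- pf[cbind(ca, p_to_a)]
  frac_b <- pf[cbind(cb, p_to_b)]
  mean_a <- pm[cbind(ca, p_to_a)]
  mean_b <- pm[cbind(cb, p_to_b)]
  expressed <- frac_a >= thresholds$min_frac & frac_b >= thresholds$min_frac
  cidx_a <- match(ca, clusters_needed)
  cidx_b <- match(cb, clusters_needed)
  has_de <- de_any[cbind(cidx_a, grid$ia)] | de_any[cbind(cidx_b, grid$ia)]
  relevant <- expressed & has_de

  de_members <- character(nrow(grid))
  need <- which(has_de)
  for (k in need) {
    g <- union_members[[grid$ia[k]]]
    cls <- unique(c(ca[k], cb[k]))
    hits <- which(de_ok[cls, g, drop = FALSE], arr.ind = TRUE)
    de_members[k] <- paste(sprintf("%s:%s", g[hits[, 2]], cls[hits[, 1]]),
                           collapse = ";")
  }

  out <- data.frame(interaction_id = ia$interaction_id[grid$ia],
                    cluster_a = ca, cluster_b = cb,
                    microenvironment = env,
                    orientation = grid$orient,
                    partner_to_a = p_to_a, partner_to_b = p_to_b,
                    frac_a = frac_a, frac_b = frac_b,
                    mean_a = mean_a, mean_b = mean_b,
                    de_members = de_members,
                    relevant = relevant,
                    stringsAsFactors = FALSE)
  ord <- order(out$microenvironment, out$cluster_a, out$cluster_b,
               out$interaction_id, out$orientation, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("relevance_table", "data.frame"), skipped = skipped)
}

#' @method [ relevance_table
#' @export
`[.relevance_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @method print relevance_table
#' @export
print.relevance_table <- function(x, ...) {
  cat(sprintf("relevance_table: %d records, %d relevant (%d interactions, %d pairs)\n",
              nrow(x), sum(x$relevant),
              length(unique(x$interaction_id)),
              nrow(unique(x[, c("cluster_a", "cluster_b", "microenvironment")]))))
  invisible(x)
}

#' Binary interaction x cluster-pair matrix
#'
#' Rows are interactions, columns are `microenvironment|cluster_a|cluster_b`
#' combinations; an entry is 1 when any orientation of that interaction is
#' relevant for that pair, else 0. The full frame of the relevance table is
#' kept even when nothing is relevant.
#'
#' @param relevance a `relevance_table`.
#' @return Integer matrix.
#' @export
to_binary_matrix <- function(relevance) {
  if (nrow(relevance) == 0L) {
    return(matrix(0L, 0L, 0L))
  }
  rows <- unique(relevance$interaction_id)
  colkey <- paste(relevance$microenvironment, relevance$cluster_a,
                  relevance$cluster_b, sep = "|")
  cols <- unique(colkey)
  m <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  rel <- relevance[relevance$relevant, , drop = FALSE]
  if (nrow(rel)) {
    relkey <- paste(rel$microenvironment, rel$cluster_a, rel$cluster_b,
                    sep = "|")
    m[cbind(rel$interaction_id, relkey)] <- 1L
  }
  m
}
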