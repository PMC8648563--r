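# Sequencing-depth-stratified Wilcoxon one-vs-rest differential expression.
#
# Rank tests on droplet data are confounded by sequencing depth: deeper cells
# detect more genes, so a cluster that happens to be deeper looks globally
# "upregulated". The remedy implemented here partitions cells into quartiles
# of total counts (independent of donor), runs the rank-sum test within each
# stratum, and combines the per-stratum Z-scores (Stouffer).

#' Assign cells to sequencing-depth quartile strata
#'
#' Cells are ranked by total counts (ties broken by stable input order) and
#' the rank range is split into `n_strata` contiguous blocks whose sizes
#' differ by at most one (earlier blocks take the remainder).
#'
#' @param total_counts numeric vector of per-cell total counts.
#' @param n_strata number of depth strata (4 = quartiles).
#' @return Integer vector of stratum indices in `1:n_strata`, aligned to the
#'   input order.
#' @export
depth_quartiles <- function(total_counts, n_strata = 4L) {
  n <- length(total_counts)
  if (n < n_strata) {
    abort(sprintf("need at least %d cells to form %d depth strata (got %d)",
                  n_strata, n_strata, n),
          "envcci_degenerate_error")
  }
  ord <- order(total_counts, seq_len(n))   # stable tie-break by input order
  sizes <- rep(n %/% n_strata, n_strata)
  extra <- n %% n_strata
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  strata <- integer(n)
  strata[ord] <- rep.int(seq_len(n_strata), sizes)
  strata
}

#' Normal-approximation Wilcoxon rank-sum Z
#'
#' Z-score of the rank-sum statistic of `values_in` against `values_out`
#' with tie-corrected variance and no continuity correction. Positive Z
#' means `values_in` is stochastically larger. If every value is tied (zero
#' rank variance) the statistic carries no information and 0 is returned.
#'
#' @param values_in,values_out numeric vectors, both non-empty.
#' @return A single Z value.
#' @export
wilcoxon_z <- function(values_in, values_out) {
  n1 <- length(values_in)
  n2 <- length(values_out)
  if (n1 == 0L || n2 == 0L) {
    abort("both groups must be non-empty", "envcci_degenerate_error")
  }
  v <- c(values_in, values_out)
  r <- rank(v)
  m <- n1 + n2
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (m + 1) / 2
  tl <- rle(sort(v))$lengths
  varw <- n1 * n2 / 12 * ((m + 1) - sum(tl^3 - tl) / (m * (m - 1)))
  if (varw <= 0) return(0)
  (w - mu) / sqrt(varw)
}

#' Stouffer combination of per-stratum Z-scores
#'
#' `sum(w * z) / sqrt(sum(w^2))` over contributing strata. The default
#' downstream weighting is `sqrt(n_in + n_out)` per stratum, so strata with
#' more cells carry more weight; equal weights give the unweighted Stouffer
#' combination. `NA` entries (non-contributing strata) are dropped together
#' with their weights.
#'
#' @param z numeric vector of per-stratum Z-scores (NA = not contributing).
#' @param weights positive weights, recycled to `length(z)`.
#' @return The combined Z, or `NA` if no stratum contributes.
#' @export
combine_z <- function(z, weights = rep(1, length(z))) {
  weights <- rep_len(weights, length(z))
  if (any(weights <= 0, na.rm = TRUE)) {
    abort("weights must be positive", "envcci_degenerate_error")
  }
  keep <- !is.na(z)
  if (!any(keep)) return(NA_real_)
  z <- z[keep]
  w <- weights[keep]
  sum(w * z) / sqrt(sum(w^2))
}

# Per-gene rank-sum Z for all genes of one stratum at once.
# Returns NA for genes with zero rank variance in the stratum.
stratum_z_matrixwise <- function(x, in_mask) {
  n1 <- sum(in_mask)
  m <- nrow(x)
  n2 <- m - n1
  if (n1 == 0L || n2 == 0L) return(rep(NA_real_, ncol(x)))
  g <- ncol(x)
  w <- numeric(g)
  tiesum <- numeric(g)
  for (j in seq_len(g)) {
    r <- rank(x[, j])
    w[j] <- sum(r[in_mask])
    tl <- rle(sort(x[, j]))$lengths
    tiesum[j] <- sum(tl^3 - tl)
  }
  mu <- n1 * (m + 1) / 2
  varw <- n1 * n2 / 12 * ((m + 1) - tiesum / (m * (m - 1)))
  z <- ifelse(varw > 0, (w - mu) / sqrt(pmax(varw, 0)), NA_real_)
  z
}

#' Depth-stratified one-vs-rest differential expression for one cluster
#'
#' For each gene, the Wilcoxon rank-sum Z of the target cluster's cells
#' against all other cells is computed within each depth stratum, the
#' per-stratum Z-scores are Stouffer-combined (weights `sqrt(stratum size)`
#' by default), two-sided p-values are taken from the standard normal, and
#' Benjamini-Hochberg adjustment is applied across genes within this
#' one-vs-rest comparison. The log2 fold change compares normalized means
#' with a 1e-9 pseudocount. Strata where either group is empty, or where the
#' gene is constant, contribute nothing; a gene with no contributing stratum
#' gets Z = 0 and p = 1 by convention.
#'
#' @param norm normalized matrix (cells x genes).
#' @param annot aligned annotation with `cluster` and `total_counts`.
#' @param target_cluster cluster label to test one-vs-rest.
#' @param strata optional precomputed stratum assignment; defaults to
#'   [depth_quartiles()] of `annot$total_counts`.
#' @param n_strata number of depth strata when `strata` is not given; 1
#'   gives the naive unstratified Wilcoxon.
#' @param weighting `"sqrt_n"` (default) or `"unweighted"` Stouffer weights.
#' @param universe optional character vector of cells defining the analysis
#'   set (the one-vs-rest out-group); default all cells in `norm`.
#' @return Data frame with columns `cluster, gene, z_combined, p_value,
#'   q_value, log2_fc, n_in, n_out`.
#' @export
stratified_de <- function(norm, annot, target_cluster, strata = NULL,
                          n_strata = 4L,
                          weighting = c("sqrt_n", "unweighted"),
                          universe = NULL) {
  weighting <- match.arg(weighting)
  cl <- as.character(annot$cluster)
  if (!target_cluster %in% cl) {
    abort(sprintf("cluster '%s' not present in annotation", target_cluster),
          "envcci_lookup_error")
  }
  keep <- rep(TRUE, nrow(norm))
  if (!is.null(universe)) keep <- rownames(norm) %in% universe
  x <- norm[keep, , drop = FALSE]
  cl <- cl[keep]
  if (is.null(strata)) {
    strata <- depth_quartiles(annot$total_counts[keep], n_strata = n_strata)
  } else {
    strata <- strata[keep]
  }
  in_mask <- cl == target_cluster
  if (!any(in_mask) || all(in_mask)) {
    abort(sprintf("cluster '%s' has no in/out split in the analysis set",
                  target_cluster),
          "envcci_degenerate_error")
  }
  levels_s <- sort(unique(strata))
  g <- ncol(x)
  zmat <- matrix(NA_real_, nrow = length(levels_s), ncol = g)
  wts <- rep(NA_real_, length(levels_s))
  for (si in seq_along(levels_s)) {
    sel <- strata == levels_s[si]
    n_in_s <- sum(in_mask & sel)
    n_out_s <- sum(!in_mask & sel)
    if (n_in_s == 0L || n_out_s == 0L) next
    zmat[si, ] <- stratum_z_matrixwise(x[sel, , drop = FALSE], in_mask[sel])
    wts[si] <- if (weighting == "sqrt_n") sqrt(n_in_s + n_out_s) else 1
  }
  zc <- vapply(seq_len(g), function(j) {
    zj <- zmat[, j]
    ok <- !is.na(zj) & !is.na(wts)
    if (!any(ok)) return(0)                       # constant gene convention
    sum(wts[ok] * zj[ok]) / sqrt(sum(wts[ok]^2))
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(zc))
  q <- stats::p.adjust(p, method = "BH")
  eps <- 1e-9
  mean_in <- colMeans(x[in_mask, , drop = FALSE])
  mean_out <- colMeans(x[!in_mask, , drop = FALSE])
  lfc <- log2((mean_in + eps) / (mean_out + eps))
  data.frame(cluster = target_cluster,
             gene = colnames(x),
             z_combined = zc,
             p_value = p,
             q_value = q,
             log2_fc = unname(lfc),
             n_in = sum(in_mask),
             n_out = sum(!in_mask),
             stringsAsFactors = FALSE)
}

#' Stratified one-vs-rest DE for several clusters
#'
#' Runs [stratified_de()] per cluster (sharing one stratum assignment over
#' the analysis set) and binds the rows; BH adjustment stays within each
#' one-vs-rest comparison.
#'
#' @inheritParams stratified_de
#' @param clusters clusters to test; default all clusters in `annot`.
#' @return Combined data frame (a DE table covering the requested clusters).
#' @export
de_all_clusters <- function(norm, annot, clusters = NULL, n_strata = 4L,
                            weighting = c("sqrt_n", "unweighted"),
                            universe = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(clusters)) clusters <- sort(unique(as.character(annot$cluster)))
  keep <- rep(TRUE, nrow(norm))
  if (!is.null(universe)) keep <- rownames(norm) %in% universe
  strata <- rep(NA_integer_, nrow(norm))
  strata[keep] <- depth_quartiles(annot$total_counts[keep], n_strata = n_strata)
  out <- lapply(clusters, function(cc) {
    stratified_de(norm, annot, cc, strata = strata,
                  weighting = weighting, universe = universe)
  })
  do.call(rbind, out)
}
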