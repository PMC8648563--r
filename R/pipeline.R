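# End-to-end run: normalize -> per-cluster summary -> stratified DE for the
# clusters appearing in eligible pairs -> relevance calling (-> optional
# permutation null), plus writing of all tabular outputs and a JSON run
# manifest sufficient to reproduce the run from the same inputs.

#' Run the full microenvironment-restricted communication analysis
#'
#' @param counts cells x genes raw count matrix.
#' @param annot cell annotation (`cell`, `cluster`, optional `donor`,
#'   `total_counts`).
#' @param db an `lr_database`.
#' @param envs a `microenv_set`.
#' @param thresholds a [relevance_thresholds()] object.
#' @param scale normalization target row sum (counts per `scale`).
#' @param n_strata depth strata for the DE test (4 = quartiles).
#' @param weighting Stouffer weighting mode, see [stratified_de()].
#' @param universe optional analysis-set cells for the DE out-group.
#' @param focal optional focal clusters passed to [eligible_pairs()].
#' @param permutation `NULL` (skip) or a [permutation_config()].
#' @param seed integer seed applied before any stochastic stage.
#' @return Object of class `ccc_analysis`: list with `summary`, `de`,
#'   `pairs`, `relevance`, `binary`, `permutation`, `thresholds`, `params`.
#' @export
run_ccc <- function(counts, annot, db, envs,
                    thresholds = relevance_thresholds(), scale = 1e4,
                    n_strata = 4L, weighting = c("sqrt_n", "unweighted"),
                    universe = NULL, focal = NULL, permutation = NULL,
                    seed = NULL) {
  weighting <- match.arg(weighting)
  if (!is.null(seed)) set.seed(seed)
  annot <- align_annotation(counts, annot)
  norm <- normalize_counts(counts, scale = scale)
  summary <- summarize_clusters(norm, counts, annot)
  clusters <- rownames(summary$mean_expr)
  pairs <- eligible_pairs(envs, clusters = clusters, focal = focal)
  clusters_needed <- sort(unique(c(pairs$cluster_a, pairs$cluster_b)))
  de <- if (length(clusters_needed)) {
    de_all_clusters(norm, annot, clusters = clusters_needed,
                    n_strata = n_strata, weighting = weighting,
                    universe = universe)
  } else {
    data.frame(cluster = character(), gene = character(),
               z_combined = numeric(), p_value = numeric(),
               q_value = numeric(), log2_fc = numeric(),
               n_in = integer(), n_out = integer())
  }
  relevance <- call_interactions(summary, db, de, pairs,
                                 thresholds = thresholds)
  binary <- to_binary_matrix(relevance)
  perm <- NULL
  if (!is.null(permutation)) {
    perm <- permutation_pvalues(norm, annot, db, pairs, cfg = permutation,
                                counts = counts)
  }
  structure(list(summary = summary, de = de, pairs = pairs,
                 relevance = relevance, binary = binary, permutation = perm,
                 thresholds = thresholds,
                 params = list(scale = scale, n_strata = n_strata,
                               weighting = weighting, seed = seed,
                               db_version = db$version,
                               permutation = permutation)),
            class = "ccc_analysis")
}

#' @method print ccc_analysis
#' @export
print.ccc_analysis <- function(x, ...) {
  cat("Microenvironment-restricted cell-cell communication analysis\n")
  cat(sprintf("  clusters summarized : %d\n", nrow(x$summary$mean_expr)))
  cat(sprintf("  eligible pairs      : %d (over %d microenvironments)\n",
              nrow(x$pairs), length(unique(x$pairs$microenvironment))))
  cat(sprintf("  relevance records   : %d, of which relevant: %d\n",
              nrow(x$relevance), sum(x$relevance$relevant)))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation records : %d\n", nrow(x$permutation)))
  }
  invisible(x)
}

#' @method summary ccc_analysis
#' @export
summary.ccc_analysis <- function(object, ...) {
  rel <- object$relevance[object$relevance$relevant, , drop = FALSE]
  by_env <- table(rel$microenvironment[!duplicated(
    rel[, c("interaction_id", "cluster_a", "cluster_b", "microenvironment")])])
  out <- list(n_relevant_records = nrow(rel),
              relevant_pairs_by_env = by_env,
              thresholds = unclass(object$thresholds))
  class(out) <- "summary.ccc_analysis"
  out
}

#' @method print summary.ccc_analysis
#' @export
print.summary.ccc_analysis <- function(x, ...) {
  cat(sprintf("Relevant records: %d\n", x$n_relevant_records))
  cat("Relevant (interaction, pair) combinations per microenvironment:\n")
  print(x$relevant_pairs_by_env)
  cat(sprintf("Thresholds: frac >= %g, log2FC > %g, FDR < %g\n",
              x$thresholds$min_frac, x$thresholds$min_log2_fc,
              x$thresholds$max_fdr))
  invisible(x)
}

#' Write all analysis outputs plus a JSON run manifest
#'
#' Writes `relevance.tsv` (long form), `binary_matrix.tsv`, `de.tsv`,
#' optionally `permutation.tsv`, and `manifest.json` recording the package
#' version, thresholds, seed, database version and MD5 digests of any input
#' files supplied, so a run can be reproduced bit for bit from the same
#' inputs.
#'
#' @param x a `ccc_analysis`.
#' @param dir output directory.
#' @param input_paths optional named character vector of input files to
#'   digest into the manifest.
#' @return Named vector of written paths, invisibly.
#' @export
write_ccc_results <- function(x, dir, input_paths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(relevance = file.path(dir, "relevance.tsv"),
             binary = file.path(dir, "binary_matrix.tsv"),
             de = file.path(dir, "de.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_ccc_tsv(as.data.frame(x$relevance), paths["relevance"])
  bm <- as.data.frame(x$binary)
  bm <- cbind(interaction_id = rownames(x$binary), bm)
  utils::write.table(bm, paths["binary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_ccc_tsv(x$de, paths["de"])
  if (!is.null(x$permutation)) {
    paths["permutation"] <- file.path(dir, "permutation.tsv")
    write_ccc_tsv(x$permutation, paths["permutation"])
  }
  digests <- if (!is.null(input_paths)) {
    as.list(tools::md5sum(input_paths))
  } else NULL
  manifest <- list(
    package = "envcci",
    package_version = as.character(utils::packageVersion("envcci")),
    thresholds = unclass(x$thresholds),
    params = x$params[c("scale", "n_strata", "weighting", "seed",
                        "db_version")],
    permutation = if (!is.null(x$params$permutation))
      unclass(x$params$permutation),
    input_md5 = digests
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(paths)
}
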