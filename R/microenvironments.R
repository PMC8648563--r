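# Named microenvironments: sets of cell types declared to co-occur in space
# and time. Only cluster pairs sharing a microenvironment are eligible for
# interaction testing; phase tags (e.g. proliferative / secretory) are
# annotation only, since distinct phases are encoded as distinct
# microenvironments.

#' Load a microenvironment membership table
#'
#' Accepts a TSV path or a data frame with columns `cell_type`,
#' `microenvironment` and optionally `phase`. Duplicate rows are collapsed;
#' a cell type may belong to several microenvironments.
#'
#' @param x TSV path or data frame.
#' @return Object of class `microenv_set` (a tidy membership data frame).
#' @export
load_microenvironments <- function(x) {
  df <- if (is.character(x)) read_tsv_file(x) else as.data.frame(x)
  require_columns(df, c("cell_type", "microenvironment"),
                  "microenvironment table")
  if (nrow(df) == 0L) {
    abort("microenvironment table is empty", "envcci_config_error")
  }
  if (!"phase" %in% names(df)) df$phase <- NA_character_
  df <- unique(df[, c("cell_type", "microenvironment", "phase")])
  rownames(df) <- NULL
  structure(df, class = c("microenv_set", "data.frame"))
}

#' Check microenvironment members against annotated clusters
#'
#' Members that match no cluster in the annotation are kept but reported as
#' a warning record (and a warning), mirroring tolerant loading of
#' user-supplied membership files.
#'
#' @param envs a `microenv_set`.
#' @param clusters character vector of cluster labels present in the data.
#' @return `envs` with attribute `"unmatched"` listing unknown members.
#' @export
validate_microenvironments <- function(envs, clusters) {
  unmatched <- setdiff(unique(envs$cell_type), clusters)
  if (length(unmatched)) {
    warning(sprintf("microenvironment member(s) not found among clusters: %s",
                    paste(unmatched, collapse = ", ")))
  }
  attr(envs, "unmatched") <- unmatched
  envs
}

#' Enumerate cluster pairs eligible for interaction testing
#'
#' All ordered pairs (including self-pairs, for autocrine signaling) of
#' clusters that share a microenvironment, tagged by that microenvironment.
#' A pair co-occurring in two microenvironments appears once per
#' microenvironment; pairs never span microenvironments.
#'
#' @param envs a `microenv_set`.
#' @param clusters optional cluster labels present in the data; members
#'   absent from it are dropped (with a warning via
#'   [validate_microenvironments()]).
#' @param focal optional cluster labels; keep only pairs touching at least
#'   one focal cluster (e.g. restrict to epithelial-centered signaling).
#' @return Data frame with columns `cluster_a`, `cluster_b`,
#'   `microenvironment`.
#' @export
eligible_pairs <- function(envs, clusters = NULL, focal = NULL) {
  if (!is.null(clusters)) envs <- validate_microenvironments(envs, clusters)
  env_names <- unique(envs$microenvironment)
  out <- lapply(env_names, function(e) {
    members <- unique(envs$cell_type[envs$microenvironment == e])
    if (!is.null(clusters)) members <- intersect(members, clusters)
    if (length(members) == 0L) return(NULL)
    g <- expand.grid(cluster_a = members, cluster_b = members,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$microenvironment <- e
    g
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(cluster_a = character(), cluster_b = character(),
                      microenvironment = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(focal)) {
    out <- out[out$cluster_a %in% focal | out$cluster_b %in% focal, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
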