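# Count-matrix ingestion, library-size normalization, and per-cluster
# expression summaries at gene and complex-partner level.

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count matrix needs cell row names and gene column names",
          "envcci_schema_error")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("duplicate cell names in count matrix", "envcci_schema_error")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("duplicate gene names in count matrix", "envcci_schema_error")
  }
  if (min(counts) < 0) {
    abort("count matrix has negative entries", "envcci_schema_error")
  }
  invisible(counts)
}

#' Read a counts matrix from MatrixMarket MTX plus name files
#'
#' The standard single-cell triplet layout: an MTX file with genes in rows
#' and cells in columns (set `orientation = "cells_by_genes"` if transposed),
#' a one-per-line gene name file, and a one-per-line cell barcode file.
#'
#' @param mtx_path MatrixMarket file.
#' @param genes_path,cells_path plain-text name files, one id per line.
#' @param orientation `"genes_by_cells"` (default, the 10x convention) or
#'   `"cells_by_genes"`.
#' @return A dense cells x genes integer matrix with dimnames.
#' @export
read_counts_mtx <- function(mtx_path, genes_path, cells_path,
                            orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (orientation == "genes_by_cells") m <- t(m)
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    abort(sprintf("matrix is %d x %d after orientation but %d cells / %d genes named",
                  nrow(m), ncol(m), length(cells), length(genes)),
          "envcci_schema_error")
  }
  dimnames(m) <- list(cells, genes)
  storage.mode(m) <- "double"
  validate_counts(m)
  m
}

#' Read a counts matrix from a dense TSV
#'
#' @param path TSV with row and column names.
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"`.
#' @return A dense cells x genes matrix.
#' @export
read_counts_tsv <- function(path,
                            orientation = c("cells_by_genes", "genes_by_cells")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (orientation == "genes_by_cells") m <- t(m)
  validate_counts(m)
  m
}

#' Write a counts matrix as MTX plus name files
#' @param counts cells x genes matrix.
#' @param dir output directory.
#' @return Paths of the three files, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, "matrix.mtx")
  gp <- file.path(dir, "genes.txt")
  bp <- file.path(dir, "barcodes.txt")
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE), mp)
  writeLines(colnames(counts), gp)
  writeLines(rownames(counts), bp)
  invisible(c(matrix = mp, genes = gp, cells = bp))
}

#' Read a per-cell annotation table
#'
#' TSV with columns `cell`, `cluster`, optionally `donor` and
#' `total_counts`. Missing total counts are derived from the matrix by
#' [align_annotation()].
#'
#' @param path TSV file path.
#' @return Data frame of cell annotations.
#' @export
read_cell_annotation <- function(path) {
  ann <- read_tsv_file(path)
  require_columns(ann, c("cell", "cluster"), "cell annotation")
  ann
}

#' Align an annotation table to a count matrix
#'
#' Checks that every cell in the matrix is annotated exactly once, reorders
#' the annotation to matrix row order, and fills `total_counts` from the
#' matrix row sums when absent.
#'
#' @param counts cells x genes matrix.
#' @param annot annotation data frame with columns `cell`, `cluster`.
#' @return The aligned annotation data frame.
#' @export
align_annotation <- function(counts, annot) {
  require_columns(annot, c("cell", "cluster"), "cell annotation")
  if (anyDuplicated(annot$cell)) {
    abort("cells annotated more than once", "envcci_schema_error")
  }
  idx <- match(rownames(counts), annot$cell)
  if (anyNA(idx)) {
    abort(sprintf("cells missing from annotation: %s",
                  paste(utils::head(rownames(counts)[is.na(idx)], 5),
                        collapse = ", ")),
          "envcci_schema_error")
  }
  ann <- annot[idx, , drop = FALSE]
  rownames(ann) <- NULL
  if (any(!nzchar(as.character(ann$cluster))) || anyNA(ann$cluster)) {
    abort("empty cluster labels in annotation", "envcci_schema_error")
  }
  if (is.null(ann$total_counts)) ann$total_counts <- unname(rowSums(counts))
  if (is.null(ann$donor)) ann$donor <- "donor1"
  ann
}

#' Library-size normalize a count matrix
#'
#' Rescales each cell so its values sum to `scale` (counts per 10,000 by
#' default). Zero entries stay zero; a cell with zero total counts is a
#' degenerate input and is rejected by name.
#'
#' @param counts cells x genes matrix of non-negative counts.
#' @param scale positive target row sum.
#' @return Matrix of the same shape, each row summing to `scale`.
#' @export
normalize_counts <- function(counts, scale = 1e4) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    abort(sprintf("cell(s) with zero total counts: %s",
                  paste(utils::head(rownames(counts)[totals <= 0], 5),
                        collapse = ", ")),
          "envcci_degenerate_error")
  }
  counts / totals * scale
}

#' Summarize expression per cluster
#'
#' For every (cluster, gene): the arithmetic mean of the normalized
#' expression over the cluster's cells, and the fraction of the cluster's
#' cells with raw count > 0 (the quantity thresholded at 10% by the
#' relevance criteria).
#'
#' @param norm normalized matrix from [normalize_counts()].
#' @param counts the raw count matrix (defines "expressed": raw count > 0).
#' @param annot aligned annotation (see [align_annotation()]).
#' @return An object of class `cluster_summary` with clusters x genes
#'   matrices `mean_expr` and `frac_expr` and a named `n_cells` vector.
#' @export
summarize_clusters <- function(norm, counts, annot) {
  if (!identical(dim(norm), dim(counts))) {
    abort("normalized and raw matrices have different shapes",
          "envcci_schema_error")
  }
  annot <- align_annotation(counts, annot)
  cl <- as.character(annot$cluster)
  n_cells <- table(cl)
  if (is.factor(annot$cluster)) {
    empty <- setdiff(levels(annot$cluster), names(n_cells))
    if (length(empty)) {
      warning(sprintf("cluster(s) with no cells omitted from summary: %s",
                      paste(empty, collapse = ", ")))
    }
  }
  mean_expr <- rowsum(norm, cl) / as.vector(n_cells[sort(unique(cl))])
  frac_expr <- rowsum((counts > 0) + 0, cl) / as.vector(n_cells[sort(unique(cl))])
  structure(list(mean_expr = mean_expr,
                 frac_expr = frac_expr,
                 n_cells = stats::setNames(as.integer(n_cells), names(n_cells))),
            class = "cluster_summary")
}

#' @method print cluster_summary
#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("cluster_summary: %d clusters x %d genes (%d cells)\n",
              nrow(x$mean_expr), ncol(x$mean_expr), sum(x$n_cells)))
  invisible(x)
}

#' Partner-level expression summary (min rule over subunits)
#'
#' A heteromeric complex is only as available as its least-expressed subunit,
#' so both the mean expression and the fraction expressing of a complex
#' partner are the minimum over its subunits; a simple partner returns its
#' gene's values unchanged.
#'
#' @param summary a `cluster_summary`.
#' @param db an `lr_database`.
#' @param partner gene id or complex id.
#' @param cluster cluster label present in the summary.
#' @return Named numeric vector `c(mean_expr =, frac_expr =)`.
#' @export
partner_summary <- function(summary, db, partner, cluster) {
  members <- members_of(db, partner)
  if (!cluster %in% rownames(summary$mean_expr)) {
    abort(sprintf("cluster '%s' not in summary", cluster),
          "envcci_lookup_error")
  }
  missing <- setdiff(members, colnames(summary$mean_expr))
  if (length(missing)) {
    abort(sprintf("member gene(s) of '%s' absent from expression matrix: %s",
                  partner, paste(missing, collapse = ", ")),
          "envcci_missing_gene")
  }
  c(mean_expr = min(summary$mean_expr[cluster, members]),
    frac_expr = min(summary$frac_expr[cluster, members]))
}
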