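# Internal helpers shared across modules.

# Classed conditions so callers can dispatch on failure category rather than
# matching message text.
abort <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "envcci_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")),
          "envcci_schema_error")
  }
  invisible(df)
}

#' Write a data frame as TSV with stable numeric formatting
#'
#' Tabular outputs are written with headers, tab separation, and doubles
#' rounded to 6 significant digits so repeated runs diff cleanly.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_ccc_tsv <- function(df, path) {
  dbl <- vapply(df, function(x) is.double(x), logical(1))
  df[dbl] <- lapply(df[dbl], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
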