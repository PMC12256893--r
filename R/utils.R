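# Shared tabular IO: every table in the pipeline is tab-separated with a
# header row, UTF-8, unquoted.

#' Read a pipeline table
#'
#' All tabular interchange in the pipeline uses tab-separated files with a
#' header row. Empty fields are read as missing.
#'
#' @param path Path to a TSV file.
#' @param col_types Optional readr column specification.
#' @return A tibble.
#' @export
read_table_tsv <- function(path, col_types = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  readr::read_tsv(path, col_types = col_types, show_col_types = FALSE,
                  progress = FALSE, na = c("", "NA"))
}

#' Write a pipeline table
#'
#' @param x A data frame.
#' @param path Output path; parent directories are created.
#' @return `x`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x, path, na = "", quote = "none", progress = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(x, cols, what = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
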