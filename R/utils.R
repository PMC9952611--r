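# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used throughout the reporting layer. Base `round()`
#' rounds half to even; disproportionality tables conventionally round
#' half away from zero, so 2.615 prints as 2.62.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-away-from-zero.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a free-text term
#'
#' Lowercases, trims, and collapses internal whitespace. Used for both
#' MedDRA preferred-term strings and verbatim drug names; no fuzzy
#' matching is attempted anywhere in the package.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Write a data.frame as plain TSV (no quoting, no row names).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

stop_pv <- function(..., call. = FALSE) stop(..., call. = call.)
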