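# Internal helpers shared across modules.

#' Stop with a classed invalid-argument error
#' @noRd
np_stop <- function(..., class = "netpharm_invalid_argument") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Check that a value is a single non-negative whole number
#' @noRd
check_count <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < if (positive) 1 else 0) {
    np_stop(name, " must be a single ",
            if (positive) "positive" else "non-negative", " integer")
  }
  as.integer(x)
}

#' Check that a value is a single number in [lo, hi]
#' @noRd
check_fraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    np_stop(name, " must be a number in ", if (open) "(" else "[",
            lo, ", ", hi, if (open) ")" else "]")
  }
  as.numeric(x)
}

#' Normalize gene symbols: trim whitespace, upper-case, drop empties
#' @noRd
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  unique(x[nzchar(x) & !is.na(x)])
}

#' Read a one-symbol-per-line gene list
#' @noRd
read_symbol_list <- function(path) {
  if (!file.exists(path)) np_stop("gene list file not found: ", path)
  normalize_symbols(readLines(path, warn = FALSE))
}

#' Write a TSV with fixed column order, no quoting
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by write_tsv
#' @noRd
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "", ...)
}
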