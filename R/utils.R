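#' @useDynLib kccomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames runif rpois
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

kc_stop <- function(...) stop(sprintf(...), call. = FALSE)

kc_assert <- function(cond, ...) if (!isTRUE(cond)) kc_stop(...)

#' Message to stderr with a level gate
#'
#' Machine outputs from this package go to files or stdout; all logging goes
#' to stderr so the two never interleave.
#' @param level one of "debug", "info", "warn"
#' @param ... passed to [sprintf()]
#' @keywords internal
kc_log <- function(level = "info", ...) {
  threshold <- getOption("kccomp.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[%s] %s", level, sprintf(...)))
  }
  invisible(NULL)
}

## Centralized coordinate conversion: internal convention is 1-based inclusive
## (GFF3-style). BED output is 0-based half-open.
to_bed_coords <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

from_bed_coords <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

trim_ws <- function(x) gsub("^\\s+|\\s+$", "", x)

split_list_field <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(v) trim_ws(v[nzchar(trim_ws(v))]))
}

join_list_field <- function(x) {
  vapply(x, function(v) paste(v, collapse = ","), character(1))
}
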