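#' @importFrom rlang %||%
#' @importFrom Rcpp sourceCpp
#' @useDynLib rimcore, .registration = TRUE
NULL

.rc_env <- new.env(parent = emptyenv())
.rc_env$log <- character()

# structured per-stage log: degenerate features, dropped patients/fits, ...
rc_log <- function(...) {
  msg <- sprintf(...)
  .rc_env$log <- c(.rc_env$log, msg)
  invisible(msg)
}

#' Inspect or clear the package's run log
#'
#' Degenerate-feature fallbacks, dropped bootstrap fits, truncated
#' extensions and omitted patients are appended here rather than silently
#' discarded.
#'
#' @return `rimcore_log()` returns a character vector of log records.
#' @export
rimcore_log <- function() .rc_env$log

#' @rdname rimcore_log
#' @export
rimcore_log_clear <- function() {
  .rc_env$log <- character()
  invisible(NULL)
}

# deterministic integer sub-seeds derived from one master seed
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
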