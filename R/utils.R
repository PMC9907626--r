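#' @noRd
hsi_log <- function(...) {
  if (isTRUE(getOption("hsicolor.verbose"))) message(sprintf(...))
  invisible()
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded generator calls
#' do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' @noRd
stop_structural <- function(...) {
  stop(structure(class = c("hsi_structural_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' @noRd
stop_validation <- function(...) {
  stop(structure(class = c("hsi_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' @noRd
stop_format <- function(...) {
  stop(structure(class = c("hsi_format_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' @noRd
stop_calibration <- function(...) {
  stop(structure(class = c("hsi_calibration_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
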