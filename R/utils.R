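# Internal helpers shared across modules.

#' Round half away from zero to a fixed number of decimals
#'
#' Base `round()` rounds half to even; printed tables in the muscle
#' literature round half up, so table-reproduction code uses this.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() wrapper that keeps call noise out of user-facing errors
fail <- function(...) stop(..., call. = FALSE)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fail(name, " must be a single finite number")
  if (positive && x <= 0) fail(name, " must be > 0")
  invisible(x)
}
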