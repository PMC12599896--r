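# Shared helpers: phase arithmetic and argument checking.

#' Wrap angles to [0, 360) degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles mapped to the half-open interval \[0, 360).
#' @export
wrap_deg <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

#' Circular distance between phases
#'
#' Wrap-corrected absolute difference between two phase angles, i.e. the
#' shorter way around the circle, in \[0, 180\] degrees.
#'
#' @param a,b Numeric vectors of phases in degrees (recycled).
#' @return Circular distances in degrees, in \[0, 180\].
#' @export
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# stopifnot-style check that names the offending argument in the message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

check_scalar_pos <- function(x, name) {
  check_that(is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0,
             sprintf("`%s` must be a single positive finite number (got %s)",
                     name, paste(format(x), collapse = ", ")))
}

check_finite <- function(x, name) {
  check_that(is.numeric(x) && all(is.finite(x)),
             sprintf("`%s` must be finite (non-finite value signals a sensor fault)",
                     name))
}
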