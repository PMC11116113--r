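#' Wrap angles into \eqn{[-\pi, \pi)}
#'
#' All heading arithmetic in the package goes through wrapped differences so
#' that comparisons near the \eqn{\pm 180^\circ} branch cut are exact.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of the same length, wrapped into `[-pi, pi)`.
#' @export
#' @examples
#' wrap_angle(c(pi, -pi, 3 * pi / 2))
wrap_angle <- function(theta) {
  ((theta + pi) %% (2 * pi)) - pi
}

#' Smallest absolute angular difference between two angles
#'
#' @param a,b numeric vectors of angles in radians (recycled).
#' @return `|wrap_angle(a - b)|`, in `[0, pi]`.
#' @export
angle_diff <- function(a, b) {
  abs(wrap_angle(a - b))
}

# A deterministic 32-bit substream seed for unit `i` of a base seed.  Keeps
# every per-individual draw sequence independent of how many other
# individuals are simulated.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 1000003) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_socioscope <- function(msg, ..., class = "socioscope_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}
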