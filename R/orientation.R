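#' Wrap angles into the canonical orientation range
#'
#' Orientations (as opposed to directions) live on a circle of period
#' \eqn{\pi}.  Every angle is represented by a unique value in the half-open
#' interval \eqn{[-\pi/2, \pi/2)}; the half-open convention guarantees that
#' \eqn{-\pi/2} and \eqn{+\pi/2}, which are the same orientation, have a
#' single representative.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector of the same length, wrapped into
#'   \eqn{[-\pi/2, \pi/2)}.
#' @examples
#' wrap_orientation(c(0, pi / 2, pi, -3 * pi / 4))
#' @export
wrap_orientation <- function(theta) {
  stopifnot(is.numeric(theta))
  ((theta + pi / 2) %% pi) - pi / 2
}

#' Signed difference between two orientations
#'
#' Computes \eqn{a - b} wrapped with period \eqn{\pi} into the half-open
#' interval \eqn{(-\pi/2, \pi/2]}.  This is the natural signed distance on
#' the orientation circle; its absolute value is at most \eqn{\pi/2}
#' (orthogonal orientations).  The boundary case of exactly orthogonal
#' orientations is reported as \eqn{+\pi/2}.
#'
#' @param a,b Numeric vectors of angles in radians (recycled).
#' @return Numeric vector of wrapped differences in \eqn{(-\pi/2, \pi/2]}.
#' @examples
#' delta_po(0.3, 0.3)        # 0
#' delta_po(pi / 4, -pi / 4) # pi/2 (orthogonal)
#' @export
delta_po <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  d <- (a - b) %% pi
  ifelse(d > pi / 2, d - pi, d)
}
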