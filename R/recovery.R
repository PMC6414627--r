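#' Recover the A-P bow amplitude of a digitized curve
#'
#' Estimates the anterior bow amplitude of a single (unaligned, mm-scale)
#' semilandmark curve: displacement of each semilandmark from the chord
#' line through the endpoints is projected onto the curve's own anatomical
#' A-P axis, and the maximum projection is returned. For the parametric
#' template family this recovers the generative amplitude A up to
#' semilandmark discretization; it is the downstream ground-truth check for
#' the synthetic generator's diachronic trend.
#'
#' @param curve A [semilandmark_curve()] or k x 3 matrix in mm.
#' @return Estimated bow amplitude (mm).
#' @export
estimate_bow_amplitude <- function(curve) {
  x <- as_config(curve)
  fr <- anatomical_frame(x)
  disp <- sweep(x, 2L, x[1L, ])
  perp <- disp - (disp %*% fr$pd_axis) %*% rbind(fr$pd_axis)
  max(perp %*% fr$ap_axis)
}

#' Recover the M-L sigmoid amplitude of a digitized curve
#'
#' Companion to [estimate_bow_amplitude()]: maximum absolute medio-lateral
#' component of the chord-line displacement.
#'
#' @param curve A [semilandmark_curve()] or k x 3 matrix in mm.
#' @return Estimated sigmoid amplitude (mm).
#' @export
estimate_sigmoid_amplitude <- function(curve) {
  x <- as_config(curve)
  fr <- anatomical_frame(x)
  disp <- sweep(x, 2L, x[1L, ])
  perp <- disp - (disp %*% fr$pd_axis) %*% rbind(fr$pd_axis)
  max(abs(perp %*% fr$ml_axis))
}
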