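#' Axial (fiber-orientation) angle utilities
#'
#' Fiber orientations are axial quantities: an axis at 10 degrees is the same
#' axis as one at 190 degrees, so all comparisons are taken modulo 180 and the
#' distance between two axes lies in \[0, 90\] degrees.
#'
#' @param a_deg,b_deg angles in degrees (any real values; reduced mod 180).
#' @return `axial_difference()` returns the minimal axial angle between the two
#'   axes, in \[0, 90\]. `axial_signed_difference()` returns the signed offset
#'   `a - b` folded into \[-90, 90), i.e. the rotation that carries axis `b`
#'   onto axis `a` along the shorter way.
#' @examples
#' axial_difference(175, 5)   # 10, across the 180 wrap
#' axial_signed_difference(2, 175)  # +7
#' @export
axial_difference <- function(a_deg, b_deg) {
  m <- abs(a_deg - b_deg) %% 180
  pmin(m, 180 - m)
}

#' @rdname axial_difference
#' @export
axial_signed_difference <- function(a_deg, b_deg) {
  ((a_deg - b_deg + 90) %% 180) - 90
}

#' Axial circular mean and median
#'
#' The axial mean doubles the angles so that axes 180 degrees apart coincide,
#' averages the resulting unit phasors (optionally weighted), and halves the
#' argument.  The axial median minimises the summed axial distance to the
#' sample; when several sample values tie as minimisers (e.g. with two
#' observations) their axial mean is returned.
#'
#' @param angles_deg numeric vector of axes in degrees.
#' @param w optional non-negative weights.
#' @return an angle in \[0, 180).
#' @export
axial_mean <- function(angles_deg, w = NULL) {
  if (length(angles_deg) == 0L) stop("empty angle vector")
  if (is.null(w)) w <- rep(1, length(angles_deg))
  z <- sum(w * exp(2i * angles_deg * pi / 180))
  if (Mod(z) < 1e-12) return(NA_real_)  # no preferred axis
  out <- (Arg(z) * 180 / pi / 2) %% 180
  if (out >= 180 - 1e-9) 0 else out  # guard the wrap against Arg() round-off
}

#' @rdname axial_mean
#' @export
axial_median <- function(angles_deg) {
  n <- length(angles_deg)
  if (n == 0L) stop("empty angle vector")
  if (n == 1L) return(angles_deg %% 180)
  cost <- vapply(angles_deg, function(c) sum(axial_difference(c, angles_deg)),
                 numeric(1))
  best <- which(cost <= min(cost) + 1e-9)
  axial_mean(angles_deg[best])
}
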