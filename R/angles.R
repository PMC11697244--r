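#' Angle utilities for director (optic-axis) and doubled-angle arithmetic
#'
#' Fiber orientation is a director: an angle defined modulo 180 degrees.
#' All harmonic phases produced by the polarization sweep live in the
#' doubled-angle domain (period 360 degrees there, 180 in orientation),
#' because the photoacoustic signal depends on cos 2(theta - phi) only.
#'
#' @name angles
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap doubled-angle phases to (-180, 180] degrees
#'
#' @param x angles in degrees (doubled-angle domain).
#' @return wrapped angles in (-180, 180].
#' @export
wrap_phase <- function(x) {
  r <- x %% 360
  i <- which(r > 180)
  r[i] <- r[i] - 360
  r
}

#' Wrap orientations (directors) to (-90, 90] degrees
#'
#' @param x angles in degrees (orientation domain, period 180).
#' @return wrapped angles in (-90, 90].
#' @export
wrap_orientation <- function(x) {
  r <- x %% 180
  i <- which(r > 90)
  r[i] <- r[i] - 180
  r
}

#' Signed difference between two orientations
#'
#' The difference is computed on the director circle, so 89 deg and -89 deg
#' are 2 degrees apart, not 178.
#'
#' @param a,b orientations in degrees.
#' @return wrapped difference a - b in (-90, 90].
#' @export
orientation_diff <- function(a, b) wrap_orientation(a - b)

#' Circular mean and dispersion of orientations
#'
#' Computed by vector averaging on the doubled-angle circle and halving,
#' the standard construction for axial (director) data.
#'
#' @param phi orientations in degrees; NA dropped.
#' @return list with `mean` (degrees, NA when the resultant vanishes, e.g.
#'   equal mass at two perpendicular orientations), `std` (circular standard
#'   deviation, degrees), `resultant` (mean resultant length in [0, 1]) and
#'   `n` (number of observations used).
#' @export
orientation_mean <- function(phi) {
  phi <- phi[is.finite(phi)]
  n <- length(phi)
  if (n == 0L) {
    return(list(mean = NA_real_, std = NA_real_, resultant = NA_real_, n = 0L))
  }
  z <- mean(exp(2i * deg2rad(phi)))
  r <- Mod(z)
  if (r < 1e-8) {
    return(list(mean = NA_real_, std = NA_real_, resultant = r, n = n))
  }
  m <- wrap_orientation(rad2deg(Arg(z)) / 2)
  s <- rad2deg(sqrt(-2 * log(r))) / 2
  list(mean = m, std = s, resultant = r, n = n)
}

# Linear interpolation of orientations along an index axis, performed on
# doubled-angle unit vectors so it is safe across the +/-90 wrap. Ends are
# filled with the nearest known value (approx rule = 2).
interp_orientation <- function(idx_known, phi_known, idx_out) {
  keep <- is.finite(phi_known)
  idx_known <- idx_known[keep]
  phi_known <- phi_known[keep]
  if (length(idx_known) == 0L) return(rep(NA_real_, length(idx_out)))
  if (length(idx_known) == 1L) return(rep(wrap_orientation(phi_known), length(idx_out)))
  a2 <- deg2rad(2 * phi_known)
  cx <- stats::approx(idx_known, cos(a2), xout = idx_out, rule = 2)$y
  sx <- stats::approx(idx_known, sin(a2), xout = idx_out, rule = 2)$y
  wrap_orientation(rad2deg(atan2(sx, cx)) / 2)
}
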