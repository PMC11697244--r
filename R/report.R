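#' Orientation histogram and circular summary over a region
#'
#' Bins recovered optic-axis orientations over (-90, 90] and summarizes
#' them with director circular statistics (vector averaging of doubled
#' angles, halved). The histogram peak indicates the dominant fiber
#' orientation of the region.
#'
#' @param phi_map orientation matrix, degrees.
#' @param valid logical validity matrix; NULL = all finite pixels.
#' @param roi region of interest, a list with integer vectors `rows` and
#'   `cols` (grid indices); NULL = whole image.
#' @param bin_width histogram bin width in degrees; must divide 180.
#' @return object of class `orientation_summary`: `counts`, `breaks`,
#'   `mids`, `circular_mean` (deg, NA when the resultant vanishes),
#'   `circular_std` (deg), `n_pixels`, `roi`.
#' @export
orientation_histogram <- function(phi_map, valid = NULL, roi = NULL,
                                  bin_width = 5) {
  if (abs(180 / bin_width - round(180 / bin_width)) > 1e-9)
    stop("bin_width must divide 180", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(phi_map)
  sel <- valid & is.finite(phi_map)
  if (!is.null(roi)) {
    m <- matrix(FALSE, nrow(phi_map), ncol(phi_map))
    m[roi$rows, roi$cols] <- TRUE
    sel <- sel & m
  }
  values <- wrap_orientation(phi_map[sel])
  if (length(values) == 0L) stop("empty ROI", call. = FALSE)
  breaks <- seq(-90, 90, by = bin_width)
  # values lie in (-90, 90]: bin k is (breaks[k], breaks[k+1]]
  counts <- tabulate(findInterval(values, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  cm <- orientation_mean(values)
  structure(list(counts = counts, breaks = breaks,
                 mids = breaks[-length(breaks)] + bin_width / 2,
                 circular_mean = cm$mean, circular_std = cm$std,
                 resultant = cm$resultant, n_pixels = length(values),
                 roi = roi),
            class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat("<orientation_summary> n=", x$n_pixels,
      "  circular mean=", if (is.na(x$circular_mean)) "undefined"
      else sprintf("%.2f deg", x$circular_mean),
      "  circular sd=", if (is.na(x$circular_std)) "-"
      else sprintf("%.2f deg", x$circular_std), "\n", sep = "")
  invisible(x)
}

#' Root-mean-square angular error between orientation maps
#'
#' Per-pixel differences are wrapped on the director circle to (-90, 90]
#' (89 deg vs -89 deg is a 2-degree error) before squaring.
#'
#' @param phi_est_map,phi_true_map orientation matrices, degrees.
#' @param valid logical matrix of pixels to include; NULL = all pixels
#'   finite in both maps.
#' @return RMSE in degrees.
#' @export
angular_error <- function(phi_est_map, phi_true_map, valid = NULL) {
  stopifnot(all(dim(phi_est_map) == dim(phi_true_map)))
  if (is.null(valid)) valid <- TRUE
  sel <- valid & is.finite(phi_est_map) & is.finite(phi_true_map)
  if (!any(sel)) stop("no overlapping valid pixels", call. = FALSE)
  d <- orientation_diff(phi_est_map[sel], phi_true_map[sel])
  sqrt(mean(d^2))
}

#' Depth profiles of the observables and recovered parameters
#'
#' Collects, for one lateral column, the raw H1 phase (halved to the
#' orientation domain), the recovered phi and psi, and the modulation
#' amplitudes alpha and beta against depth — the standard A-line diagnostic
#' of the method.
#'
#' @param spectral a `spectral_maps`.
#' @param est an `estimate_maps`.
#' @param column lateral column index.
#' @return data.frame with depth_cm, eta_half, phi, psi, alpha, beta, xi.
#' @export
depth_profiles <- function(spectral, est, column = 1L) {
  z <- depth_centers(spectral$grid)
  data.frame(depth_cm = z,
             eta_half = wrap_orientation(spectral$h1_phase[, column] / 2),
             xi = spectral$xi[, column],
             phi = est$phi_map[, column],
             psi = est$psi_map[, column],
             alpha = est$alpha_map[, column],
             beta = est$beta_map[, column])
}

#' Plot A-line phase and modulation profiles
#'
#' Two stacked panels mirroring the method's diagnostic figure: phases
#' (raw H1 phase, recovered phi and psi) and modulations (alpha, beta, xi)
#' versus depth.
#'
#' @param profiles data.frame from [depth_profiles()].
#' @param file optional PNG path; NULL plots to the active device.
#' @return `file` (or NULL), invisibly.
#' @export
plot_depth_profiles <- function(profiles, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 900, height = 700)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  z <- profiles$depth_cm * 10
  graphics::plot(z, profiles$eta_half, type = "p", pch = 1, col = "grey40",
                 ylim = c(-90, 180), xlab = "depth [mm]", ylab = "angle [deg]",
                 main = "phases")
  graphics::lines(z, profiles$phi, col = "firebrick", lwd = 2)
  graphics::lines(z, profiles$psi, col = "steelblue", lwd = 2, lty = 2)
  graphics::legend("topleft", c("raw H1 phase / 2", "phi (optic axis)",
                                "psi (fluence)"),
                   col = c("grey40", "firebrick", "steelblue"),
                   lty = c(NA, 1, 2), pch = c(1, NA, NA), bty = "n")
  graphics::plot(z, profiles$alpha, type = "l", col = "steelblue", lwd = 2,
                 xlab = "depth [mm]", ylab = "modulation",
                 ylim = range(c(0, profiles$alpha, profiles$beta, profiles$xi),
                              na.rm = TRUE),
                 main = "modulations")
  graphics::lines(z, profiles$beta, col = "firebrick", lwd = 2)
  graphics::lines(z, profiles$xi, col = "grey40", lty = 3)
  graphics::legend("topleft", c("alpha (fluence)", "beta (dichroism)",
                                "xi (measured)"),
                   col = c("steelblue", "firebrick", "grey40"),
                   lty = c(1, 1, 3), bty = "n")
  invisible(file)
}

#' Export an orientation map as TIFF
#'
#' Writes the map scaled from (-90, 90] to [0, 1]; NA pixels map to 0.
#' Requires the optional tiff package.
#'
#' @param phi_map orientation matrix in degrees.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_phi_tiff <- function(phi_map, file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  img <- (wrap_orientation(phi_map) + 90) / 180
  img[!is.finite(img)] <- 0
  tiff::writeTIFF(img, file)
  invisible(file)
}
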