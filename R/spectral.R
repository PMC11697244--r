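#' Correct frames for recorded pulse-energy fluctuations
#'
#' Divides each acquisition by its recorded relative pulse energy (the
#' global per-shot laser fluctuation) and resets the energies to 1, the
#' standard correction when the laser energy is logged per shot.
#'
#' @param stack a `sweep_stack`.
#' @return the corrected `sweep_stack`.
#' @export
energy_correct <- function(stack) {
  e <- stack$energies
  if (any(!is.finite(e)) || any(e <= 0))
    stop("recorded pulse energies must be positive", call. = FALSE)
  T <- length(e)
  for (t in seq_len(T)) stack$data[, , t] <- stack$data[, , t] / e[t]
  stack$energies <- rep(1, T)
  stack
}

#' Per-pixel harmonic demodulation of a polarization sweep
#'
#' FFT of each pixel's amplitude across the polarization sweep. The signal
#' has period 180 degrees in polarization, so its spectrum concentrates in
#' three components: DC (mean pressure), the fundamental H1 at cos 2theta
#' (the mixed fluence/absorption modulation), and the second harmonic H2 at
#' cos 4theta (the fluence x absorption product term). Phases are returned
#' in the doubled-angle convention: the fitted component is
#' A cos(2 theta - delta) for H1 and A cos(4 theta - delta2) for H2, with
#' `h2_phase` = delta2/2 so it is directly comparable to phi + psi
#' (modulo 180). When the sweep's end angle duplicates its start modulo 180
#' (e.g. 0 to 1080 inclusive) the final sample is dropped so the analysis
#' window is an integer number of modulation periods and the bins are
#' leakage-free.
#'
#' @param stack a `sweep_stack` (energy-correct it first if the energies
#'   are not all 1).
#' @return object of class `spectral_maps` with matrices `p_mean`,
#'   `h1_amp`, `h1_phase` (deg, (-180, 180]), `h2_amp`, `h2_phase` (deg),
#'   `xi` = h1_amp / p_mean, plus `n_cycles`, `grid` and the stack's
#'   `truth` pass-through.
#' @export
polarization_spectrum <- function(stack) {
  thetas <- stack$thetas
  T <- length(thetas)
  if (T < 3) stop("need at least 3 acquisitions", call. = FALSE)
  steps <- diff(thetas)
  if (max(abs(steps - steps[1])) > 1e-9)
    stop("polarization angles must be uniformly spaced", call. = FALSE)
  step <- steps[1]
  if (step >= 90)
    stop("theta_step must be < 90 deg (at least 2 samples per 180-deg ",
         "modulation period)", call. = FALSE)
  drop_last <- abs((thetas[T] - thetas[1]) %% 180) < 1e-9
  N <- if (drop_last) T - 1L else T
  cyc <- N * step / 180
  if (abs(cyc - round(cyc)) > 1e-9)
    stop("sweep window must span an integer number of 180-deg modulation ",
         "periods", call. = FALSE)
  cyc <- as.integer(round(cyc))
  if (2L * cyc >= N)
    stop("too few samples to resolve the second harmonic", call. = FALSE)

  g <- stack$grid
  nd <- g$n_depth; nl <- g$n_lateral
  m <- matrix(stack$data, nd * nl, T)[, seq_len(N), drop = FALSE]
  X <- stats::mvfft(t(m)) / N           # N x npix, bins 0..N-1 in rows
  th0 <- thetas[1]

  p_mean <- matrix(Re(X[1, ]), nd, nl)
  h1 <- X[cyc + 1L, ]
  h1_amp <- matrix(2 * Mod(h1), nd, nl)
  h1_phase <- matrix(wrap_phase(2 * th0 - rad2deg(Arg(h1))), nd, nl)
  h2 <- X[2L * cyc + 1L, ]
  h2_amp <- matrix(2 * Mod(h2), nd, nl)
  h2_phase <- matrix(wrap_phase(4 * th0 - rad2deg(Arg(h2))) / 2, nd, nl)

  xi <- h1_amp / p_mean
  xi[!is.finite(xi) | p_mean <= 0] <- NA_real_
  structure(list(p_mean = p_mean, h1_amp = h1_amp, h1_phase = h1_phase,
                 h2_amp = h2_amp, h2_phase = h2_phase, xi = xi,
                 n_cycles = cyc, n_samples = N, grid = g,
                 truth = stack$truth, mode = stack$mode),
            class = "spectral_maps")
}

#' @export
print.spectral_maps <- function(x, ...) {
  cat("<spectral_maps> ", x$grid$n_depth, "x", x$grid$n_lateral,
      " pixels, fundamental bin ", x$n_cycles, " over ", x$n_samples,
      " samples\n", sep = "")
  invisible(x)
}

#' Closed-form fundamental (H1) observables of the product model
#'
#' The two-tone sum alpha cos(2theta - 2psi) + beta cos(2theta - 2phi)
#' has amplitude xi = sqrt(alpha^2 + beta^2 + 2 alpha beta cos 2(phi - psi))
#' and phase eta = atan2(alpha sin 2psi + beta sin 2phi,
#'                       alpha cos 2psi + beta cos 2phi).
#' For fixed phase difference, eta moves sigmoid-like between the
#' absorption asymptote 2 phi (alpha/beta -> 0) and the fluence asymptote
#' 2 psi (alpha/beta -> Inf).
#'
#' @param alpha fluence modulation amplitude(s), >= 0.
#' @param beta dichroism ratio(s), >= 0.
#' @param phi optic-axis orientation(s), degrees.
#' @param psi fluence phase(s), degrees.
#' @return list with `xi` (dimensionless) and `eta` (degrees, doubled-angle
#'   domain, NA where the amplitude vanishes and the phase is
#'   indeterminate, e.g. alpha = beta with phi - psi = 90 deg).
#' @export
h1_closed_form <- function(alpha, beta, phi, psi) {
  p2 <- 2 * deg2rad(psi)
  f2 <- 2 * deg2rad(phi)
  S <- alpha * sin(p2) + beta * sin(f2)
  C <- alpha * cos(p2) + beta * cos(f2)
  xi <- sqrt(S^2 + C^2)
  eta <- wrap_phase(rad2deg(atan2(S, C)))
  eta[xi < 1e-12] <- NA_real_
  list(xi = xi, eta = eta)
}
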