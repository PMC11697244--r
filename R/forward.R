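#' Polarization sweep protocol
#'
#' Defaults follow the acquisition protocol used throughout: half-wave-plate
#' driven polarization from 0 to 1080 degrees (three revolutions) in steps
#' of 10 degrees (109 acquisitions), 40-frame averaging per angle, and a
#' surface fluence of 5 mJ/cm2.
#'
#' @param theta_start,theta_end sweep limits in degrees.
#' @param theta_step angular increment per acquisition, degrees, > 0.
#' @param n_averages frames averaged per acquisition, >= 1.
#' @param fluence_0 surface fluence F0 in mJ/cm2.
#' @return object of class `sweep_config`; `n_acquisitions(cfg)` gives the
#'   number of frames.
#' @export
sweep_config <- function(theta_start = 0, theta_end = 1080, theta_step = 10,
                         n_averages = 40, fluence_0 = 5) {
  stopifnot(theta_step > 0, n_averages >= 1, fluence_0 > 0)
  nsteps <- (theta_end - theta_start) / theta_step
  if (abs(nsteps - round(nsteps)) > 1e-9)
    stop("(theta_end - theta_start) must be an integer multiple of theta_step",
         call. = FALSE)
  structure(list(theta_start = theta_start, theta_end = theta_end,
                 theta_step = theta_step, n_averages = as.integer(n_averages),
                 fluence_0 = fluence_0),
            class = "sweep_config")
}

#' Number of acquisitions in a sweep
#' @param sweep a `sweep_config`.
#' @return integer frame count.
#' @export
n_acquisitions <- function(sweep)
  as.integer(round((sweep$theta_end - sweep$theta_start) / sweep$theta_step)) + 1L

#' Acquisition noise model
#'
#' Additive per-frame Gaussian noise (acoustic/electronic) and multiplicative
#' pulse-to-pulse laser energy jitter, the two instabilities the protocol
#' counteracts by frame averaging and by recording the pulse energy.
#'
#' @param additive_sigma per-frame additive noise standard deviation, in
#'   pressure units, >= 0. Frame averaging reduces it by sqrt(n_averages).
#' @param energy_jitter_cv coefficient of variation of the pulse energy,
#'   >= 0 (energies have mean 1).
#' @param seed RNG seed for reproducible acquisitions (NULL = current RNG).
#' @return object of class `noise_config`.
#' @export
noise_config <- function(additive_sigma = 0, energy_jitter_cv = 0, seed = NULL) {
  stopifnot(additive_sigma >= 0, energy_jitter_cv >= 0)
  structure(list(additive_sigma = additive_sigma,
                 energy_jitter_cv = energy_jitter_cv, seed = seed),
            class = "noise_config")
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Polarization-dependent absorption coefficient
#'
#' mu_a(theta) = mu_a_mean + (delta_mu_a/2) cos 2(theta - phi): the linear
#' dichroism law for a uniaxial absorber. Under this sign convention theta
#' aligned with the optic axis gives the ordinary coefficient; set
#' `convention = "extraordinary-aligned"` to flip the sign of the dichroic
#' term instead.
#'
#' @param phantom a `tissue_phantom`.
#' @param pixel integer pair (depth row, lateral column), or NULL for the
#'   whole map.
#' @param theta polarization angle in degrees (scalar).
#' @param convention dichroic sign convention (see above).
#' @return absorption coefficient(s) in 1/cm; a scalar for a pixel, a
#'   matrix for the whole map. Water pixels return 0.
#' @export
absorption_at <- function(phantom, pixel = NULL, theta,
                          convention = c("ordinary-aligned", "extraordinary-aligned")) {
  convention <- match.arg(convention)
  s <- if (convention == "ordinary-aligned") 1 else -1
  if (is.null(pixel)) {
    mu <- phantom$mu_a_mean_map
    dmu <- phantom$delta_mu_a_map
    phi <- phantom$phi_map
    co <- cos(2 * deg2rad(theta - phi))
    co[!is.finite(co)] <- 0   # water: phi undefined, dmu = 0 anyway
    return(mu + s * dmu / 2 * co)
  }
  i <- pixel[1]; j <- pixel[2]
  g <- phantom$grid
  if (i < 1 || i > g$n_depth || j < 1 || j > g$n_lateral)
    stop("pixel outside grid", call. = FALSE)
  mu <- phantom$mu_a_mean_map[i, j]
  dmu <- phantom$delta_mu_a_map[i, j]
  phi <- phantom$phi_map[i, j]
  if (!is.finite(phi)) return(mu)
  mu + s * dmu / 2 * cos(2 * deg2rad(theta - phi))
}

# Cumulative line integral along depth (trapezoid at grid resolution, with
# the half-cell from the surface to the first center as a rectangle):
# I_i = dz * (sum_{k<=i} m_k - m_i/2), exact for piecewise-constant columns.
cumtrapz_depth <- function(m, dz) {
  cs <- apply(m, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = nrow(m))
  dz * (cs - m / 2)
}

# Scattering contribution to the attenuation integrand: the reduced
# scattering coefficient applies inside tissue only.
mus_map <- function(phantom, mus_prime) {
  if (mus_prime == 0) return(0)
  mus_prime * (phantom$mu_a_mean_map > 0)
}

#' Exact per-polarization fluence
#'
#' Beer-Lambert decay along each ballistic ray (one per lateral column):
#' F(z, theta) = F0 exp(-integral_0^z mu_a(theta) dz'), with the line
#' integral accumulated by trapezoid on the grid. With `mus_prime > 0` the
#' integrand becomes the effective attenuation mu_a + mus_prime inside
#' tissue (scattering substitution; default off).
#'
#' @param phantom a `tissue_phantom`.
#' @param theta polarization angle, degrees.
#' @param F0 surface fluence, mJ/cm2.
#' @param mus_prime reduced scattering coefficient, 1/cm.
#' @return fluence matrix in mJ/cm2 (n_depth x n_lateral).
#' @export
fluence_exact <- function(phantom, theta, F0 = 5, mus_prime = 0) {
  mu <- absorption_at(phantom, NULL, theta) + mus_map(phantom, mus_prime)
  F0 * exp(-cumtrapz_depth(mu, phantom$grid$dz))
}

# Accumulated dichroic integral per column, as a complex map:
# C(z) = integral_0^z (delta_mu_a/2) e^{i 2 phi} dz'.
# The truncated fluence's modulation is m(theta, z) = -Re(e^{i2theta} conj(C))
# = alpha cos(2 theta - 2 psi) with alpha = |C|, 2psi = arg(-C); the minus
# sign of the Maclaurin expansion is absorbed into psi so alpha stays >= 0
# (homogeneous media then satisfy phi = psi + 90 deg).
dichroic_accumulation <- function(phantom) {
  phi2 <- 2 * deg2rad(phantom$phi_map)
  integ <- phantom$delta_mu_a_map / 2 * exp(1i * phi2)
  integ[!is.finite(integ)] <- 0 + 0i
  cre <- cumtrapz_depth(Re(integ), phantom$grid$dz)
  cim <- cumtrapz_depth(Im(integ), phantom$grid$dz)
  C <- cre + 1i * cim
  alpha <- Mod(C)
  psi2 <- Arg(-C)                       # radians, doubled-angle
  psi2[alpha < 1e-300] <- NA_real_
  list(C = C, alpha = alpha, psi2 = psi2)
}

# All theta-independent fields of the truncated (product-form) model.
forward_fields <- function(phantom, F0 = 5, mus_prime = 0) {
  acc <- dichroic_accumulation(phantom)
  mu <- phantom$mu_a_mean_map
  Ibar <- cumtrapz_depth(mu + mus_map(phantom, mus_prime), phantom$grid$dz)
  beta <- ifelse(mu > 0, phantom$delta_mu_a_map / (2 * mu), 0)
  list(fbar = F0 * exp(-Ibar),
       pbar = phantom$grueneisen_eta * mu * F0 * exp(-Ibar),
       alpha = acc$alpha, psi2 = acc$psi2, beta = beta,
       phi2 = 2 * deg2rad(phantom$phi_map))
}

#' Truncated (second-order) per-polarization fluence
#'
#' Maclaurin truncation of the dichroic part of the Beer-Lambert exponent:
#' F ~ F0 exp(-int mu_a_mean) (1 + alpha cos(2 theta - 2 psi)), where
#' (alpha, psi) are the amplitude and phase of the accumulated fluence
#' modulation at each pixel. alpha is nonnegative; psi is reported in
#' [0, 180) degrees so a homogeneous layer satisfies psi = phi + 90.
#'
#' @inheritParams fluence_exact
#' @return list with `fluence` (matrix, mJ/cm2), `alpha` (matrix,
#'   dimensionless) and `psi` (matrix, degrees in [0, 180), NA where
#'   alpha = 0).
#' @export
fluence_approx <- function(phantom, theta, F0 = 5, mus_prime = 0) {
  f <- forward_fields(phantom, F0, mus_prime)
  m <- f$alpha * cos(2 * deg2rad(theta) - f$psi2)
  m[!is.finite(m)] <- 0
  psi <- rad2deg(f$psi2) / 2
  psi <- ifelse(is.finite(psi), psi %% 180, NA_real_)
  list(fluence = f$fbar * (1 + m), alpha = f$alpha, psi = psi)
}

#' Initial-pressure map at one polarization angle
#'
#' p = Grueneisen_eta * F * mu_a per pixel. In `approx` mode this is
#' identically the product form
#' p = pbar (1 + alpha cos(2 theta - 2 psi)) (1 + beta cos(2 theta - 2 phi)),
#' with pbar the polarization-independent mean pressure and
#' beta = delta_mu_a / (2 mu_a_mean) the local dichroism ratio.
#'
#' @inheritParams fluence_exact
#' @param mode "approx" (truncated fluence, the analysis model) or "exact"
#'   (full Beer-Lambert).
#' @return pressure matrix (n_depth x n_lateral).
#' @export
pressure_map <- function(phantom, theta, F0 = 5, mode = c("approx", "exact"),
                         mus_prime = 0) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    return(phantom$grueneisen_eta *
             fluence_exact(phantom, theta, F0, mus_prime) *
             absorption_at(phantom, NULL, theta))
  }
  f <- forward_fields(phantom, F0, mus_prime)
  th2 <- 2 * deg2rad(theta)
  m <- f$alpha * cos(th2 - f$psi2)
  m[!is.finite(m)] <- 0
  b <- f$beta * cos(th2 - f$phi2)
  b[!is.finite(b)] <- 0
  f$pbar * (1 + m) * (1 + b)
}

#' Simulate a full polarization-swept acquisition
#'
#' For each acquisition t at theta_t = theta_start + t * theta_step, the
#' recorded frame is energy_t * p(theta_t) + additive noise, where energy_t
#' is the relative pulse energy of that shot (mean 1, CV
#' `energy_jitter_cv`, multiplying the whole frame) and the additive noise
#' is the average of `n_averages` i.i.d. Gaussian draws (simulated directly
#' as one draw with sd additive_sigma / sqrt(n_averages); distributionally
#' identical). Fully reproducible from `noise$seed`.
#'
#' @param phantom a `tissue_phantom`.
#' @param sweep a `sweep_config`.
#' @param noise a `noise_config`.
#' @param mode forward model mode, see [pressure_map()].
#' @param mus_prime reduced scattering coefficient for the effective
#'   attenuation substitution, 1/cm.
#' @return object of class `sweep_stack`: `data` (n_depth x n_lateral x T
#'   array), `thetas` (degrees), `energies` (relative, mean ~1), `grid`,
#'   `truth` (the generating phantom), plus the generating configs.
#' @export
acquire_sweep <- function(phantom, sweep = sweep_config(),
                          noise = noise_config(), mode = c("approx", "exact"),
                          mus_prime = 0) {
  mode <- match.arg(mode)
  thetas <- seq(sweep$theta_start, sweep$theta_end, by = sweep$theta_step)
  T <- length(thetas)
  g <- phantom$grid
  nd <- g$n_depth; nl <- g$n_lateral
  sig <- noise$additive_sigma / sqrt(sweep$n_averages)
  f <- if (mode == "approx") forward_fields(phantom, sweep$fluence_0, mus_prime)
  data <- array(0, dim = c(nd, nl, T))
  with_seed(noise$seed, {
    energies <- if (noise$energy_jitter_cv > 0)
      pmax(1 + stats::rnorm(T, 0, noise$energy_jitter_cv), 1e-6)
    else rep(1, T)
    for (t in seq_len(T)) {
      p <- if (mode == "approx") {
        th2 <- 2 * deg2rad(thetas[t])
        m <- f$alpha * cos(th2 - f$psi2); m[!is.finite(m)] <- 0
        b <- f$beta * cos(th2 - f$phi2); b[!is.finite(b)] <- 0
        f$pbar * (1 + m) * (1 + b)
      } else {
        pressure_map(phantom, thetas[t], sweep$fluence_0, "exact", mus_prime)
      }
      frame <- energies[t] * p
      if (sig > 0) frame <- frame + matrix(stats::rnorm(nd * nl, 0, sig), nd, nl)
      data[, , t] <- frame
    }
  })
  structure(list(data = data, thetas = thetas, energies = energies,
                 grid = g, truth = phantom, sweep = sweep, noise = noise,
                 mode = mode, mus_prime = mus_prime),
            class = "sweep_stack")
}

#' @export
print.sweep_stack <- function(x, ...) {
  cat("<sweep_stack> ", dim(x$data)[1], "x", dim(x$data)[2], " pixels, ",
      length(x$thetas), " acquisitions (", x$thetas[1], " to ",
      x$thetas[length(x$thetas)], " deg), mode=", x$mode, "\n", sep = "")
  invisible(x)
}

#' Additive noise level for a target surface H1 SNR
#'
#' Computes the per-frame additive noise sigma such that, after frame
#' averaging and harmonic demodulation, the surface-pixel fundamental (H1)
#' amplitude is `target_snr` times the standard deviation of the background
#' H1-amplitude noise floor. The floor is Rayleigh: with per-pixel
#' post-averaging noise sd s and N demodulated samples, the background H1
#' amplitude has sd s * sqrt(2/N) * sqrt(2 - pi/2). Closed form; no
#' simulation involved.
#'
#' @param phantom a `tissue_phantom`.
#' @param sweep a `sweep_config`.
#' @param target_snr desired surface H1 amplitude / background sd.
#' @return additive sigma for [noise_config()].
#' @export
calibrate_additive_sigma <- function(phantom, sweep = sweep_config(),
                                     target_snr = 20) {
  f <- forward_fields(phantom, sweep$fluence_0)
  surf <- which(phantom$mu_a_mean_map[, 1] > 0)[1]
  if (is.na(surf)) stop("phantom has no tissue", call. = FALSE)
  amp_surf <- f$pbar[surf, 1] * abs(f$beta[surf, 1])
  T <- n_acquisitions(sweep)
  span <- (sweep$theta_end - sweep$theta_start) %% 180
  N <- if (abs(span) < 1e-9 && T > 1) T - 1L else T
  sd_bg_per_sigma <- sqrt(2 / N) * sqrt(2 - pi / 2) / sqrt(sweep$n_averages)
  (amp_surf / target_snr) / sd_bg_per_sigma
}
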