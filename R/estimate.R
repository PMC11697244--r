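#' Inversion configuration
#'
#' All knobs of the depth-sequential constrained inversion. The masking
#' multiple (Rose criterion, 5 standard deviations) and the optimizer
#' stopping rule (first-order optimality 1e-6) follow the analysis protocol;
#' the continuity and abruptness thresholds separate the smooth evolution of
#' the accumulated fluence term from genuine layer changes at the default
#' grid resolution and are all config-exposed.
#'
#' @param rose_k masking multiple: a pixel is masked when its H1 amplitude
#'   is below `rose_k` background standard deviations.
#' @param noise_sigma explicit background H1-amplitude standard deviation;
#'   NULL to measure it from `background_rows`.
#' @param background_rows depth rows of a tissue-free region used to
#'   measure the noise floor when `noise_sigma` is NULL.
#' @param beta_mode "per-column-surface" (beta fixed per column from that
#'   column's surface pixel) or "fixed-from-surface" (one global beta, the
#'   median of the per-column surface values).
#' @param continuity_alpha max |change in alpha| per depth step.
#' @param continuity_psi max |change in psi| per depth step, degrees.
#' @param continuity_phi max |change in phi| per depth step, degrees,
#'   unless a layer change releases the constraint.
#' @param abrupt_eta_thresh doubled-angle phase change (degrees) between
#'   adjacent depths flagged as abrupt.
#' @param abrupt_xi_relthresh relative modulation change flagged as abrupt.
#' @param alpha_beta_tie_tol relative tolerance for detecting alpha ~ beta
#'   (the cancellation point).
#' @param alpha_zero_tol absolute alpha level below which the fluence phase
#'   is treated as indeterminate and a 90-degree psi advance is tried.
#' @param optimality_tol projected-gradient (first-order optimality)
#'   stopping tolerance of the constrained minimizer.
#' @param max_iter optimizer iteration cap per pixel.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(rose_k = 5, noise_sigma = NULL, background_rows = NULL,
                       beta_mode = c("per-column-surface", "fixed-from-surface"),
                       continuity_alpha = 0.01, continuity_psi = 10,
                       continuity_phi = 2, abrupt_eta_thresh = 60,
                       abrupt_xi_relthresh = 0.2, alpha_beta_tie_tol = 0.1,
                       alpha_zero_tol = 0.01, optimality_tol = 1e-6,
                       max_iter = 200) {
  beta_mode <- match.arg(beta_mode)
  stopifnot(rose_k > 0, continuity_alpha > 0, continuity_psi > 0,
            continuity_phi > 0, abrupt_eta_thresh > 0,
            abrupt_xi_relthresh > 0, alpha_beta_tie_tol > 0,
            alpha_zero_tol > 0, optimality_tol > 0, max_iter >= 1)
  structure(list(rose_k = rose_k, noise_sigma = noise_sigma,
                 background_rows = background_rows, beta_mode = beta_mode,
                 continuity_alpha = continuity_alpha,
                 continuity_psi = continuity_psi,
                 continuity_phi = continuity_phi,
                 abrupt_eta_thresh = abrupt_eta_thresh,
                 abrupt_xi_relthresh = abrupt_xi_relthresh,
                 alpha_beta_tie_tol = alpha_beta_tie_tol,
                 alpha_zero_tol = alpha_zero_tol,
                 optimality_tol = optimality_tol,
                 max_iter = as.integer(max_iter)),
            class = "fit_config")
}

#' Rose-criterion validity mask
#'
#' A pixel is valid when its H1 amplitude is at least `rose_k` (default 5)
#' background standard deviations — the Rose detectability criterion — and
#' its mean pressure is positive. Exception: a pixel failing the amplitude
#' test is retained when it is a local minimum of H1 amplitude along depth
#' whose neighboring phases differ by ~180 degrees (doubled-angle domain):
#' that signature is the alpha ~ beta cancellation of the fluence and
#' absorption modulations, real signal rather than noise.
#'
#' @param spectral a `spectral_maps`.
#' @param cfg a `fit_config` supplying `rose_k`, the noise sigma source and
#'   `abrupt_eta_thresh` (the flip tolerance).
#' @return logical matrix, TRUE = valid.
#' @export
rose_mask <- function(spectral, cfg = fit_config()) {
  sigma <- cfg$noise_sigma
  if (is.null(sigma)) {
    if (is.null(cfg$background_rows))
      stop("no background noise level: supply noise_sigma or background_rows",
           call. = FALSE)
    sigma <- stats::sd(spectral$h1_amp[cfg$background_rows, ])
  }
  amp <- spectral$h1_amp
  eta <- spectral$h1_phase
  ok_signal <- is.finite(spectral$xi) & spectral$p_mean > 0
  valid <- ok_signal & amp >= cfg$rose_k * sigma
  nd <- nrow(amp)
  if (nd >= 3) {
    for (j in seq_len(ncol(amp))) {
      for (i in 2:(nd - 1)) {
        if (valid[i, j] || !ok_signal[i, j]) next
        # the flip must be read from signal-bearing neighbors: in pure
        # noise a local minimum with a ~180-degree phase difference is a
        # spurious coincidence, while a genuine cancellation dip sits
        # between detectable pixels
        if (amp[i - 1, j] < cfg$rose_k * sigma || amp[i + 1, j] < cfg$rose_k * sigma)
          next
        if (amp[i, j] <= amp[i - 1, j] && amp[i, j] <= amp[i + 1, j]) {
          flip <- abs(wrap_phase(eta[i + 1, j] - eta[i - 1, j]))
          if (is.finite(flip) && flip >= 180 - cfg$abrupt_eta_thresh)
            valid[i, j] <- TRUE
        }
      }
    }
  }
  valid
}

#' Inversion objective for one pixel
#'
#' Squared mismatch between the observed fundamental observables and the
#' two-tone model: eps = wrap(eta_obs - eta_model)^2 + (xi_obs - xi_model)^2,
#' with the phase residual wrapped on the doubled-angle circle and expressed
#' in radians so both terms share a common scale.
#'
#' @param alpha,psi,phi,beta model parameters (psi, phi in degrees).
#' @param eta_obs observed H1 phase, degrees (doubled-angle domain).
#' @param xi_obs observed normalized H1 amplitude.
#' @return the scalar objective eps >= 0 (0 iff the model reproduces the
#'   observations exactly).
#' @export
objective <- function(alpha, psi, phi, beta, eta_obs, xi_obs) {
  m <- h1_closed_form(alpha, beta, phi, psi)
  eta_m <- if (is.na(m$eta)) 0 else m$eta
  r_phase <- deg2rad(wrap_phase(eta_obs - eta_m))
  r_amp <- xi_obs - m$xi
  r_phase^2 + r_amp^2
}

# Objective and analytic gradient for the optimizer. par is c(alpha, psi,
# phi) in (dimensionless, deg, deg), or c(alpha, psi) when phi is fixed.
obj_fn <- function(par, beta, eta_obs, xi_obs, phi_fixed = NULL) {
  alpha <- par[1]; psi <- par[2]
  phi <- if (is.null(phi_fixed)) par[3] else phi_fixed
  p2 <- 2 * deg2rad(psi); f2 <- 2 * deg2rad(phi)
  S <- alpha * sin(p2) + beta * sin(f2)
  C <- alpha * cos(p2) + beta * cos(f2)
  R2 <- S^2 + C^2
  xi_m <- sqrt(R2)
  eta_m <- atan2(S, C)
  rp <- deg2rad(wrap_phase(eta_obs - rad2deg(eta_m)))
  ra <- xi_obs - xi_m
  rp^2 + ra^2
}

obj_gr <- function(par, beta, eta_obs, xi_obs, phi_fixed = NULL) {
  alpha <- par[1]; psi <- par[2]
  phi <- if (is.null(phi_fixed)) par[3] else phi_fixed
  p2 <- 2 * deg2rad(psi); f2 <- 2 * deg2rad(phi)
  S <- alpha * sin(p2) + beta * sin(f2)
  C <- alpha * cos(p2) + beta * cos(f2)
  R2 <- max(S^2 + C^2, 1e-24)
  xi_m <- sqrt(R2)
  eta_m <- atan2(S, C)
  rp <- deg2rad(wrap_phase(eta_obs - rad2deg(eta_m)))
  ra <- xi_obs - xi_m
  # partials of (S, C) wrt alpha and wrt psi/phi in radians
  dS <- c(sin(p2), 2 * alpha * cos(p2), 2 * beta * cos(f2))
  dC <- c(cos(p2), -2 * alpha * sin(p2), -2 * beta * sin(f2))
  d_eta <- (C * dS - S * dC) / R2        # d eta_m (rad) / d par_rad
  d_xi <- (S * dS + C * dC) / xi_m
  g <- -2 * rp * d_eta - 2 * ra * d_xi
  scale <- c(1, pi / 180, pi / 180)  # psi, phi supplied in degrees
  g <- g * scale
  if (is.null(phi_fixed)) g else g[1:2]
}

# Surface dichroism ratio. The continuous surface rule is beta = xi at
# z -> 0; the first depth cell's center already carries the half-cell
# accumulated fluence modulation, so when two adjacent valid surface pixels
# exist (with consistent phase) xi is extrapolated linearly to z = 0.
# Falls back to the first pixel's xi otherwise.
surface_beta <- function(xi, eta, idx, cfg) {
  i0 <- idx[1]
  if (length(idx) >= 2 && idx[2] == i0 + 1 &&
      abs(wrap_phase(eta[idx[2]] - eta[i0])) < cfg$abrupt_eta_thresh) {
    b <- xi[i0] + (xi[i0] - xi[idx[2]]) * (i0 - 0.5)
    if (b > 0) return(b)
  }
  xi[i0]
}

# Constrained fit of one pixel, boxed around the seed.
fit_pixel <- function(seed, box_lo, box_hi, beta, eta_obs, xi_obs, cfg,
                      fix_phi = FALSE) {
  phi_fixed <- if (fix_phi) seed[3] else NULL
  np <- if (fix_phi) 2L else 3L
  par <- pmin(pmax(seed[seq_len(np)], box_lo[seq_len(np)]), box_hi[seq_len(np)])
  res <- tryCatch(
    stats::optim(par, obj_fn, gr = obj_gr, method = "L-BFGS-B",
                 lower = box_lo[seq_len(np)], upper = box_hi[seq_len(np)],
                 control = list(pgtol = cfg$optimality_tol,
                                maxit = cfg$max_iter,
                                factr = 0),
                 beta = beta, eta_obs = eta_obs, xi_obs = xi_obs,
                 phi_fixed = phi_fixed),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  par_out <- if (fix_phi) c(res$par, seed[3]) else res$par
  list(par = par_out, value = res$value, converged = res$convergence %in% c(0L, 52L))
}

#' Depth-sequential inversion of one A-line
#'
#' Marches from the surface downward, recovering (phi, psi, alpha) per
#' depth with beta held fixed, by constrained minimization of the
#' [objective()] seeded from the previous depth. Four scenario rules drive
#' the march:
#' \describe{
#'   \item{S1 (surface)}{at the first valid pixel fluence modulation is
#'     negligible: phi = eta/2, beta = xi, alpha = 0, psi = phi + 90.}
#'   \item{S2 (continuity)}{alpha and psi may only change by the configured
#'     per-step amounts; phi stays near its previous value.}
#'   \item{S3 (cancellation)}{a ~180-degree doubled-angle phase flip while
#'     alpha ~ beta is the fluence term overtaking the absorption term:
#'     phi is held and only (alpha, psi) are refit. Separately, when the
#'     running alpha is near zero below the surface the fluence phase is
#'     indeterminate and may have advanced by 90 degrees; both psi branches
#'     are fitted and the lower objective wins (ties keep continuity).}
#'   \item{S4 (layer change)}{simultaneous abrupt changes of eta and xi
#'     signal a new optic-axis orientation: phi is re-seeded from the
#'     current eta/2 and its continuity box is released.}
#' }
#' A pixel whose constrained fit fails is masked and flagged; the march
#' continues from the last good state with continuity boxes widened
#' proportionally to the gap.
#'
#' @param xi_profile,eta_profile per-depth observables, surface first.
#' @param valid_profile logical validity per depth (from [rose_mask()]).
#' @param cfg a `fit_config`.
#' @param beta fixed dichroism ratio; NULL = take the surface xi.
#' @return list of per-depth vectors `phi`, `psi`, `alpha`, `beta` (the
#'   value used), `scenario` (0 masked/skipped, 1 surface, 2 continuity,
#'   3 cancellation hold, 4 layer change, 5 psi advanced), `objective`,
#'   and `valid` (validity after fit failures).
#' @export
estimate_aline <- function(xi_profile, eta_profile, valid_profile,
                           cfg = fit_config(), beta = NULL) {
  n <- length(xi_profile)
  stopifnot(length(eta_profile) == n, length(valid_profile) == n)
  phi <- psi <- alpha <- eps <- rep(NA_real_, n)
  scen <- integer(n)
  valid <- valid_profile & is.finite(xi_profile) & is.finite(eta_profile)
  idx <- which(valid)
  if (length(idx) == 0L)
    return(list(phi = phi, psi = psi, alpha = alpha, beta = NA_real_,
                scenario = scen, objective = eps, valid = valid))
  i0 <- idx[1]
  phi[i0] <- wrap_orientation(eta_profile[i0] / 2)
  if (is.null(beta)) beta <- surface_beta(xi_profile, eta_profile, idx, cfg)
  alpha[i0] <- max(0, beta - xi_profile[i0])
  psi[i0] <- phi[i0] + 90
  eps[i0] <- 0
  scen[i0] <- 1L
  # running (unwrapped) state
  st <- list(alpha = alpha[i0], psi = psi[i0], phi = phi[i0],
             eta = eta_profile[i0], xi = xi_profile[i0], i = i0)
  st2 <- NULL
  alpha_peak <- alpha[i0]
  for (i in idx[idx > i0]) {
    gap <- i - st$i
    eta_i <- eta_profile[i]; xi_i <- xi_profile[i]
    d_eta <- abs(wrap_phase(eta_i - st$eta))
    d_xi_rel <- abs(xi_i - st$xi) / max(abs(st$xi), 1e-12)
    # could alpha have reached beta since the last fitted pixel? Across a
    # masked run the fluence term keeps evolving, so the tie tolerance
    # grows with the gap
    tie <- abs(st$alpha - beta) <=
      cfg$alpha_beta_tie_tol * max(beta, 1e-12) +
      (gap - 1L) * cfg$continuity_alpha
    flip <- d_eta >= 180 - cfg$abrupt_eta_thresh
    # a layer-change event across a masked gap is only trusted when the new
    # pixel starts a contiguous valid run; an isolated above-threshold pixel
    # inside a masked region must not release the phi constraint
    corroborated <- gap == 1L || (i < n && valid[i + 1L])
    abrupt <- d_eta > cfg$abrupt_eta_thresh &&
      d_xi_rel > cfg$abrupt_xi_relthresh && corroborated

    a_lo <- max(0, st$alpha - gap * cfg$continuity_alpha)
    a_hi <- st$alpha + gap * cfg$continuity_alpha
    p_lo <- st$psi - gap * cfg$continuity_psi
    p_hi <- st$psi + gap * cfg$continuity_psi

    # Each candidate fit is two-stage: (alpha, psi) first with phi held at
    # its seed — within a layer the observables must be explainable by the
    # smoothly evolving fluence term alone — then a polish over all three
    # parameters with phi boxed. The anchor keeps the underdetermined
    # three-parameter problem from wandering along its zero-residual
    # manifold.
    two_stage <- function(seed, phi_lo, phi_hi, scen_code) {
      f1 <- fit_pixel(seed, c(a_lo, p_lo + seed[2] - st$psi),
                      c(a_hi, p_hi + seed[2] - st$psi), beta, eta_i, xi_i,
                      cfg, fix_phi = TRUE)
      seed2 <- if (!is.null(f1) && f1$converged) f1$par else seed
      f2 <- fit_pixel(seed2, c(a_lo, p_lo + seed[2] - st$psi, phi_lo),
                      c(a_hi, p_hi + seed[2] - st$psi, phi_hi), beta,
                      eta_i, xi_i, cfg)
      if (is.null(f2) || !f2$converged) f2 <- f1
      if (is.null(f2)) return(NULL)
      c(f2, scen = scen_code)
    }
    # offer the cancellation interpretation on a clean flip, and also on
    # any re-entry after a masked gap (the phase at the band edge is
    # noise-dominated, so the flip signature cannot be required there)
    s3_trig <- tie && (flip || gap > 1L)
    fits <- list()
    if (s3_trig) {
      # S3: hold phi, attribute the flip to the fluence term. When the
      # abruptness signature would also admit a layer change, both
      # interpretations are fitted and the objective decides (ties prefer
      # the cancellation branch: the fluence explanation is the
      # constrained one).
      f <- fit_pixel(c(st$alpha, st$psi, st$phi), c(a_lo, p_lo),
                     c(a_hi, p_hi), beta, eta_i, xi_i, cfg, fix_phi = TRUE)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- c(f, scen = 3L)
      # the continuity seed sits on the near side of the alpha = beta
      # amplitude null, which the optimizer cannot cross; also seed from
      # the closed-form (alpha, psi) that reproduces the observation with
      # phi held, which lies on the far side
      tv <- xi_i * exp(1i * deg2rad(eta_i)) - beta * exp(1i * deg2rad(2 * st$phi))
      if (Mod(tv) > 1e-12) {
        psB <- rad2deg(Arg(tv)) / 2
        psB <- st$psi + orientation_diff(psB, st$psi)
        fB <- fit_pixel(c(Mod(tv), psB, st$phi), c(a_lo, p_lo),
                        c(a_hi, p_hi), beta, eta_i, xi_i, cfg, fix_phi = TRUE)
        if (!is.null(fB)) fits[[length(fits) + 1L]] <- c(fB, scen = 3L)
      }
    }
    if (abrupt && !(s3_trig && length(fits) > 0 &&
                    min(vapply(fits, `[[`, numeric(1), "value")) < 1e-10)) {
      # S4: new layer; re-seed phi and release its box. The fluence term is
      # accumulated and cannot jump across a layer change, so the dichroic
      # contribution of the new layer is the observed fundamental vector
      # minus the previous fluence vector; its phase seeds phi. The fluence
      # vector is advanced by half the previous per-cell increment because
      # the cell straddling the boundary still accrues the old layer's
      # dichroism over its first half. When the previous alpha is
      # negligible this reduces to the surface rule phi = eta / 2.
      flu_prev <- st$alpha * exp(1i * deg2rad(2 * st$psi))
      flu_seed <- if (!is.null(st2) && st$i - st2$i == 1L && gap == 1L)
        flu_prev + 0.5 * (flu_prev - st2$alpha * exp(1i * deg2rad(2 * st2$psi)))
      else flu_prev
      resid <- xi_i * exp(1i * deg2rad(eta_i)) - flu_seed
      phi_seed <- if (Mod(resid) > 1e-9)
        wrap_orientation(rad2deg(Arg(resid)) / 2)
      else wrap_orientation(eta_i / 2)
      # keep the seed on the branch nearest the previous (unwrapped) phi
      phi_seed <- st$phi + orientation_diff(phi_seed, st$phi)
      f <- two_stage(c(st$alpha, st$psi, phi_seed),
                     phi_seed - 90, phi_seed + 90, 4L)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
    if (length(fits) == 0L || (!s3_trig && !abrupt)) {
      # S2: continuity march. The phi box does not widen with masked-gap
      # length: within a layer the optic axis is constant, and only a
      # layer-change event (S4) releases it.
      f_lo <- st$phi - cfg$continuity_phi
      f_hi <- st$phi + cfg$continuity_phi
      f <- two_stage(c(st$alpha, st$psi, st$phi), f_lo, f_hi, 2L)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
      if (st$alpha <= cfg$alpha_zero_tol && alpha_peak > cfg$alpha_zero_tol) {
        # the fluence term has returned to zero below the surface (the
        # accumulated integral passed through zero): its phase is
        # indeterminate and may have advanced by 90 deg
        f2 <- two_stage(c(st$alpha, st$psi + 90, st$phi), f_lo, f_hi, 5L)
        if (!is.null(f2)) fits[[length(fits) + 1L]] <- f2
      }
    }
    fits <- Filter(function(f) isTRUE(f$converged), fits)
    if (length(fits) == 0L) { valid[i] <- FALSE; next }
    vals <- vapply(fits, `[[`, numeric(1), "value")
    best <- fits[[which.min(vals + 1e-12 * (seq_along(vals) - 1))]]
    alpha[i] <- best$par[1]
    psi[i] <- best$par[2]
    phi[i] <- best$par[3]
    eps[i] <- best$value
    scen[i] <- best$scen
    alpha_peak <- max(alpha_peak, alpha[i])
    st2 <- st
    st <- list(alpha = alpha[i], psi = psi[i], phi = phi[i],
               eta = eta_i, xi = xi_i, i = i)
  }
  list(phi = wrap_orientation(phi), psi = ifelse(is.finite(psi), psi %% 180, NA_real_),
       alpha = alpha, beta = beta, scenario = scen, objective = eps,
       valid = valid)
}

#' Column-wise inversion of a whole B-scan
#'
#' Applies [estimate_aline()] independently to every lateral column
#' (estimation marches along the light path only; no lateral
#' regularization). Deterministic given inputs and configuration.
#'
#' @param spectral a `spectral_maps`.
#' @param valid logical validity mask (e.g. from [rose_mask()]); NULL to
#'   compute it from `cfg`.
#' @param cfg a `fit_config`.
#' @return object of class `estimate_maps` with matrices `phi_map` (deg,
#'   (-90, 90]), `psi_map` (deg, [0, 180)), `alpha_map`, `beta_map`,
#'   `valid`, `scenario_map`, `objective_map`, and `phi_interp` = NULL
#'   until [interpolate_masked()] is applied.
#' @export
estimate_image <- function(spectral, valid = NULL, cfg = fit_config()) {
  if (is.null(valid)) valid <- rose_mask(spectral, cfg)
  nd <- spectral$grid$n_depth; nl <- spectral$grid$n_lateral
  phi <- psi <- alpha <- beta <- eps <- matrix(NA_real_, nd, nl)
  scen <- matrix(0L, nd, nl)
  vout <- matrix(FALSE, nd, nl)
  beta_global <- NULL
  if (cfg$beta_mode == "fixed-from-surface") {
    surf_xi <- vapply(seq_len(nl), function(j) {
      i <- which(valid[, j] & is.finite(spectral$xi[, j]))[1]
      if (is.na(i)) NA_real_ else spectral$xi[i, j]
    }, numeric(1))
    beta_global <- stats::median(surf_xi, na.rm = TRUE)
  }
  for (j in seq_len(nl)) {
    r <- estimate_aline(spectral$xi[, j], spectral$h1_phase[, j], valid[, j],
                        cfg, beta = beta_global)
    phi[, j] <- r$phi; psi[, j] <- r$psi; alpha[, j] <- r$alpha
    beta[, j] <- r$beta; eps[, j] <- r$objective
    scen[, j] <- r$scenario; vout[, j] <- r$valid
  }
  structure(list(phi_map = phi, psi_map = psi, alpha_map = alpha,
                 beta_map = beta, valid = vout, scenario_map = scen,
                 objective_map = eps, phi_interp = NULL,
                 grid = spectral$grid, truth = spectral$truth,
                 config = cfg),
            class = "estimate_maps")
}

#' @export
print.estimate_maps <- function(x, ...) {
  cat("<estimate_maps> ", x$grid$n_depth, "x", x$grid$n_lateral,
      " pixels, ", sum(x$valid), " valid\n", sep = "")
  invisible(x)
}

#' Fill masked orientations by circular linear interpolation along depth
#'
#' Masked runs between valid pixels are filled by linear interpolation of
#' the doubled-angle unit vectors (safe across the +/-90 wrap) and
#' re-wrapped to (-90, 90]; runs touching the profile ends take the nearest
#' valid value.
#'
#' @param phi_map orientation matrix in degrees, or an `estimate_maps`.
#' @param valid logical validity matrix (ignored when `phi_map` is an
#'   `estimate_maps`, which carries its own).
#' @return filled orientation matrix; for an `estimate_maps` input, the
#'   object with `phi_interp` set.
#' @export
interpolate_masked <- function(phi_map, valid = NULL) {
  if (inherits(phi_map, "estimate_maps")) {
    est <- phi_map
    est$phi_interp <- interpolate_masked(est$phi_map, est$valid)
    return(est)
  }
  stopifnot(is.matrix(phi_map), is.matrix(valid))
  out <- phi_map
  nd <- nrow(phi_map)
  for (j in seq_len(ncol(phi_map))) {
    known <- which(valid[, j] & is.finite(phi_map[, j]))
    if (length(known) == 0L) { out[, j] <- NA_real_; next }
    out[, j] <- interp_orientation(known, phi_map[known, j], seq_len(nd))
  }
  out
}
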