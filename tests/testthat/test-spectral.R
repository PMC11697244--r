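# Build a sweep stack directly from a per-pixel signal function of theta.
synthetic_stack <- function(f, nd = 2, nl = 2, sweep = sweep_config()) {
  thetas <- seq(sweep$theta_start, sweep$theta_end, sweep$theta_step)
  data <- array(0, dim = c(nd, nl, length(thetas)))
  for (t in seq_along(thetas)) data[, , t] <- f(thetas[t])
  structure(list(data = data, thetas = thetas,
                 energies = rep(1, length(thetas)),
                 grid = grid_spec(nd, nl, 0.01, 0.03), truth = NULL,
                 mode = "approx"),
            class = "sweep_stack")
}

test_that("demodulation recovers a single tone exactly", {
  st <- synthetic_stack(function(th) 1 + 0.1 * cos(2 * (th * pi / 180) - 80 * pi / 180))
  sp <- polarization_spectrum(st)
  expect_equal(sp$n_samples, 108L)
  expect_equal(sp$n_cycles, 6L)
  expect_equal(sp$p_mean[1, 1], 1, tolerance = 1e-12)
  expect_equal(sp$h1_amp[1, 1], 0.1, tolerance = 1e-12)
  expect_equal(sp$h1_phase[1, 1], 80, tolerance = 1e-9)
  expect_equal(sp$h2_amp[1, 1], 0, tolerance = 1e-12)
  expect_equal(sp$xi[1, 1], 0.1, tolerance = 1e-12)
})

test_that("demodulation agrees with a least-squares tone oracle", {
  f <- function(th) 2 * (1 + 0.2 * cos(2 * th * pi / 180 - 240 * pi / 180)) *
    (1 + 0.05 * cos(2 * th * pi / 180 - 60 * pi / 180))
  st <- synthetic_stack(f)
  sp <- polarization_spectrum(st)
  thetas <- st$thetas[1:108]
  y <- sapply(thetas, f)
  o1 <- oracle_tone(y, thetas, harmonic = 1)
  expect_equal(sp$h1_amp[1, 1], o1$amp, tolerance = 1e-9)
  expect_equal(sp$h1_phase[1, 1], wrap_phase(o1$delta), tolerance = 1e-7)
  o2 <- oracle_tone(y, thetas, harmonic = 2)
  expect_equal(sp$h2_amp[1, 1], o2$amp, tolerance = 1e-9)
  expect_equal(orientation_diff(sp$h2_phase[1, 1], o2$delta / 2), 0,
               tolerance = 1e-7)
})

test_that("the product signal produces the predicted second harmonic", {
  alpha <- 0.2; beta <- 0.05; phi <- 30; psi <- 120; pbar <- 1
  f <- function(th) {
    t2 <- 2 * th * pi / 180
    pbar * (1 + alpha * cos(t2 - 2 * psi * pi / 180)) *
      (1 + beta * cos(t2 - 2 * phi * pi / 180))
  }
  sp <- polarization_spectrum(synthetic_stack(f))
  # H2 amplitude = pbar * alpha * beta / 2, phase = phi + psi (mod 180)
  expect_equal(sp$h2_amp[1, 1], pbar * alpha * beta / 2, tolerance = 1e-12)
  expect_equal(orientation_diff(sp$h2_phase[1, 1], phi + psi), 0,
               tolerance = 1e-9)
  # DC carries the documented alpha*beta/2 interaction bias
  expect_equal(sp$p_mean[1, 1],
               pbar * (1 + alpha * beta * cos(2 * (phi - psi) * pi / 180) / 2),
               tolerance = 1e-12)
})

test_that("equal counter-phase modulations cancel the fundamental", {
  alpha <- 0.05; beta <- 0.05; phi <- 30; psi <- 120
  f <- function(th) {
    t2 <- 2 * th * pi / 180
    (1 + alpha * cos(t2 - 2 * psi * pi / 180)) *
      (1 + beta * cos(t2 - 2 * phi * pi / 180))
  }
  sp <- polarization_spectrum(synthetic_stack(f))
  expect_lt(sp$h1_amp[1, 1], 1e-12)
})

test_that("closed-form H1 observables reduce correctly in the limits", {
  expect_equal(h1_closed_form(0, 0.07, 25, 60),
               list(xi = 0.07, eta = 50), tolerance = 1e-12)
  expect_equal(h1_closed_form(0.12, 0, 25, 60),
               list(xi = 0.12, eta = 120), tolerance = 1e-12)
  r <- h1_closed_form(0.1, 0.05, 0, 90)
  expect_equal(r$xi, 0.05, tolerance = 1e-12)
  expect_equal(r$eta, 180, tolerance = 1e-9)
  # indeterminate cancellation point
  r0 <- h1_closed_form(0.05, 0.05, 0, 90)
  expect_equal(r0$xi, 0, tolerance = 1e-12)
  expect_true(is.na(r0$eta))
})

test_that("H1 phase is sigmoid in alpha/beta between the two asymptotes", {
  phi <- 10; psi <- 70; beta <- 0.05
  ratios <- 10^seq(-3, 3, length.out = 41)
  eta <- sapply(ratios, function(r) h1_closed_form(r * beta, beta, phi, psi)$eta)
  expect_true(all(diff(eta) > 0))
  expect_equal(eta[1], 2 * phi, tolerance = 0.1)
  expect_equal(eta[41], 2 * psi, tolerance = 0.1)
})

test_that("demodulated observables equal the closed form on simulated stacks", {
  for (nm in c("single", "stacked_perpendicular", "stacked_30deg")) {
    ph <- tendon_presets(nm, phi1 = 25)
    st <- acquire_sweep(ph, sweep_config(), noise_config(), mode = "approx")
    sp <- polarization_spectrum(st)
    f <- dspai:::forward_fields(ph, 5)
    tissue <- which(is.finite(ph$phi_map) & f$alpha > 1e-6)
    model <- h1_closed_form(f$alpha[tissue], f$beta[tissue],
                            ph$phi_map[tissue], dspai:::rad2deg(f$psi2[tissue]) / 2)
    xi_meas <- sp$h1_amp[tissue] / f$pbar[tissue]
    expect_equal(xi_meas, model$xi, tolerance = 1e-6)
    dphase <- wrap_phase(sp$h1_phase[tissue] - model$eta)
    expect_lt(max(abs(dphase[model$xi > 1e-4])), 1e-6)
  }
})

test_that("component powers satisfy Parseval for a noiseless three-tone signal", {
  f <- function(th) {
    t2 <- 2 * th * pi / 180
    1.5 * (1 + 0.3 * cos(t2 - 1)) * (1 + 0.05 * cos(t2 - 2))
  }
  st <- synthetic_stack(f)
  sp <- polarization_spectrum(st)
  y <- sapply(st$thetas[1:108], f)
  total_power <- mean(y^2)
  comp_power <- sp$p_mean[1, 1]^2 + sp$h1_amp[1, 1]^2 / 2 + sp$h2_amp[1, 1]^2 / 2
  expect_equal(comp_power, total_power, tolerance = 1e-12)
})

test_that("energy correction divides out recorded jitter exactly", {
  ph <- tendon_presets("single", phi1 = 10, thickness = 0.12,
                       grid = grid_spec(16, 2, 0.01, 0.03))
  clean <- acquire_sweep(ph, sweep_config(), noise_config())
  jit <- acquire_sweep(ph, sweep_config(), noise_config(0, 0.05, seed = 3))
  fixed <- energy_correct(jit)
  expect_equal(fixed$data, clean$data, tolerance = 1e-12)
  expect_true(all(fixed$energies == 1))
  unch <- energy_correct(clean)
  expect_equal(unch$data, clean$data)
  bad <- jit; bad$energies[4] <- -1
  expect_error(energy_correct(bad), "positive")
})

test_that("jitter plus correction leaves the phase map within noise tolerance", {
  ph <- tendon_presets("single", phi1 = 40, thickness = 0.12,
                       grid = grid_spec(16, 2, 0.01, 0.03))
  sig <- calibrate_additive_sigma(ph, sweep_config(), 100)
  ref <- polarization_spectrum(energy_correct(
    acquire_sweep(ph, sweep_config(), noise_config(sig, 0, seed = 11))))
  jit <- polarization_spectrum(energy_correct(
    acquire_sweep(ph, sweep_config(), noise_config(sig, 0.05, seed = 11))))
  d <- wrap_phase(jit$h1_phase[1:8, ] - ref$h1_phase[1:8, ])
  expect_lt(max(abs(d)), 5)
})

test_that("invalid sweeps for demodulation are rejected", {
  st <- synthetic_stack(function(th) 1 + cos(2 * th * pi / 180))
  st$thetas[5] <- st$thetas[5] + 1
  expect_error(polarization_spectrum(st), "uniform")
  st2 <- synthetic_stack(function(th) 1, sweep = sweep_config(0, 1080, 120))
  expect_error(polarization_spectrum(st2), "90")
})
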