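test_that("polarization-dependent absorption follows the dichroism law", {
  ph <- build_layered_phantom(layer_spec(0.3, 5, 0.5, 0),
                              grid_spec(40, 4, 0.01, 0.03))
  expect_equal(absorption_at(ph, c(1, 1), theta = 0), 5.25)
  expect_equal(absorption_at(ph, c(1, 1), theta = 45), 5.0)
  expect_equal(absorption_at(ph, c(1, 1), theta = 90), 4.75)
  # convention flag flips the sign of the dichroic term
  expect_equal(absorption_at(ph, c(1, 1), theta = 0,
                             convention = "extraordinary-aligned"), 4.75)
  expect_error(absorption_at(ph, c(99, 1), theta = 0), "outside")
})

test_that("exact fluence is Beer-Lambert in an isotropic absorber", {
  ph <- build_layered_phantom(layer_spec(0.35, 5, 0, NA),
                              grid_spec(40, 4, 0.01, 0.03))
  z <- depth_centers(ph$grid)
  for (theta in c(0, 30, 120)) {
    f <- fluence_exact(ph, theta, F0 = 1)
    expect_equal(f[1:35, 1], exp(-5 * z[1:35]), tolerance = 1e-12)
  }
})

test_that("exact fluence matches the analytic layered oracle with dichroism", {
  layers <- list(layer_spec(0.12, 5, 0.5, 30), layer_spec(0.12, 4, 0.4, -45))
  ph <- build_layered_phantom(layers, grid_spec(30, 3, 0.01, 0.03))
  z <- depth_centers(ph$grid)
  for (theta in c(0, 30, 75)) {
    f <- fluence_exact(ph, theta, F0 = 2)
    oracle <- sapply(z, function(zz) 2 * exp(-oracle_attenuation(layers, zz, theta)))
    # trapezoid smears one cell at the layer boundary; compare away from it
    keep <- abs(z - 0.12) > 0.011
    expect_equal(f[keep, 2], oracle[keep], tolerance = 1e-10)
  }
  # at theta = phi the top layer attenuates with mu_a,o = 5.25
  f0 <- fluence_exact(ph, 30, F0 = 1)
  expect_equal(f0[10, 1], exp(-5.25 * z[10]), tolerance = 1e-12)
})

test_that("truncated fluence carries the closed-form accumulated modulation", {
  ph <- build_layered_phantom(layer_spec(0.3, 5, 0.5, 30),
                              grid_spec(40, 4, 0.01, 0.03))
  z <- depth_centers(ph$grid)
  fa <- fluence_approx(ph, theta = 30, F0 = 1)
  expect_equal(fa$alpha[1:30, 1], 0.25 * z[1:30], tolerance = 1e-12)
  expect_equal(fa$psi[1:30, 1], rep(120, 30), tolerance = 1e-10)
  # at theta = phi the modulation is -alpha
  expect_equal(fa$fluence[1:30, 1],
               exp(-5 * z[1:30]) * (1 - 0.25 * z[1:30]), tolerance = 1e-12)
  # without dichroism the truncation is exact
  ph0 <- build_layered_phantom(layer_spec(0.3, 5, 0, NA),
                               grid_spec(40, 4, 0.01, 0.03))
  fa0 <- fluence_approx(ph0, theta = 10, F0 = 1)
  expect_equal(fa0$alpha, matrix(0, 40, 4))
  expect_equal(fa0$fluence, fluence_exact(ph0, 10, F0 = 1), tolerance = 1e-12)
})

test_that("perpendicular layers cancel the accumulated dichroic integral", {
  layers <- list(layer_spec(0.1, 5, 0.5, 0), layer_spec(0.1, 5, 0.5, 90))
  ph <- build_layered_phantom(layers, grid_spec(22, 3, 0.01, 0.03))
  z <- depth_centers(ph$grid)
  fa <- fluence_approx(ph, 0, F0 = 1)
  oracle <- sapply(z, function(zz) Mod(oracle_dichroic(layers, zz)))
  keep <- abs(z - 0.1) > 0.011 & z < 0.2
  expect_equal(fa$alpha[keep, 1], oracle[keep], tolerance = 1e-10)
  # the integral returns to (numerically) zero at the bottom of layer 2
  expect_lt(fa$alpha[20, 1], 2e-3)
  expect_gt(fa$alpha[10, 1], 0.02)
})

test_that("approx-mode pressure equals the product form", {
  ph <- tendon_presets("single", phi1 = 30)
  f <- fluence_approx(ph, 40, F0 = 5)
  beta <- ph$delta_mu_a_map / (2 * pmax(ph$mu_a_mean_map, 1e-12))
  p <- pressure_map(ph, 40, F0 = 5, mode = "approx")
  pbar <- ph$mu_a_mean_map * 5 * exp(-dspai:::cumtrapz_depth(ph$mu_a_mean_map, 0.01))
  prod_form <- pbar * (1 + f$alpha * cos(2 * (40 - f$psi) * pi / 180)) *
    (1 + beta * cos(2 * (40 - ph$phi_map) * pi / 180))
  tissue <- is.finite(ph$phi_map)
  expect_equal(p[tissue], prod_form[tissue], tolerance = 1e-12)
  # surface pixel: alpha ~ 0, so p(theta)/pbar ~ 1 + beta cos 2(theta - phi)
  r <- sapply(seq(0, 170, 10), function(th)
    pressure_map(ph, th, F0 = 5)[1, 1]) / pbar[1, 1]
  expect_equal(r, 1 + 0.05 * cos(2 * (seq(0, 170, 10) - 30) * pi / 180),
               tolerance = 2e-3)
})

test_that("alpha equals beta at the inverse-attenuation depth", {
  ph <- tendon_presets("single", phi1 = 10)  # mu_a_mean 5 -> 1/mu = 0.2 cm
  f <- fluence_approx(ph, 0, F0 = 5)
  beta <- 0.05
  cross <- which(f$alpha[, 1] >= beta)[1]
  z <- depth_centers(ph$grid)
  expect_lte(abs(z[cross] - 0.2), ph$grid$dz)
  # pressure is 180-deg periodic in polarization
  expect_equal(pressure_map(ph, 37), pressure_map(ph, 37 + 180), tolerance = 1e-12)
  # fluence decreases strictly with depth inside tissue
  fe <- fluence_exact(ph, 12)
  expect_true(all(diff(fe[1:32, 1]) < 0))
})

test_that("truncation error scales quadratically with dichroism", {
  errs <- sapply(c(0.5, 0.25, 0.125), function(dmu) {
    ph <- build_layered_phantom(layer_spec(0.3, 5, dmu, 30),
                                grid_spec(40, 2, 0.01, 0.03))
    mx <- 0
    for (th in seq(0, 170, 30)) {
      fe <- fluence_exact(ph, th)
      fa <- fluence_approx(ph, th)$fluence
      mx <- max(mx, max(abs(fa - fe) / fe))
    }
    mx
  })
  expect_gt(errs[1] / errs[2], 3.5)
  expect_lt(errs[1] / errs[2], 4.5)
  expect_gt(errs[2] / errs[3], 3.5)
  expect_lt(errs[2] / errs[3], 4.5)
})

test_that("sweep acquisition honours protocol, determinism and noise settings", {
  expect_equal(n_acquisitions(sweep_config()), 109L)
  expect_error(sweep_config(0, 100, 7), "integer")
  ph <- tendon_presets("single", phi1 = 20, thickness = 0.15,
                       grid = grid_spec(20, 4, 0.01, 0.03))
  clean <- acquire_sweep(ph, sweep_config(), noise_config())
  expect_equal(dim(clean$data), c(20, 4, 109))
  expect_equal(clean$data[, , 5], pressure_map(ph, clean$thetas[5]),
               tolerance = 1e-12)
  n1 <- acquire_sweep(ph, sweep_config(), noise_config(0.01, 0.05, seed = 7))
  n2 <- acquire_sweep(ph, sweep_config(), noise_config(0.01, 0.05, seed = 7))
  expect_identical(n1$data, n2$data)
  expect_identical(n1$energies, n2$energies)
  n3 <- acquire_sweep(ph, sweep_config(), noise_config(0.01, 0.05, seed = 8))
  expect_false(identical(n1$data, n3$data))
  expect_equal(mean(n1$energies), 1, tolerance = 0.02)
})

test_that("effective attenuation substitution only affects the fluence decay", {
  ph <- tendon_presets("single", phi1 = 0, thickness = 0.2,
                      grid = grid_spec(20, 2, 0.01, 0.03))
  f0 <- fluence_exact(ph, 0, F0 = 1)
  f1 <- fluence_exact(ph, 0, F0 = 1, mus_prime = 10)
  z <- depth_centers(ph$grid)
  expect_equal(f1[1:20, 1], f0[1:20, 1] * exp(-10 * z[1:20]), tolerance = 1e-12)
  # local absorption in the pressure is unchanged: ratio p1/p0 = fluence ratio
  p0 <- pressure_map(ph, 0, mode = "exact")
  p1 <- pressure_map(ph, 0, mode = "exact", mus_prime = 10)
  expect_equal(p1[5, 1] / p0[5, 1], exp(-10 * z[5]), tolerance = 1e-12)
})
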