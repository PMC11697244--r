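# Shared fixtures: small phantoms and a closed-form layered Beer-Lambert
# oracle, independent of the package's grid-trapezoid integrator.

default_sweep <- function() sweep_config()

# Analytic cumulative absorption integral for a stack of homogeneous
# layers: integral_0^z mu(theta) dz' with exact layer boundaries.
oracle_attenuation <- function(layers, z, theta) {
  lo <- 0
  total <- 0
  for (l in layers) {
    hi <- lo + l$thickness
    seg <- max(0, min(z, hi) - lo)
    if (seg > 0) {
      mu <- l$mu_a_mean
      if (is.finite(l$phi))
        mu <- mu + l$delta_mu_a / 2 * cos(2 * (theta - l$phi) * pi / 180)
      total <- total + mu * seg
    }
    lo <- hi
  }
  total
}

# Accumulated dichroic integral (complex) for layered media, exact.
oracle_dichroic <- function(layers, z) {
  lo <- 0
  acc <- 0 + 0i
  for (l in layers) {
    hi <- lo + l$thickness
    seg <- max(0, min(z, hi) - lo)
    if (seg > 0 && is.finite(l$phi))
      acc <- acc + l$delta_mu_a / 2 * exp(2i * l$phi * pi / 180) * seg
    lo <- hi
  }
  acc
}

# Least-squares single-tone extraction: independent oracle for the FFT
# demodulator (regression on cos/sin regressors).
oracle_tone <- function(y, thetas_deg, harmonic = 1) {
  w <- 2 * harmonic * thetas_deg * pi / 180
  fit <- stats::lm(y ~ cos(w) + sin(w))
  co <- stats::coef(fit)
  amp <- sqrt(co[2]^2 + co[3]^2)
  # y ~ A cos(w - delta): cos coefficient A cos(delta), sin coef A sin(delta)
  delta <- atan2(co[3], co[2]) * 180 / pi
  list(dc = unname(co[1]), amp = unname(amp), delta = unname(delta))
}
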