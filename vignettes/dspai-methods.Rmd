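---
title: "Depth-resolved fiber orientation from dichroism-sensitive photoacoustics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved fiber orientation from dichroism-sensitive photoacoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspai)
```

## The physical model

Fibrous tissues with a dominant uniaxial fiber direction — tendon is the
canonical example, through its aligned collagen — absorb linearly polarized
light anisotropically. With the optic axis at orientation $\phi$ (a
director, defined modulo 180°) and polarization angle $\theta$, the
absorption coefficient is

$$\mu_a(\theta) = \bar\mu_a + \tfrac{\Delta\mu_a}{2}\cos 2(\theta - \phi),$$

where $\bar\mu_a = (\mu_{a,o} + \mu_{a,e})/2$ is the mean of the ordinary
and extraordinary coefficients and $\Delta\mu_a = \mu_{a,o} - \mu_{a,e}$
is the linear dichroism. The photoacoustic initial pressure at a pixel is
$p = \Gamma\eta_{th}\,F\,\mu_a$, so sweeping the polarization modulates
the signal with period 180°.

At depth, a second modulation appears: the fluence
$F = F_0 e^{-\int_\ell \mu_a\,dz}$ along a scattering-free ballistic ray
accumulates the dichroism of all overlying tissue. Expanding the dichroic
part of the exponent to first order (valid while the accumulated integral
is small) gives the product model

$$p = \bar p\,\bigl(1 + \alpha\cos(2\theta - 2\psi)\bigr)\,
       \bigl(1 + \beta\cos(2\theta - 2\phi)\bigr),$$

with $\beta = \Delta\mu_a/(2\bar\mu_a)$ the local dichroism ratio and
$(\alpha, \psi)$ the amplitude and phase of the accumulated fluence
modulation. We keep $\alpha \ge 0$ and absorb the expansion's minus sign
into $\psi$, writing $2\psi = \arg(-C)$ for the accumulated complex
integral $C(z) = \int_0^z \tfrac{\Delta\mu_a}{2} e^{i2\phi}\,dz'$; a
homogeneous layer then satisfies $\psi = \phi + 90°$ — fluence and
absorption modulations in counter-phase.

Expanding the product yields three spectral components in the sweep: DC,
the fundamental H1 at $\cos 2\theta$, and a second harmonic H2 at
$\cos 4\theta$ with amplitude $\bar p\,\alpha\beta/2$ and doubled-angle
phase $2(\phi + \psi)$. The normalized H1 observables are

$$\xi = \sqrt{\alpha^2 + \beta^2 + 2\alpha\beta\cos 2(\phi - \psi)},\qquad
  \eta = \operatorname{atan2}\!\bigl(\alpha\sin 2\psi + \beta\sin 2\phi,\;
  \alpha\cos 2\psi + \beta\cos 2\phi\bigr).$$

$\eta$ behaves like a sigmoid in $\alpha/\beta$ between the absorption
asymptote $2\phi$ and the fluence asymptote $2\psi$. In a homogeneous
sample the two terms are in counter-phase, so the raw H1 phase sits at
$2\phi$ near the surface, the amplitude collapses where $\alpha = \beta$,
and the phase flips by 90° of orientation at a depth approximately equal
to $1/\bar\mu_a$. This flip is an artifact of fluence build-up, not a
change of fiber orientation — correcting it is the purpose of the
inversion.

## What the simulator emulates, and what it does not

`acquire_sweep()` reproduces the acquisition protocol: polarization swept
0°–1080° (three half-wave-plate revolutions) in 10° steps — 109 frames —
with 40-frame averaging, per-shot pulse-energy jitter recorded for later
correction, and additive Gaussian noise. Averaging is simulated as
noise-variance reduction (one draw with $\sigma/\sqrt{n}$), which is
distributionally identical to storing and averaging frames. Energy jitter
multiplies whole frames, matching a global pulse-energy fluctuation.

The tendon presets use a mean absorption of 5 cm⁻¹ and dichroism ratio
$\Delta\mu_a/\bar\mu_a = 0.1$. The ratio is what tendon optics at 532 nm
constrains; the absolute scale is an assumption chosen so the predicted
phase-flip depth $1/\bar\mu_a = 2$ mm lies inside the imaged depth, and it
is overridable in every constructor. Stacked presets use two 0.16 cm
layers (spanning 3.2 mm); the single-tendon preset uses one 0.32 cm layer
so the flip depth falls inside the tissue. The default grid is 40 × 16
cells of 0.01 cm (depth) × 0.03 cm (lateral) — finer than the 0.3 mm
axial resolution of the physical system, so discretization does not
dominate any tested behavior. These sizes keep a full simulate–recover
cycle under a second and the whole 13-phantom noise experiment under a
minute on one CPU.

Not modelled: scattering and depolarization (an effective-attenuation
substitution $\mu_a \to \mu_a + \mu_s'$ in the fluence decay is available
as a switch, default off), refraction and reflection losses at water–tissue
interfaces (water gaps only attenuate by absorbing nothing), acoustic
propagation, transducer bandwidth and beamforming, and speckle. Passing
tests on these phantoms therefore demonstrates correctness of the
signal-model inversion, not robustness to every artifact of real scans;
deep regions of real data will degrade sooner than the simulation
suggests, exactly as scattering-free theory predicts.

## Demodulation choices

`polarization_spectrum()` takes an FFT per pixel across the sweep. When
the end angle duplicates the start modulo 180° (0°–1080° inclusive), the
last sample is dropped so the window holds an integer number (6) of
modulation periods; the harmonic bins are then leakage-free, which beats
any window correction at these sample counts. Phases are stored in the
doubled-angle convention — the fitted component is $A\cos(2\theta-\delta)$
— wrapped to (−180°, 180°]; the H2 phase is stored halved, comparable to
$\phi + \psi$ modulo 180°. $\bar p$ is estimated by the DC term, which
carries a known interaction bias of relative size $\alpha\beta/2$
(≤ 4% at the deepest fluence modulations considered); it is documented
rather than corrected, since the estimator consumes the ratio
$\xi = $ H1/DC whose bias is second-order in the residual.

## The depth-sequential inversion

Per pixel the model has three unknowns $(\phi, \psi, \alpha)$ (with
$\beta$ held fixed — tendon dichroism is homogeneous to good
approximation) against two observables $(\xi, \eta)$: an underdetermined
problem whose zero-residual solutions form a one-parameter family. The
estimator resolves the ambiguity with physics: fluence evolves
continuously along the light path, while the optic axis is piecewise
constant. `estimate_aline()` marches from the surface down, minimizing

$$\varepsilon = \operatorname{wrap}(\eta_{obs} - \eta_{model})^2
  + (\xi_{obs} - \xi_{model})^2$$

(phase residual wrapped on the doubled-angle circle and taken in radians so
both terms share a scale) with L-BFGS-B under box constraints, stopping at
projected-gradient 1e-6. Four rules drive the march:

* **Surface.** At the first valid pixel fluence modulation is negligible:
  $\phi = \eta/2$, $\beta = \xi$, $\alpha \approx 0$, $\psi = \phi + 90°$.
  On a grid, the first cell center already carries half a cell of
  accumulated fluence, so $\beta$ is obtained by extrapolating $\xi$
  linearly to $z = 0$ from the two topmost valid pixels and the initial
  $\alpha$ is set to $\beta - \xi_1$; this is the same surface rule,
  evaluated where it actually holds.
* **Continuity.** $\alpha$ and $\psi$ may change by at most
  `continuity_alpha` (0.01) and `continuity_psi` (10°) per depth step
  (scaled across masked gaps); $\phi$ stays within `continuity_phi` (2°)
  of its previous value, *not* scaled across gaps — the axis is constant
  within a layer. Each fit is two-stage: $(\alpha, \psi)$ first with
  $\phi$ held, then a three-parameter polish with $\phi$ boxed. The
  anchor stops the underdetermined fit from drifting along its
  zero-residual manifold, which otherwise accumulates several degrees of
  $\phi$ error per layer.
* **Cancellation.** A ~180° doubled-angle flip while $\alpha$ is within
  `alpha_beta_tie_tol` of $\beta$ (the tolerance widened by
  `continuity_alpha` per masked cell, since $\alpha$ keeps evolving where
  nothing was fitted) is the fluence term overtaking the absorption term:
  $\phi$ is held and only $(\alpha, \psi)$ refit. Two seeds are used —
  the previous state and the closed-form $(\alpha, \psi)$ solving the
  observation with $\phi$ held — because the amplitude null at
  $\alpha = \beta$ is a ridge the optimizer cannot cross from one side.
  Separately, if $\alpha$ returns to ~0 below the surface (the
  accumulated integral passing through zero, as between perpendicular
  layers), $\psi$ is indeterminate and may have advanced by 90°; both
  $\psi$ branches are fitted and the lower objective wins, ties keeping
  continuity. This branch only arms after $\alpha$ has actually left
  zero (a high-water mark), so it cannot fire during the initial growth.
* **Layer change.** Simultaneous abrupt changes of $\eta$
  (> `abrupt_eta_thresh` = 60°) and relative $\xi$ (> 0.2) signal a new
  orientation: $\phi$ is re-seeded and released. Because the fluence
  vector cannot jump, the new layer's dichroic contribution is the
  observed H1 vector minus the extrapolated fluence vector; its phase is
  the $\phi$ seed (reducing to $\eta/2$ at the surface). The fluence
  vector is advanced by half the previous per-cell increment, since the
  cell straddling the boundary accrues the old layer's dichroism over its
  first half. Across masked gaps the event must be corroborated by the
  next pixel being valid — an isolated above-threshold pixel inside a
  masked band must not release $\phi$.

The abruptness thresholds, tie tolerance and per-step continuity bounds
are not physical constants; they separate smooth fluence evolution from
layer changes at the default grid resolution and are all exposed in
`fit_config()`. $\beta$ defaults to a per-column surface estimate
(tolerating lateral inhomogeneity); a single global surface median is
available as `beta_mode = "fixed-from-surface"`.

Masking uses the Rose criterion: pixels whose H1 amplitude is below 5
background standard deviations are untrustworthy, except a local amplitude
minimum flanked by a ~180° phase flip — the cancellation signature — which
is kept. The flip must be read from neighbors that themselves pass the
amplitude rule; in pure noise the min-plus-flip coincidence is common, and
without that requirement noise pixels deep in the masked band would enter
the estimate. Masked orientations are filled afterwards by linear
interpolation of doubled-angle unit vectors along depth (safe across the
±90° wrap; chord interpolation deviates from angular linearity only at
second order within a run), with nearest-value fill at profile ends.

## Numerical choices and degenerate inputs

Line integrals use cumulative trapezoids at grid resolution, with the
half-cell from the surface treated as a rectangle — exact for
piecewise-constant columns away from layer boundaries, and smearing one
cell at a boundary. Water pixels carry $\bar\mu_a = \Delta\mu_a = 0$ and
an undefined orientation (NA) excluded from every statistic; their mean
pressure is exactly zero, which the mask treats as invalid. The phase of
a vanishing harmonic is reported NA. A pixel whose constrained fit fails
to converge is masked and flagged, and the march continues from the last
good state. All angle reporting is in degrees: $\phi$ in (−90°, 90°],
$\psi$ in [0°, 180°) so the homogeneous counter-phase relation reads
$\psi = \phi + 90°$ without wrapping.

One known residual: in the 30°-stack preset separated by a water gap, the
boundary-straddle extrapolation cannot be applied across the gap and the
recovered lower-layer orientation carries a constant offset of about
0.7°; at the default gap-free presets the recovery is exact to better
than 0.02°.

## Circular statistics and error metrics

Orientations are directors, so all averaging happens on doubled angles:
`orientation_histogram()` reports the circular mean and standard deviation
via the resultant of $e^{i2\phi}$ (undefined and flagged when the
resultant vanishes, e.g. equal mass at perpendicular orientations), and
`angular_error()` wraps per-pixel differences to (−90°, 90°] before the
root-mean-square — 89° versus −89° is a 2° error.

The packaged noise experiment (13 single-tendon phantoms at −90°…90° in
15° steps) calibrates the additive noise so the surface H1 amplitude is
20 times the background amplitude noise floor, derived in closed form
from the Rayleigh statistics of the demodulated background. Under those
conditions the pooled orientation RMSE over unmasked tissue pixels is
between about 2.4° and 2.8° across seeds — the reference single-tendon
error of 3.97° from real scans bounds it. Pixels beyond the cancellation
band are mostly masked at that SNR, so the pool is dominated by the upper
two millimeters; that mirrors what the masking rule is for.
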