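# dspai — dichroism-sensitive photoacoustic imaging at depth

Polarization-swept photoacoustic (DS-PA) imaging reads the fiber
architecture of anisotropic tissue: collagen-rich structures such as
tendon absorb linearly polarized light differently along and across their
fibers (linear dichroism), so sweeping the illumination polarization
modulates the photoacoustic amplitude with a phase tied to the optic-axis
orientation. Near the surface that works directly — but at depth the
*fluence* itself becomes polarized-modulated by all the dichroic tissue
above, and eventually overwhelms the local absorption signature, flipping
the apparent orientation by 90°. `dspai` is for researchers developing or
evaluating depth-resolved DS-PA orientation imaging: it provides a forward
simulator for the full physics and a model-based inversion that untangles
the two modulations to recover the true fiber map.

## Model

With polarization angle θ and optic axis φ, absorption follows
μₐ(θ) = μ̄ₐ + (Δμₐ/2)cos 2(θ−φ), and the ballistic fluence is
F = F₀·exp(−∫μₐ dz). To second order the initial pressure is a product of
two cosines,

    p = p̄ (1 + α cos(2θ − 2ψ)) (1 + β cos(2θ − 2φ)),

where β = Δμₐ/(2μ̄ₐ) is the local dichroism ratio and (α, ψ) the
accumulated fluence modulation. Demodulating the sweep gives per-pixel
observables ξ (normalized fundamental amplitude) and η (fundamental
phase); η slides sigmoid-like between 2φ and 2ψ as α/β grows, with an
amplitude null and 90° orientation flip where α = β (at depth ≈ 1/μ̄ₐ in a
homogeneous sample). The inversion minimizes

    ε = wrap(η − η_model)² + (ξ − ξ_model)²

per pixel, marching depth-sequentially with continuity constraints on
(α, ψ), a piecewise-constant prior on φ, Rose-criterion (5σ) masking with
an exception for cancellation points, and circular interpolation of masked
pixels. See the methods vignette (`vignettes/dspai-methods.Rmd`) for the
full account.

## Worked example

Simulate a single tendon oriented at 30°, with additive noise calibrated
so the surface fundamental sits at 20× the background noise floor, then
recover the orientation map:

```r
library(dspai)

phantom <- tendon_presets("single", phi1 = 30)
sigma   <- calibrate_additive_sigma(phantom, sweep_config(), target_snr = 20)
stack   <- acquire_sweep(phantom, sweep_config(),
                         noise_config(sigma, 0.05, seed = 42))
stack    <- energy_correct(stack)
spectral <- polarization_spectrum(stack)

cfg <- fit_config(background_rows = 33:40)   # water rows = noise reference
est <- interpolate_masked(estimate_image(spectral, rose_mask(spectral, cfg), cfg))

orientation_histogram(est$phi_map, est$valid)
#> <orientation_summary> n=196  circular mean=30.38 deg  circular sd=2.56 deg
angular_error(est$phi_map, phantom$phi_map, est$valid)
#> [1] 2.59
head(depth_profiles(spectral, est, column = 8), 4)
#>   depth_cm eta_half    phi     psi alpha  beta
#> 1    0.005   29.422 29.422 119.422 0.003 0.054
#> 2    0.015   29.711 29.422 117.955 0.009 0.054
#> 3    0.025   24.585 27.471 123.992 0.017 0.054
#> 4    0.035   29.708 27.533 113.992 0.021 0.054
```

The histogram peaks at the true 30° orientation with a pooled error of
2.6° over the 196 unmasked pixels; the profile shows the recovered φ
holding near 30° while the fluence phase ψ stays in counter-phase
(≈ 120°) and α builds up from zero. Rows deeper than the α = β
cancellation are masked at this noise level and filled by interpolation.
`plot_depth_profiles(depth_profiles(spectral, est, 8))` draws the
phase/modulation diagnostic; in a noiseless run the raw phase `eta_half`
flips from 30° to −60° at exactly 2 mm while the corrected φ stays flat.

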