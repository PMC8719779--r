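# beadcal

Thermal-motion force calibration for single-molecule video-tracking
experiments (magnetic and optical tweezers), in R.

In these experiments a micron-scale bead, tethered by a single molecule
and held by a trap of stiffness κ (pN/nm), diffuses with drag coefficient
γ (pN s/nm) in a harmonic potential; the applied force follows as
F = κL from the tether geometry. Calibration means estimating γ and κ
from the recorded bead trajectory. Doing that well at video rates
requires correcting for the camera: exposure blur low-passes the spectrum
by sinc²(fτ₀), sampling folds aliases into the band, tracking error adds
a white floor ε²/f_s, and the scatter of spectral estimates is
Gamma-distributed — so least-squares fits of the raw or log spectrum
mis-estimate the parameters, while maximum likelihood with the correct
Gamma weights does not.

beadcal implements the full chain:

- **Simulator** (`simulate_trajectory()`): exact Ornstein–Uhlenbeck
  propagation with camera-exposure averaging and optional Gaussian
  tracking error; seeded and bit-reproducible.
- **Spectrum estimators**: Welch power spectral density with Hann window
  and half-overlapping segments (`psd_welch()`), and octave-sampled
  overlapping Allan variance (`avar_overlapping()`) with per-point
  equivalent degrees of freedom from power-law noise identification
  (`identify_noise_lag1()`, `edf_empirical()`).
- **Models**: closed-form PSD with blur + aliasing
  (`psd_closed_form()`, exact match to the truncated alias sum
  `psd_aliased_sum()`), a dead-time variant, the thermal Allan-variance
  curve `av_thermal()` (peak at τ ≈ 1.89 γ/κ), and "+tracking" variants;
  user curves via `register_thermal_model()`.
- **Inference**: Gamma-likelihood MLE (`fit_thermal()`) with parameter
  fixing and abscissa cutoffs, Hessian uncertainties, and an
  affine-invariant ensemble MCMC sampler (`mcmc_sample()`).
- **Diagnostics**: normalized residuals, reduced χ², support F, AIC and
  ΔAIC ≥ 4 model comparison (`compare_models()`).

Everything is data-frame-first and pipe-friendly: trajectories and
spectra are tibbles, fits have `tidy()`/`glance()`/`augment()` methods
and `autoplot()` figures. A thin CLI (`inst/cli/beadcal`) exposes
`simulate`, `spectrum`, `calibrate`, `curve` and `benchmark`
subcommands.

## Worked example

Simulate a bead at f_c = 5 Hz (γ = 10⁻⁵ pN s/nm, κ = 3.14×10⁻⁴ pN/nm)
sampled at 100 Hz, then calibrate from the Allan variance:

```r
library(beadcal)
traj <- simulate_trajectory(n = 4096, f_s = 100, gamma = 1e-5,
                            kappa = 2 * pi * 1e-5 * 5, seed = 42)
fit <- fit_thermal(avar_overlapping(traj))
fit
#> Thermal-motion calibration fit: av:lansdorp (11 points)
#>   gamma    1.083e-05 +/- 4.6e-07 pN s/nm
#>   kappa    0.0003273 +/- 7.4e-06 pN/nm
#>   chi2_nu = 0.910 (nu = 9), support = 0.485, AIC = 135.4
```

Both parameters land within two reported standard errors of the
simulation truth; χ²_ν ≈ 0.91 with support 0.49 says the residual
scatter is consistent with the Gamma model. The same numbers in tidy
form, and MCMC intervals for comparison:

```r
tidy(fit)
#> # A tibble: 2 × 4
#>   term   estimate   std.error fixed
#>   <chr>     <dbl>       <dbl> <lgl>
#> 1 gamma 0.0000108 0.000000456 FALSE
#> 2 kappa 0.000327  0.00000742  FALSE
tidy(mcmc_sample(fit, seed = 1))
#> # A tibble: 2 × 5
#>   term     median     q15.8     q84.2   std_error
#>   <chr>     <dbl>     <dbl>     <dbl>       <dbl>
#> 1 gamma 0.0000108 0.0000104 0.0000113 0.000000457
#> 2 kappa 0.000327  0.000320  0.000335  0.00000741
```

The MCMC percentile half-widths reproduce the Hessian errors to better
than 1% here. With the fitted stiffness, a 700 nm tether carries
`trap_force(3.27e-4, 700)` ≈ 0.23 pN. For a PSD-route calibration use
`fit_thermal(psd_welch(traj))`; `calibrate()` runs either route
end-to-end and writes a self-describing JSON report.

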