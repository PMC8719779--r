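---
title: "Thermal-motion force calibration: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-motion force calibration: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

beadcal calibrates the force in single-molecule video-tracking experiments
(magnetic and optical tweezers) from the thermal motion of the trapped
bead. This vignette is the package's own account of the science: the
model, the estimators, the numerical choices, and what the tests do and do
not demonstrate.

Units are fixed package-wide: positions in nm, time in s, rates in Hz,
forces in pN, energies in pN nm; the drag coefficient γ is in pN s/nm and
the trap stiffness κ in pN/nm. The default thermal energy is
kT = 4.11 pN nm (T = 298 K).

## The physical model

A bead of drag coefficient γ held in a harmonic trap of stiffness κ obeys
the overdamped Langevin equation κx + γẋ = F_L(t), with ⟨F_L(t+t′)F_L(t)⟩
= 2γkT δ(t′). Hydrodynamic memory matters only below ~10⁻⁴ s and is
ignored, which is appropriate at video rates. Two derived scales organize
everything: the corner frequency f_c = κ/(2πγ) and the relaxation time
τ_c = γ/κ. The applied force follows from the fitted stiffness and the
tether geometry as F = κL (`trap_force()`).

The position power spectral density (PSD) is a Lorentzian,
P(f) = kT / (2π²γ(f_c² + f²)), whose full-line integral is the
equipartition variance kT/κ. A video camera does not sample x(t)
instantaneously: with zero dead time the exposure spans the whole sampling
interval τ_s = 1/f_s, multiplying the spectrum by the low-pass filter
I(f) = sinc²(fτ_s), and sampling folds all aliases |f + n f_s| onto the
band (0, f_s/2]. `psd_aliased_sum()` evaluates that sum by adaptive
truncation; for zero dead time the sum has an exact closed form
(`psd_closed_form()`), and the two agree to better than 10⁻⁶ across
f_c/f_s from 0.002 to 0.5 (an oracle pair exercised in the tests).
Gaussian per-frame tracking error of standard deviation ε adds the white
floor ε²/f_s (`psd_with_tracking()`).

The Allan variance (AV) — one half the mean squared difference between
averages of adjacent observation windows of duration τ — has the
closed form implemented in `av_thermal()`. This formula circulates in
the literature with typographically ambiguous coefficients; the reading
implemented here is fixed uniquely by three requirements (documented in
the code):
the free-diffusion limit 2kTτ/(3γ) as τ → 0, the uncorrelated-positions
limit 2kTγ/(κ²τ) as τ → ∞, and the maximum at τ ≈ 1.89 τ_c. Tracking
error adds ε²τ_s/τ (`av_with_tracking()`). The AV needs no exposure or
aliasing correction: window averaging *is* the exposure model (zero dead
time assumed; the residual dead-time bias is negligible whenever
τ_s < τ_c).

## The simulator

`simulate_trajectory()` is both the fixture generator and the benchmark
engine. It uses the exact Ornstein–Uhlenbeck transition
x(t+δt) = x e^(−δt/τ_c) + N(0, (kT/κ)(1 − e^(−2δt/τ_c))), which is
distributionally exact at any step, with x(0) drawn from the stationary
distribution so there is no burn-in transient. Camera exposure is
emulated by propagating `oversample` fine steps per frame
(δt = 1/(oversample·f_s), default 1000, the benchmark protocol) and
averaging each block; tracking error is an independent Gaussian stream
drawn *after* the thermal stream, so runs sharing a seed but differing in
ε share their thermal noise (useful for paired tests). In the large test
ensembles the package uses oversample = 50: the discretization error of
block-averaged exposure is O(1/oversample²) and far below Monte-Carlo
resolution at those sizes, while the acceptance benchmark keeps the full
1000.

What the simulator deliberately does not emulate: bead–surface
hydrodynamic coupling, rotational/3-D motion, mechanical drift, line-
frequency pickup, or non-Gaussian tracking artefacts. Tests passing on
simulated data therefore demonstrate correctness of the estimators and
inference under the stated model, not robustness to every laboratory
parasitic; the cutoff mechanism (below) is the practical tool for the
latter.

```{r}
library(beadcal)
traj <- simulate_trajectory(n = 4096, f_s = 100, gamma = 1e-5,
                            kappa = 2 * pi * 1e-5 * 5, seed = 1)
fit <- fit_thermal(avar_overlapping(traj))
tidy(fit)
glance(fit)
```

## Spectrum estimators

`psd_welch()` splits the trajectory into M half-overlapping segments
(default 3), removes each segment's mean (suppressing DC leakage from
slow drift; switchable), applies a Hann window with the √(8/3) amplitude
factor that restores the window's power loss, and averages the per-segment
periodograms. The segment length is L = 2⌊N_x/(M+1)⌋ — even, so the
half-overlap step is integral — and the grid is f_k = k f_s/L,
k = 1..L/2 (DC dropped, Nyquist kept; the model functions accept the
closed interval (0, f_s/2]). The reported values are a two-sided density
shown on positive frequencies: white noise of variance ε² sits at
ε²/f_s, and the Lorentzian integrates to kT/κ over the full line, so the
closed-form models apply verbatim. This convention is pinned by a
dedicated test. Each PSD value is treated as Gamma-distributed with shape
η = M. `log_bin_psd()` exists for display only and is refused by the
fitter.

`avar_overlapping()` computes the octave-sampled overlapping AV: bin
lengths m_k = 2^k up to N_x/2, window pairs separated by m_k samples with
start indices sliding one sample, prefactor 1/(2(N_x − 2m_k + 1)),
implemented with cumulative sums (linear cost per τ). A brute-force
enumeration oracle pins the estimator exactly on a thousand random short
series. Note the octave grid starts at m = 2; there is no m = 1 point.

### Degrees of freedom of the AV points

Each AV value is Gamma-distributed with shape η_k = ν_k/2. The crude
choice ν = N_x/m − 1 (`edf_approximate()`, the `edf = "approx"` mode)
counts non-overlapping differences. The default instead computes the
equivalent degrees of freedom of the *overlapping* estimator given the
dominant power-law noise at each τ: `identify_noise_lag1()` classifies
the m-averaged series by the lag-1 autocorrelation statistic (differencing
until δ = r₁/(1+r₁) < 1/4, exponent α = −2(δ + d); white positions α = 0,
flicker −1, random walk −2, drift below), and `edf_empirical()` evaluates
the combined-edf machinery on generalized autocovariances. Points with
N_x/m < 32 inherit the class of the last well-identified point; if
identification fails outright the package warns and falls back on the
approximate dof.

One design point deserves emphasis. The edf machinery admits a
phase-averaging factor F; published implementations aimed at
point-sampled phase data use F = m for unmodified variances. Camera
frames, however, are time-averages of the continuous process, which makes
the accumulated phase point-sampled — the F → ∞ variant. Against an
exact trace-formula oracle (ν = tr(C)²/tr(C²) for the estimator's
quadratic form under a known data covariance) the F → ∞ variant
reproduces the exact dof of white positions and of exposure-averaged
free diffusion at every m, while F = m errs by up to 17% at small m; the
package therefore uses the point-phase variant for α ≤ 0 and the
published tabulated branches for α = +1/+2. A caveat found with the same
oracle: the common statement that ν = N_x/m − 1 *underestimates* the
overlapping estimator's dof holds for white-class points (m ≥ 2) but is
slightly reversed for random-walk-class points (e.g. 236 exact vs 255
approximate at N_x = 512, m = 2); the suite asserts the inequality only
where it is true.

## Gamma-likelihood inference

Averaged periodogram and AV values are Gamma, not Gaussian — at η = 3
markedly so — and least-squares fitting is then the wrong estimator.
The cost minimized is ℓ = Σ_k η_k[ŷ_k/y_k + ln y_k] (the Gamma negative
log-likelihood without its parameter-independent constant); the full
log-density, constants included, is kept separately because AIC
comparisons across models need absolute ln L̂. Where the misuse of least
squares actually bites, in this package's measurements: log-space LSQ is
biased by the Gamma log-mean offset (≈ +19% on both parameters at
η = 3); unweighted LSQ on raw values, by contrast, is nearly unbiased
here (E[ŷ] = y keeps its estimating equations consistent) though far
less efficient; the Gamma MLE is unbiased to a fraction of a percent.

`fit_thermal()` optimizes over the logs of the free parameters
(positivity for free), Nelder–Mead with a restart, followed by a damped
Newton polish that drives the log-space gradient to numerical zero.
Initial guesses are closed-form moment estimates: κ₀ from the
equipartition band power (PSD) or from kT·0.336/max AV; γ₀ from the
diffusive high-frequency tail or the short-τ slope 2kTτ/(3γ); ε₀ from
the high-frequency floor. Parameters can be fixed (`fix=`), which
removes them from K — the practical remedy when f_c ≳ f_s/8 leaves γ
poorly constrained; inclusive abscissa `cutoffs=` restrict the fitted
range (exactly equivalent to pre-truncating the spectrum), the practical
remedy for drift-dominated low frequencies / long observation times.
ε is a parameter only of the "+tracking" models; it is absent, not
"fixed at zero", in the plain ones.

Uncertainties invert the Hessian of ℓ at the minimum
(Richardson-extrapolated central differences in log space, delta-method
mapping to the natural scale); an indefinite Hessian produces a warning
and NA errors rather than a silent pseudo-inverse. `mcmc_sample()`
offers the robust alternative: an affine-invariant stretch-move ensemble
sampler (32 walkers, 2500 steps, 25% burn-in by default, seeded),
reporting 15.8/84.2-percentile intervals. On well-behaved thermal fits
the two agree to a few percent.

## Diagnostics and model choice

Normalized residuals use σ_y,k = y_k/√η_k, the standard deviation of the
Gamma sampling model — chosen for self-consistency with the likelihood
and pinned by a Monte-Carlo unit-variance test. χ²_ν divides by
ν_y = N_y − K. The support F is the chi-squared CDF at the fit's χ²;
because the calibration literature uses "support close to one" and
"large p-value" with opposite orientations, both F and 1 − F are always
reported. Model comparison uses AIC = 2K − 2 ln L̂ and declares a
preference only at ΔAIC ≥ 4; with 10 nm tracking error at 1000 Hz the
tracking model wins at that margin in every replicate of the packaged
study.

## Known limitations

The likelihood treats spectrum points as independent. They are not
quite: Hann-windowed half-overlapping Welch bins are neighbour-correlated
(adjacent-bin periodogram correlation 4/9), and octave AV points share
data across τ. Consequences, measured by the packaged studies: parameter
point estimates are unaffected (biases stay within ~1%), but the
*claimed* 1σ intervals cover the truth at roughly 53–57% instead of 68%
on trajectory ensembles (both routes), and the AV's reduced χ² runs low
(median ≈ 0.6–0.7) while the PSD's stays near 1. Under the likelihood's
own sampling model — independent Gamma draws at the theory curve — the
machinery is calibrated (coverage ≈ 68%, median χ²_ν ≈ 1.0, uniform
support), which localizes the discrepancy entirely in the independence
approximation. This approximation is standard in the field's calibration
tools; treat reported uncertainties as mild underestimates, or use
`mcmc_sample()` for the same answer to the same (approximate) question.

Problem sizes used by the packaged studies: the bias benchmark runs 200
replicates of N_x = 4096 at f_s = 100 Hz, γ = 10⁻⁵ pN s/nm, f_c = 5 Hz
with 1000 fine steps per frame; the coverage study 300 replicates
(50 fine steps); the diagnostics study 500 parametric-bootstrap spectra
on the same grid; the model-selection study 100 replicates of the
20480-point, 1000 Hz, ε = 10 nm configuration. Corner-frequency sweeps
derive κ = 2πγf_c from the swept f_c.

Out of scope by design: hydrodynamic corrections below 10⁻⁴ s, Faxén
surface corrections, torque calibration, multi-coordinate joint fits,
and non-zero dead-time AV corrections (negligible for τ_s < τ_c).
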