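#' Lorentzian power spectral density of a trapped bead
#'
#' Two-sided spectral density of continuous Ornstein--Uhlenbeck motion,
#' reported on positive frequencies:
#' \deqn{P(f) = \frac{k_BT}{2\pi^2\gamma\,(f_c^2 + f^2)},\qquad
#'       f_c = \frac{\kappa}{2\pi\gamma}.}
#' Its integral over the full frequency line is the equipartition variance
#' \eqn{k_BT/\kappa}. Below the corner frequency the curve plateaus at
#' \eqn{2k_BT\gamma/\kappa^2}; above it the motion is free diffusion and
#' \eqn{P \approx k_BT/(2\pi^2\gamma f^2)}.
#'
#' @param f Frequency in Hz (vectorized, >= 0).
#' @param gamma Drag coefficient, pN s/nm.
#' @param kappa Spring constant, pN/nm.
#' @param kT Thermal energy, pN nm.
#' @return Spectral density in nm^2/Hz.
#' @export
psd_lorentzian <- function(f, gamma, kappa, kT = 4.11) {
  f_c <- kappa / (2 * pi * gamma)
  kT / (2 * pi^2 * gamma * (f_c^2 + f^2))
}

#' Camera exposure low-pass filter
#'
#' Attenuation of spectral power caused by averaging the bead position over
#' the camera exposure time `tau0`:
#' \deqn{I(f) = \mathrm{sinc}^2(f\tau_0) = \frac{\sin^2(\pi f\tau_0)}
#'       {(\pi f\tau_0)^2},}
#' with the limit \eqn{I(0) = 1} handled exactly.
#'
#' @param f Frequency in Hz (vectorized, >= 0).
#' @param tau0 Exposure time in s (> 0).
#' @return Dimensionless attenuation in (0, 1].
#' @export
exposure_filter <- function(f, tau0) {
  check_positive_scalar(tau0, "tau0")
  x <- pi * f * tau0
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- (sin(x[nz]) / x[nz])^2
  out
}

#' Aliased, exposure-filtered PSD by truncated summation
#'
#' Folds the exposure-filtered Lorentzian onto the sampled band:
#' \eqn{P_{A,B}(f) = \sum_n P(|f+nf_s|)\, I(|f+nf_s|)} over all integers
#' `n`, truncated adaptively once a rigorous bound on the remaining tail
#' (using the \eqn{1/f^2} decay of the Lorentzian and, when `tau0 > 0`, the
#' additional \eqn{1/f^2} decay of the exposure filter) falls below `tol`
#' of the partial sum. Supports `tau0 < 1/f_s` (camera dead time). With
#' `tau0 = 0` (no blur, pure aliasing) the sum is evaluated through the
#' exact sampled-Ornstein--Uhlenbeck (AR(1)) spectrum instead, since the
#' \eqn{1/f^2} tail then converges too slowly for naive truncation.
#'
#' @param f Frequencies in Hz, in (0, f_s/2] (Nyquist included, where the
#'   closed forms remain valid and the Welch grid has its last point).
#' @param gamma,kappa,kT Model parameters (see [psd_lorentzian()]).
#' @param f_s Sampling rate, Hz.
#' @param tau0 Exposure time in s, in \[0, 1/f_s\]. Default `1/f_s`
#'   (zero dead time).
#' @param tol Relative truncation tolerance for the alias sum.
#' @return Spectral density in nm^2/Hz.
#' @seealso [psd_closed_form()] for the exact closed form when
#'   `tau0 = 1/f_s`.
#' @export
psd_aliased_sum <- function(f, gamma, kappa, kT = 4.11, f_s,
                            tau0 = 1 / f_s, tol = 1e-8) {
  check_positive_scalar(f_s, "f_s")
  check_positive_scalar(tau0, "tau0", strict = FALSE)
  if (tau0 > 1 / f_s + 1e-12 / f_s) {
    abort("`tau0` cannot exceed the sampling interval 1/f_s.",
          class = "beadcal_invalid_argument")
  }
  if (any(f <= 0) || any(f > f_s / 2)) {
    abort("Frequencies must lie in (0, f_s/2].",
          class = "beadcal_invalid_argument")
  }
  if (tau0 == 0) {
    return(psd_sampled_lorentzian(f, gamma, kappa, kT, f_s))
  }
  term <- function(ff) psd_lorentzian(ff, gamma, kappa, kT) *
    exposure_filter(ff, tau0)
  acc <- term(f)
  n <- 0L
  repeat {
    n <- n + 1L
    acc <- acc + term(abs(f + n * f_s)) + term(abs(f - n * f_s))
    # Tail bound: for |m| > n, |f + m f_s| >= (m - 1/2) f_s, and
    # P(x) I(x) <= kT/(2 pi^2 gamma x^2) * 1/(pi x tau0)^2, so the
    # two-sided tail is below 2 * kT/(2 pi^4 gamma tau0^2 f_s^4) *
    # sum_{m>n} (m-1/2)^-4 <= same * 1/(3 (n-1/2)^3).
    tail_bound <- kT / (3 * pi^4 * gamma * tau0^2 * f_s^4 * (n - 0.5)^3)
    if (all(tail_bound < tol * acc) || n > 1e6) break
  }
  acc
}

# Exact spectrum of the point-sampled (unblurred) trapped bead: the sampled
# Ornstein-Uhlenbeck process is AR(1) with rho = exp(-kappa/(gamma f_s)),
# whose two-sided spectral density on (0, f_s/2) is
# (kT/kappa) (1-rho^2) / (f_s (1 + rho^2 - 2 rho cos(2 pi f/f_s))).
psd_sampled_lorentzian <- function(f, gamma, kappa, kT, f_s) {
  rho <- exp(-kappa / (gamma * f_s))
  (kT / kappa) * (1 - rho^2) /
    (f_s * (1 + rho^2 - 2 * rho * cos(2 * pi * f / f_s)))
}

#' Exact closed-form PSD with exposure blur and aliasing
#'
#' For zero camera dead time (`tau0 = 1/f_s`) the alias sum of the
#' exposure-filtered Lorentzian has the exact closed form
#' \deqn{P_{A,B}(f) = \frac{2k_BT\gamma}{\kappa^3}\left(\kappa +
#'  \frac{2\gamma f_s \sin^2(\pi f/f_s)\sinh(\kappa/\gamma f_s)}
#'       {\cos(2\pi f/f_s) - \cosh(\kappa/\gamma f_s)}\right).}
#' It is evaluated here through the identity
#' \eqn{\cosh c - \cos\theta = 2(\sinh^2(c/2) + \sin^2(\theta/2))}, which
#' removes the cancellation between the two near-equal large terms for
#' stiff traps; for \eqn{c = \kappa/(\gamma f_s) > 1400} the hyperbolic
#' ratio is within \eqn{e^{-c}} of 1 and is replaced by 1, so the result
#' stays finite for arbitrarily stiff traps.
#'
#' @inheritParams psd_aliased_sum
#' @return Spectral density in nm^2/Hz.
#' @export
psd_closed_form <- function(f, gamma, kappa, kT = 4.11, f_s) {
  check_positive_scalar(f_s, "f_s")
  if (any(f <= 0) || any(f > f_s / 2)) {
    abort("Frequencies must lie in (0, f_s/2].",
          class = "beadcal_invalid_argument")
  }
  c2 <- kappa / (gamma * f_s) / 2   # c/2
  s2 <- sin(pi * f / f_s)^2         # sin^2(theta/2)
  # sinh(c) / (cos(theta) - cosh(c)) = -sinh(c/2)cosh(c/2) /
  #   (sinh^2(c/2) + sin^2(theta/2))
  ratio <- if (c2 > 700) rep(1, length(f)) else {
    sh <- sinh(c2)
    sh * cosh(c2) / (sh^2 + s2)
  }
  (2 * kT * gamma / kappa^3) * (kappa - 2 * gamma * f_s * s2 * ratio)
}

#' Closed-form PSD with camera tracking error
#'
#' Adds the white spectral floor of Gaussian per-frame localization noise,
#' \eqn{\epsilon^2/f_s}, to [psd_closed_form()].
#'
#' @inheritParams psd_closed_form
#' @param epsilon Tracking-error standard deviation, nm (>= 0).
#' @return Spectral density in nm^2/Hz.
#' @export
psd_with_tracking <- function(f, gamma, kappa, epsilon = 0, kT = 4.11, f_s) {
  psd_closed_form(f, gamma, kappa, kT, f_s) + epsilon^2 / f_s
}

#' Thermal-motion Allan variance of a trapped bead
#'
#' Closed-form Allan variance of the exposure-averaged (zero-dead-time)
#' trapped bead at observation time `tau`:
#' \deqn{\sigma^2_{AV}(\tau) = \frac{2k_BT\gamma}{\kappa^2\tau}\left(1 +
#'   \frac{2\gamma}{\kappa\tau}e^{-\kappa\tau/\gamma} -
#'   \frac{\gamma}{2\kappa\tau}e^{-2\kappa\tau/\gamma} -
#'   \frac{3\gamma}{2\kappa\tau}\right).}
#'
#' The coefficient pattern (2, 1/2, 3/2) is fixed uniquely by three
#' requirements: with a = kappa tau / gamma, the bracket must expand as
#' a^2/3 - a^3/4 + 7a^4/60 - a^5/24 + O(a^6) so that
#' sigma^2 -> 2 kT tau / (3 gamma) as tau -> 0 (free-diffusion limit); it
#' must tend to 1 so that sigma^2 -> 2 kT gamma/(kappa^2 tau) as
#' tau -> infinity (uncorrelated-positions limit); and the resulting curve
#' must peak at tau ~= 1.89 gamma/kappa. Any other reading of the
#' coefficients breaks at least one of these limits. For a < 1e-2 the
#' bracket is evaluated by that series (direct evaluation there loses ~2
#' digits per decade of smallness to cancellation between O(1/a) terms).
#'
#' @param tau Observation time in s (> 0, vectorized).
#' @param gamma,kappa,kT Model parameters (see [psd_lorentzian()]).
#' @return Allan variance in nm^2.
#' @export
av_thermal <- function(tau, gamma, kappa, kT = 4.11) {
  if (any(tau <= 0) || any(!is.finite(tau))) {
    abort("`tau` must be positive.", class = "beadcal_invalid_argument")
  }
  a <- kappa * tau / gamma
  bracket <- ifelse(
    a < 1e-2,
    a^2 / 3 - a^3 / 4 + 7 * a^4 / 60 - a^5 / 24,
    1 + (2 / a) * exp(-a) - exp(-2 * a) / (2 * a) - 3 / (2 * a)
  )
  (2 * kT * gamma / (kappa^2 * tau)) * bracket
}

#' Thermal-motion Allan variance with camera tracking error
#'
#' Adds the tracking-error contribution \eqn{\epsilon^2\tau_s/\tau}
#' (white position noise averaged over windows of length
#' \eqn{\tau/\tau_s} frames) to [av_thermal()].
#'
#' @inheritParams av_thermal
#' @param epsilon Tracking-error standard deviation, nm (>= 0).
#' @param f_s Sampling rate, Hz (sets \eqn{\tau_s = 1/f_s}).
#' @return Allan variance in nm^2.
#' @export
av_with_tracking <- function(tau, gamma, kappa, epsilon = 0, kT = 4.11, f_s) {
  check_positive_scalar(f_s, "f_s")
  av_thermal(tau, gamma, kappa, kT) + epsilon^2 / (f_s * tau)
}

# ---- model registry ---------------------------------------------------------

the_registry <- new.env(parent = emptyenv())

register_builtin_models <- function() {
  reg <- function(key, kind, params, fun, label) {
    assign(key, list(key = key, kind = kind, params = params, fun = fun,
                     label = label), envir = the_registry)
  }
  reg("psd:lansdorp", "psd", c("gamma", "kappa"),
      function(x, p, kT, f_s)
        psd_closed_form(x, p[["gamma"]], p[["kappa"]], kT, f_s),
      "PSD, exposure blur + aliasing (zero dead time)")
  reg("psd:lansdorp+tracking", "psd", c("gamma", "kappa", "epsilon"),
      function(x, p, kT, f_s)
        psd_with_tracking(x, p[["gamma"]], p[["kappa"]], p[["epsilon"]],
                          kT, f_s),
      "PSD, exposure blur + aliasing + tracking error")
  reg("psd:lorentzian-aliased", "psd", c("gamma", "kappa"),
      function(x, p, kT, f_s)
        psd_sampled_lorentzian(x, p[["gamma"]], p[["kappa"]], kT, f_s),
      "PSD, aliasing only (negligible exposure time / dead-time camera)")
  reg("av:lansdorp", "av", c("gamma", "kappa"),
      function(x, p, kT, f_s)
        av_thermal(x, p[["gamma"]], p[["kappa"]], kT),
      "AV, thermal motion (zero dead time)")
  reg("av:lansdorp+tracking", "av", c("gamma", "kappa", "epsilon"),
      function(x, p, kT, f_s)
        av_with_tracking(x, p[["gamma"]], p[["kappa"]], p[["epsilon"]],
                         kT, f_s),
      "AV, thermal motion + tracking error")
}

#' Register a user-defined spectral model
#'
#' Adds a theory curve to the model registry so it can be fitted with
#' [fit_thermal()] exactly like the built-in models.
#'
#' @param key Registry key, e.g. `"psd:mymodel"`.
#' @param kind `"psd"` or `"av"` — which experimental estimate the model
#'   describes.
#' @param params Character vector of free-parameter names, in order.
#' @param fun `function(x, params, kT, f_s)` returning model values (> 0)
#'   on abscissa `x` (frequency in Hz for PSD, observation time in s for
#'   AV); `params` is a named numeric vector.
#' @param label Human-readable description.
#' @return `key`, invisibly.
#' @export
register_thermal_model <- function(key, kind = c("psd", "av"), params, fun,
                                   label = key) {
  kind <- match.arg(kind)
  stopifnot(is.character(key), length(key) == 1L, is.function(fun),
            is.character(params), length(params) >= 1L)
  assign(key, list(key = key, kind = kind, params = params, fun = fun,
                   label = label), envir = the_registry)
  invisible(key)
}

#' List registered spectral models
#'
#' @return A tibble with one row per registered model: key, kind,
#'   parameter names, label.
#' @export
list_thermal_models <- function() {
  keys <- sort(ls(the_registry))
  purrr::map_dfr(keys, function(k) {
    m <- get(k, envir = the_registry)
    tibble::tibble(key = m$key, kind = m$kind,
                   params = paste(m$params, collapse = ","),
                   label = m$label)
  })
}

get_thermal_model <- function(key) {
  if (!exists(key, envir = the_registry, inherits = FALSE)) {
    abort(sprintf("Unknown model key '%s'. See list_thermal_models().", key),
          class = "beadcal_unknown_model")
  }
  get(key, envir = the_registry)
}

#' Tabulate a registered model curve
#'
#' Evaluates a registered theory curve on an abscissa grid; useful for
#' plotting or for exporting a curve as CSV.
#'
#' @param key Registry key (see [list_thermal_models()]).
#' @param x Abscissa grid: frequency (Hz) for PSD models, observation time
#'   (s) for AV models.
#' @param params Named numeric vector of model parameters (e.g.
#'   `c(gamma = 1e-5, kappa = 3e-4)`).
#' @param kT Thermal energy, pN nm.
#' @param f_s Sampling rate, Hz.
#' @return Tibble with columns `x` and `value`.
#' @export
thermal_model_curve <- function(key, x, params, kT = 4.11, f_s) {
  m <- get_thermal_model(key)
  missing <- setdiff(m$params, names(params))
  if (length(missing)) {
    abort(sprintf("Model '%s' needs parameters: %s.", key,
                  paste(missing, collapse = ", ")),
          class = "beadcal_invalid_argument")
  }
  tibble::tibble(x = x, value = m$fun(x, params, kT, f_s))
}
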