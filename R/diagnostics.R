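#' Normalized residuals of a spectral fit
#'
#' \eqn{\Delta_k = (\hat y_k - y_k)/\sigma_{y,k}} with
#' \eqn{\sigma_{y,k} = y_k/\sqrt{\eta_k}}, the standard deviation of a
#' Gamma variate with shape \eqn{\eta_k} and mean \eqn{y_k} — the same
#' sampling model the likelihood uses. Under a correct model the
#' \eqn{\Delta_k} have unit variance (and become Gaussian as
#' \eqn{\eta_k \to \infty}).
#'
#' @param values Experimental values \eqn{\hat y_k} (>= 0).
#' @param shapes Gamma shapes \eqn{\eta_k} (> 0).
#' @param model_values Model predictions \eqn{y_k} (> 0).
#' @return Numeric vector of residuals.
#' @export
normalized_residuals <- function(values, shapes, model_values) {
  if (any(shapes <= 0)) {
    abort("Shapes must be positive.", class = "beadcal_invalid_argument")
  }
  if (any(model_values <= 0)) {
    abort("Model values must be positive.",
          class = "beadcal_invalid_argument")
  }
  (values - model_values) / (model_values / sqrt(shapes))
}

#' Reduced chi-squared of a fit
#'
#' \eqn{\chi^2_\nu = \sum_k \Delta_k^2 / \nu_y} with
#' \eqn{\nu_y = N_y - K} degrees of freedom (`K` free parameters). A value
#' near one indicates residual scatter consistent with the assumed
#' per-point uncertainty.
#'
#' @param residuals Normalized residuals from [normalized_residuals()].
#' @param K Number of free parameters.
#' @return A list with `chi2`, `nu` and `chi2_nu`.
#' @export
reduced_chi2 <- function(residuals, K) {
  n_y <- length(residuals)
  if (n_y <= K) {
    abort("Need more points than free parameters.",
          class = "beadcal_invalid_argument")
  }
  chi2 <- sum(residuals^2)
  list(chi2 = chi2, nu = n_y - K, chi2_nu = chi2 / (n_y - K))
}

#' Support of a fit (chi-squared distribution function)
#'
#' \eqn{F = P(\nu/2,\ \chi^2/2)}, the regularized lower incomplete gamma
#' function, i.e. the chi-squared CDF evaluated at the fit's \eqn{\chi^2}.
#' The complementary p-value \eqn{1 - F} is returned alongside; both are
#' reported because "support close to one" and "large p-value" are used
#' interchangeably in the calibration literature with opposite
#' orientations.
#'
#' @param chi2 Chi-squared statistic (>= 0).
#' @param nu Degrees of freedom (> 0).
#' @return A list with `support` (F) and `p_value` (1 - F).
#' @export
support <- function(chi2, nu) {
  if (any(chi2 < 0) || any(nu <= 0)) {
    abort("Need chi2 >= 0 and nu > 0.", class = "beadcal_invalid_argument")
  }
  F <- pchisq(chi2, df = nu)
  list(support = F, p_value = 1 - F)
}

#' Akaike information criterion
#'
#' \eqn{AIC = 2K - 2\ln\hat L}, with \eqn{\ln\hat L} the full maximized
#' log-likelihood (constants included, so AIC is comparable across models
#' with different parameter counts).
#'
#' @param logLik_hat Maximized log-likelihood.
#' @param K Number of free parameters (>= 0).
#' @return AIC value.
#' @export
aic <- function(logLik_hat, K) {
  if (any(K < 0)) {
    abort("`K` must be >= 0.", class = "beadcal_invalid_argument")
  }
  2 * K - 2 * logLik_hat
}

#' Compare fitted models by AIC
#'
#' Ranks fits of the *same* spectrum by AIC and declares a preferred model
#' only when every rival trails by \eqn{\Delta AIC \ge 4}; smaller gaps are
#' reported as indistinguishable.
#'
#' @param ... Two or more `thermal_fit` objects (or a single list of them)
#'   fitted to identical points.
#' @return A tibble ranked by AIC with columns `model`, `K`, `AIC`,
#'   `delta_aic`, `preferred`; attribute `preferred` holds the winning
#'   model key or `NA`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "thermal_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2L) {
    abort("Need at least two fits to compare.",
          class = "beadcal_invalid_argument")
  }
  ref <- fits[[1]]$data
  for (f in fits[-1]) {
    if (nrow(f$data) != nrow(ref) ||
        !isTRUE(all.equal(f$data$abscissa, ref$abscissa)) ||
        !isTRUE(all.equal(f$data$value, ref$value))) {
      abort("Fits must be over identical spectrum points (same data and cutoffs).",
            class = "beadcal_invalid_argument")
    }
  }
  out <- purrr::map_dfr(fits, function(f)
    tibble::tibble(model = f$model, K = f$K, AIC = f$diagnostics$AIC)) |>
    dplyr::arrange(.data$AIC) |>
    dplyr::mutate(delta_aic = .data$AIC - min(.data$AIC))
  decided <- nrow(out) >= 2 && all(out$delta_aic[-1] >= 4)
  out$preferred <- decided & out$delta_aic == 0
  attr(out, "preferred") <- if (decided) out$model[1] else NA_character_
  out
}
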