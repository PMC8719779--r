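#' Gamma negative log-likelihood cost of a spectral fit
#'
#' The cost minimized by the calibration:
#' \deqn{\ell = \sum_k \eta_k\left[\hat y_k / y_k + \ln y_k\right],}
#' i.e. the negative log of the joint Gamma likelihood with its
#' parameter-independent constant dropped. The full log-density (constants
#' included), needed for AIC, is provided by [gamma_loglik()].
#'
#' @param values Experimental values \eqn{\hat y_k} (>= 0).
#' @param shapes Gamma shapes \eqn{\eta_k} (> 0).
#' @param model_values Model predictions \eqn{y_k} (> 0).
#' @return The scalar cost \eqn{\ell}.
#' @export
gamma_negloglik <- function(values, shapes, model_values) {
  if (length(values) != length(model_values) ||
      length(values) != length(shapes)) {
    abort("values, shapes and model_values must have equal length.",
          class = "beadcal_invalid_argument")
  }
  if (any(shapes <= 0)) {
    abort("Shapes must be positive.", class = "beadcal_invalid_argument")
  }
  if (any(model_values <= 0) || any(!is.finite(model_values))) {
    abort("Model values must be positive and finite.",
          class = "beadcal_invalid_model_value")
  }
  sum(shapes * (values / model_values + log(model_values)))
}

#' Full Gamma log-likelihood of a spectral fit
#'
#' Joint log-density of the experimental values under the Gamma sampling
#' model with shape \eqn{\eta_k} and scale \eqn{y_k/\eta_k}, constants
#' included (used for AIC).
#'
#' @inheritParams gamma_negloglik
#' @return Scalar log-likelihood.
#' @export
gamma_loglik <- function(values, shapes, model_values) {
  sum(dgamma(values, shape = shapes, scale = model_values / shapes,
             log = TRUE))
}

#' Fit a thermal-motion model to a PSD or AV estimate by maximum likelihood
#'
#' Minimizes the Gamma-likelihood cost [gamma_negloglik()] over the free
#' parameters of a registered model, in log-parameter space (all parameters
#' are positive scales), by Nelder--Mead with one polishing restart.
#' Uncertainties come from the inverted Hessian of the cost at the minimum
#' ([hessian_errors()]); diagnostics (normalized residuals, reduced
#' chi-squared, support, AIC) are attached. Deterministic given its inputs.
#'
#' @param estimate A `spectrum_estimate` from [psd_welch()] or
#'   [avar_overlapping()].
#' @param model Registry key (see [list_thermal_models()]); defaults to
#'   `"psd:lansdorp"` / `"av:lansdorp"` according to the estimate kind.
#' @param kT Thermal energy, pN nm.
#' @param fix Named numeric vector of parameters to hold fixed, e.g.
#'   `c(gamma = 1e-5)`. Fixed parameters are excluded from `K`.
#' @param start Optional named numeric vector of initial guesses for free
#'   parameters; defaults come from closed-form moment estimates
#'   (equipartition band power for `kappa`, the diffusive tail or short-time
#'   slope for `gamma`).
#' @param cutoffs Optional `c(lower, upper)` inclusive abscissa bounds
#'   (frequency in Hz for PSD, observation time in s for AV); points
#'   outside are excluded from the fit. `NA` leaves a side open.
#' @return A `thermal_fit` object: estimates, standard errors, covariance,
#'   cost, log-likelihood, diagnostics, and a `data` tibble with per-point
#'   fitted values and normalized residuals. Methods: `print()`, `tidy()`,
#'   `glance()`, `augment()`, `autoplot()`.
#' @examples
#' traj <- simulate_trajectory(n = 4096, f_s = 100, gamma = 1e-5,
#'                             kappa = 2 * pi * 1e-5 * 5, seed = 7)
#' fit <- fit_thermal(avar_overlapping(traj))
#' tidy(fit)
#' @export
fit_thermal <- function(estimate, model = NULL, kT = 4.11, fix = NULL,
                        start = NULL, cutoffs = NULL) {
  kind <- spectrum_kind(estimate)
  if (isFALSE(attr(estimate, "fit_ok"))) {
    abort("This estimate is flagged for visualization only (log-binned PSD); fit the unbinned estimate.",
          class = "beadcal_invalid_argument")
  }
  if (is.null(model)) {
    model <- if (kind == "psd") "psd:lansdorp" else "av:lansdorp"
  }
  m <- get_thermal_model(model)
  if (m$kind != kind) {
    abort(sprintf("Model '%s' is a %s model but the estimate is a %s.",
                  model, toupper(m$kind), toupper(kind)),
          class = "beadcal_model_kind_mismatch")
  }
  f_s <- attr(estimate, "f_s")
  check_positive_scalar(kT, "kT")

  x_all <- abscissa_of(estimate)
  keep <- rep(TRUE, length(x_all))
  if (!is.null(cutoffs)) {
    if (length(cutoffs) != 2L) {
      abort("`cutoffs` must be c(lower, upper); use NA for an open side.",
            class = "beadcal_invalid_argument")
    }
    if (!is.na(cutoffs[1])) keep <- keep & x_all >= cutoffs[1]
    if (!is.na(cutoffs[2])) keep <- keep & x_all <= cutoffs[2]
  }
  x <- x_all[keep]
  yhat <- estimate$value[keep]
  eta <- estimate$shape[keep]

  if (all(yhat == 0)) {
    abort("Degenerate spectrum: all values are zero.",
          class = "beadcal_degenerate_input")
  }

  if (!is.null(fix)) {
    bad <- setdiff(names(fix), m$params)
    if (length(bad)) {
      abort(sprintf("Cannot fix '%s': model '%s' has parameters %s.",
                    paste(bad, collapse = ","), model,
                    paste(m$params, collapse = ", ")),
            class = "beadcal_invalid_argument")
    }
  }
  free <- setdiff(m$params, names(fix))
  if (length(free) == 0L) {
    abort("At least one parameter must be free.",
          class = "beadcal_invalid_argument")
  }
  if (length(x) < length(free) + 1L) {
    abort("Cutoffs leave too few points: need at least K + 1.",
          class = "beadcal_invalid_argument")
  }

  start_full <- default_start(kind, x, yhat, kT, f_s, m$params)
  if (!is.null(fix)) start_full[names(fix)] <- fix
  if (!is.null(start)) start_full[names(start)] <- start
  p0 <- start_full[free]
  if (any(p0 <= 0) || any(!is.finite(p0))) {
    abort("Initial guesses must be positive and finite.",
          class = "beadcal_invalid_argument")
  }

  assemble <- function(theta_log) {
    p <- start_full
    p[free] <- exp(theta_log)
    p
  }
  cost_log <- function(theta_log) {
    p <- assemble(theta_log)
    yk <- tryCatch(m$fun(x, p, kT, f_s), error = function(e) NULL)
    if (is.null(yk) || any(!is.finite(yk)) || any(yk <= 0)) return(Inf)
    gamma_negloglik(yhat, eta, yk)
  }

  # Nelder-Mead also handles the single-free-parameter case adequately
  # here (the Newton polish below sets the final precision), so optim's
  # advisory warning about 1-D simplex use is muffled.
  nm <- function(par) {
    withCallingHandlers(
      optim(par, cost_log, method = "Nelder-Mead",
            control = list(maxit = 1e4, reltol = 1e-10)),
      warning = function(w) {
        if (grepl("Nelder-Mead", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  opt <- nm(log(p0))
  # polish: Nelder-Mead can report flat convergence off the optimum;
  # restart once from the returned point
  opt2 <- nm(opt$par)
  if (opt2$value <= opt$value) opt <- opt2
  if (!is.finite(opt$value)) {
    abort(paste0("Fit failed to converge (cost not finite). Optimizer said: ",
                 "convergence = ", opt$convergence),
          class = "beadcal_fit_failed")
  }

  # Newton polish: Nelder-Mead stops on function-value flatness, which can
  # leave a measurable log-space gradient at these cost scales; a few
  # damped Newton steps drive it to numerical zero without changing the
  # optimizer's basin.
  theta_hat <- opt$par
  best <- opt$value
  for (it in 1:6) {
    g <- numDeriv::grad(cost_log, theta_hat)
    if (all(abs(g) < 1e-7)) break
    H <- numDeriv::hessian(cost_log, theta_hat)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    moved <- FALSE
    for (damp in c(1, 0.5, 0.25)) {
      cand <- theta_hat - damp * step
      v <- cost_log(cand)
      if (is.finite(v) && v <= best) {
        theta_hat <- cand
        best <- v
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  opt$value <- best
  names(theta_hat) <- free
  p_hat <- assemble(theta_hat)
  y_fit <- m$fun(x, p_hat, kT, f_s)

  hess <- hessian_errors(cost_log, theta_hat, natural = exp(theta_hat))
  se <- rep(NA_real_, length(m$params))
  names(se) <- m$params
  se[free] <- hess$std_errors

  resid <- normalized_residuals(yhat, eta, y_fit)
  K <- length(free)
  rc <- reduced_chi2(resid, K)
  sp <- support(rc$chi2, rc$nu)
  ll <- gamma_loglik(yhat, eta, y_fit)

  structure(list(
    model = model, kind = kind,
    estimates = p_hat[m$params],
    free = free, fixed = fix,
    std_errors = se,
    cov = hess$cov, cov_log = hess$cov_log,
    hessian_ok = hess$ok,
    cost = opt$value, logLik = ll, K = K, n_y = length(x),
    kT = kT, f_s = f_s,
    diagnostics = list(chi2 = rc$chi2, nu = rc$nu, chi2_nu = rc$chi2_nu,
                       support = sp$support, p_value = sp$p_value,
                       AIC = aic(ll, K)),
    data = tibble::tibble(abscissa = x, value = yhat, shape = eta,
                          fitted = y_fit, residual = resid),
    cutoffs = cutoffs,
    convergence = opt$convergence,
    start = start_full
  ), class = "thermal_fit")
}

# Closed-form moment starts; crude but always inside the basin for
# well-posed spectra.
default_start <- function(kind, x, yhat, kT, f_s, params) {
  pos <- yhat > 0
  if (kind == "psd") {
    df <- x[2] - x[1]
    band_var <- 2 * sum(yhat) * df          # two-sided convention
    kappa0 <- kT / max(band_var, .Machine$double.eps)
    hi <- x >= quantile(x, 0.75)
    g_tail <- kT / (2 * pi^2 * x[hi & pos]^2 * yhat[hi & pos])
    gamma0 <- median(g_tail, na.rm = TRUE)
    eps0 <- sqrt(max(f_s * quantile(yhat[pos], 0.05), 1e-6))
  } else {
    kappa0 <- 0.336 * kT / max(yhat)
    gamma0 <- 2 * kT * x[1] / (3 * yhat[1])
    eps0 <- sqrt(max(yhat[1] * x[1] * f_s, 1e-4))
  }
  out <- c(gamma = unname(gamma0), kappa = unname(kappa0),
           epsilon = unname(eps0))
  out[!is.finite(out) | out <= 0] <- 1e-6
  extra <- setdiff(params, names(out))
  if (length(extra)) out[extra] <- 1      # user-defined models: unit start
  out
}

#' Invert the cost Hessian for parameter uncertainties
#'
#' Computes the Hessian of a cost function (negative log-likelihood) at its
#' minimum in log-parameter space by Richardson-extrapolated central
#' differences, inverts it for the log-scale covariance, and maps to the
#' natural scale by the delta method. If the Hessian is not positive
#' definite the function warns and returns `NA` errors rather than
#' pseudo-inverting (Monte-Carlo sampling is recommended in that case).
#'
#' @param cost Function of the free log-parameters returning the scalar
#'   cost.
#' @param at Numeric vector: the minimum, in log-parameter space.
#' @param natural Natural-scale parameter values `exp(at)` (used by the
#'   delta method); defaults to `exp(at)`.
#' @return List with `cov` (natural scale), `cov_log`, `std_errors`
#'   (natural scale, `NA` if indefinite), `ok` (logical).
#' @export
hessian_errors <- function(cost, at, natural = exp(at)) {
  H <- numDeriv::hessian(cost, at)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || any(ev <= 0)) {
    warn(paste("Cost Hessian is not positive definite at the reported",
               "minimum; standard errors unavailable. Consider",
               "mcmc_sample() for robust uncertainties."))
    k <- length(at)
    return(list(cov = matrix(NA_real_, k, k),
                cov_log = matrix(NA_real_, k, k),
                std_errors = rep(NA_real_, k), ok = FALSE))
  }
  cov_log <- solve(H)
  cov_log <- (cov_log + t(cov_log)) / 2
  D <- diag(natural, nrow = length(natural))
  cov_nat <- D %*% cov_log %*% D
  dimnames(cov_nat) <- dimnames(cov_log) <-
    list(names(at), names(at))
  list(cov = cov_nat, cov_log = cov_log,
       std_errors = sqrt(diag(cov_nat)), ok = TRUE)
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("Thermal-motion calibration fit: %s (%d points)\n",
              x$model, x$n_y))
  est <- x$estimates
  for (p in names(est)) {
    fixed <- p %in% names(x$fixed)
    se <- x$std_errors[[p]]
    unit <- c(gamma = "pN s/nm", kappa = "pN/nm", epsilon = "nm")[p]
    if (is.na(unit)) unit <- ""
    if (fixed) {
      cat(sprintf("  %-8s %.4g %s (fixed)\n", p, est[[p]], unit))
    } else {
      cat(sprintf("  %-8s %.4g +/- %.2g %s\n", p, est[[p]], se, unit))
    }
  }
  d <- x$diagnostics
  cat(sprintf("  chi2_nu = %.3f (nu = %d), support = %.3f, AIC = %.1f\n",
              d$chi2_nu, d$nu, d$support, d$AIC))
  invisible(x)
}
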