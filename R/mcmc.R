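#' Monte-Carlo sampling of the calibration likelihood
#'
#' Draws posterior samples of the free parameters (flat prior in log
#' space, i.e. the Gamma likelihood itself) with an affine-invariant
#' ensemble "stretch move" sampler: walkers are initialized in a small ball
#' around the maximum-likelihood point, each is updated by stretching along
#' the line to a walker from the complementary half-ensemble, and the first
#' quarter of the chain is discarded as burn-in. Robust to the parameter
#' correlations between \eqn{\gamma} and \eqn{\kappa} because the move is
#' invariant under affine reparameterization.
#'
#' @param fit A converged `thermal_fit` from [fit_thermal()].
#' @param walkers Number of walkers (>= 2 x free parameters; default 32).
#' @param steps Chain length per walker (default 2500).
#' @param burn_in Fraction of steps discarded (default 0.25).
#' @param seed Integer seed (required for reproducibility; same seed, same
#'   draws).
#' @param stretch Stretch-move scale parameter a (> 1, default 2).
#' @return A `thermal_posterior`: `draws` (tibble, one column per free
#'   parameter, natural scale), `summary` (tibble with median, 15.8th and
#'   84.2nd percentiles and their half-difference as `std_error`),
#'   `acceptance` fraction, `seed`. A warning is attached (and signalled)
#'   if the acceptance fraction leaves \[0.1, 0.9\].
#' @export
mcmc_sample <- function(fit, walkers = 32, steps = 2500, burn_in = 0.25,
                        seed = NULL, stretch = 2) {
  if (!inherits(fit, "thermal_fit")) {
    abort("`fit` must be a thermal_fit.", class = "beadcal_invalid_argument")
  }
  free <- fit$free
  k <- length(free)
  if (walkers < 2 * k || walkers < 4) {
    abort("Need at least max(4, 2 x free parameters) walkers.",
          class = "beadcal_invalid_argument")
  }
  m <- get_thermal_model(fit$model)
  x <- fit$data$abscissa
  yhat <- fit$data$value
  eta <- fit$data$shape
  kT <- fit$kT
  f_s <- fit$f_s
  p_full <- fit$estimates

  # negative cost = log-likelihood (up to a constant), vectorized over a
  # matrix of walker positions (rows = walkers, cols = log-parameters)
  log_prob <- function(theta_mat) {
    apply(theta_mat, 1L, function(tl) {
      p <- p_full
      p[free] <- exp(tl)
      yk <- tryCatch(m$fun(x, p, kT, f_s), error = function(e) NULL)
      if (is.null(yk) || any(!is.finite(yk)) || any(yk <= 0)) return(-Inf)
      -gamma_negloglik(yhat, eta, yk)
    })
  }

  run <- function() {
    theta0 <- log(fit$estimates[free])
    pos <- matrix(rep(theta0, each = walkers), nrow = walkers) +
      matrix(rnorm(walkers * k, 0, 1e-4), nrow = walkers)
    lp <- log_prob(pos)
    half <- walkers %/% 2L
    idx1 <- seq_len(half)
    idx2 <- (half + 1L):walkers
    chain <- array(NA_real_, dim = c(steps, walkers, k))
    accepted <- 0L
    for (s in seq_len(steps)) {
      for (side in 1:2) {
        mov <- if (side == 1) idx1 else idx2
        oth <- if (side == 1) idx2 else idx1
        z <- ((stretch - 1) * runif(length(mov)) + 1)^2 / stretch
        partner <- oth[sample.int(length(oth), length(mov), replace = TRUE)]
        prop <- pos[partner, , drop = FALSE] +
          z * (pos[mov, , drop = FALSE] - pos[partner, , drop = FALSE])
        lp_prop <- log_prob(prop)
        log_r <- (k - 1) * log(z) + lp_prop - lp[mov]
        acc <- log(runif(length(mov))) < log_r
        pos[mov[acc], ] <- prop[acc, , drop = FALSE]
        lp[mov[acc]] <- lp_prop[acc]
        accepted <- accepted + sum(acc)
      }
      chain[s, , ] <- pos
    }
    list(chain = chain, acceptance = accepted / (steps * walkers))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  keep <- seq.int(floor(steps * burn_in) + 1L, steps)
  draws_log <- matrix(res$chain[keep, , ], ncol = k)
  draws <- exp(draws_log)
  colnames(draws) <- free
  draws <- tibble::as_tibble(draws)

  summ <- purrr::map_dfr(free, function(p) {
    q <- quantile(draws[[p]], c(0.158, 0.5, 0.842), names = FALSE)
    tibble::tibble(term = p, median = q[2], q15.8 = q[1], q84.2 = q[3],
                   std_error = (q[3] - q[1]) / 2)
  })

  warning_msg <- NULL
  if (res$acceptance < 0.1 || res$acceptance > 0.9) {
    warning_msg <- sprintf(
      "MCMC acceptance fraction %.2f outside [0.1, 0.9]; intervals may be unreliable.",
      res$acceptance)
    warn(warning_msg)
  }
  mle_inside <- vapply(free, function(p) {
    est <- fit$estimates[[p]]
    s <- summ[summ$term == p, ]
    est >= s$q15.8 && est <= s$q84.2
  }, logical(1))
  if (!all(mle_inside)) {
    warning_msg <- paste(c(warning_msg,
      "MLE lies outside the 15.8-84.2 percentile interval for some parameter."),
      collapse = " ")
    warn("MLE lies outside the 15.8-84.2 percentile interval for some parameter.")
  }

  structure(list(draws = draws, summary = summ,
                 acceptance = res$acceptance,
                 walkers = walkers, steps = steps, burn_in = burn_in,
                 seed = seed, warning = warning_msg,
                 model = fit$model),
            class = "thermal_posterior")
}

#' @export
print.thermal_posterior <- function(x, ...) {
  cat(sprintf(
    "MCMC posterior: %d draws (%d walkers x %d steps, %.0f%% burn-in), acceptance %.2f\n",
    nrow(x$draws), x$walkers, x$steps, 100 * x$burn_in, x$acceptance))
  print(x$summary)
  invisible(x)
}
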