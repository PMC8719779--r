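#' Read a bead trajectory from a delimited text file
#'
#' Accepts one-column files (positions in nm, one per line; `f_s`
#' required) or two-column files (time in s, position in nm; `f_s` is
#' inferred from the time column, which must be uniform to a relative
#' tolerance of 1e-6). A header line is detected automatically; comma,
#' tab and whitespace delimiters are accepted.
#'
#' @param path File path.
#' @param f_s Sampling rate override (Hz); required for one-column files.
#' @return A `bead_trajectory`.
#' @export
read_trajectory <- function(path, f_s = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "beadcal_io_error")
  }
  df <- tryCatch(
    data.table::fread(path, header = "auto", data.table = FALSE),
    error = function(e) abort(sprintf("Could not parse '%s': %s", path,
                                      conditionMessage(e)),
                              class = "beadcal_io_error"))
  if (ncol(df) > 2L) {
    abort("Trajectory files must have one or two columns.",
          class = "beadcal_io_error")
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    abort("Trajectory file contains non-numeric rows.",
          class = "beadcal_io_error")
  }
  if (nrow(df) < 16L) {
    abort("Trajectory too short: need at least 16 samples.",
          class = "beadcal_too_short")
  }
  if (ncol(df) == 2L) {
    f_s_file <- infer_sampling_rate(df[[1]])
    if (is.null(f_s)) f_s <- f_s_file
    new_bead_trajectory(df[[2]], f_s)
  } else {
    if (is.null(f_s)) {
      abort("One-column trajectory file: supply `f_s` (Hz).",
            class = "beadcal_invalid_argument")
    }
    check_positive_scalar(f_s, "f_s")
    new_bead_trajectory(df[[1]], f_s)
  }
}

#' Write a bead trajectory as CSV
#'
#' Columns `time_s,position_nm`, with time = index / f_s; round-trips
#' through [read_trajectory()].
#'
#' @param trajectory A `bead_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  f_s <- sampling_rate(trajectory)
  df <- data.frame(time_s = trajectory$time,
                   position_nm = trajectory$position)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spectrum estimate as CSV (plus JSON metadata)
#'
#' Writes `abscissa,value,shape` rows; estimator metadata (kind, f_s,
#' N_x, bins) goes to a JSON sidecar.
#'
#' @param estimate A `spectrum_estimate`.
#' @param path Output CSV path.
#' @param meta_path JSON metadata path (default `path` with `.json`
#'   appended).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(estimate, path, meta_path = paste0(path, ".json")) {
  df <- data.frame(abscissa = abscissa_of(estimate),
                   value = estimate$value, shape = estimate$shape)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(kind = spectrum_kind(estimate), f_s = attr(estimate, "f_s"),
               n_x = attr(estimate, "n_x"), n_bins = attr(estimate, "n_bins"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a full calibration: trajectory to fitted parameters
#'
#' The end-to-end chain: spectrum estimation (Welch PSD or overlapping AV),
#' Gamma-likelihood model fit, diagnostics, and optionally MCMC
#' uncertainties. Returns a self-describing report that can be serialized
#' with [write_report()].
#'
#' @param trajectory A `bead_trajectory`, or a file path (read with
#'   [read_trajectory()]).
#' @param method `"psd"` or `"av"`.
#' @param model Registry key; defaults to the method's standard model.
#' @param bins Welch segment count (PSD only).
#' @param edf `"empirical"` or `"approx"` degrees of freedom (AV only).
#' @param kT Thermal energy, pN nm.
#' @param fix Named numeric vector of fixed parameters.
#' @param cutoffs Inclusive abscissa bounds `c(lo, hi)` (NA = open).
#' @param mcmc Run MCMC uncertainties as well (default `FALSE`).
#' @param seed Seed for MCMC.
#' @param f_s Sampling rate override for one-column input files.
#' @return A `calibration_report` list: input metadata, settings, fit
#'   results (estimates, errors, covariance, diagnostics, residual table),
#'   optional posterior summary, package version.
#' @examples
#' traj <- simulate_trajectory(n = 4096, seed = 11)
#' rep <- calibrate(traj, method = "av")
#' rep$fit$estimates
#' @export
calibrate <- function(trajectory, method = c("psd", "av"), model = NULL,
                      bins = 3, edf = c("empirical", "approx"), kT = 4.11,
                      fix = NULL, cutoffs = NULL, mcmc = FALSE, seed = NULL,
                      f_s = NULL) {
  method <- match.arg(method)
  edf <- match.arg(edf)
  input_file <- NA_character_
  if (is.character(trajectory)) {
    input_file <- trajectory
    trajectory <- read_trajectory(trajectory, f_s = f_s)
  } else {
    trajectory <- as_bead_trajectory(trajectory, f_s)
  }
  if (!is.null(model)) {
    mk <- get_thermal_model(model)
    if (mk$kind != method) {
      abort(sprintf("Model '%s' is a %s model; method is '%s'.",
                    model, toupper(mk$kind), method),
            class = "beadcal_model_kind_mismatch")
    }
  }
  est <- if (method == "psd") {
    psd_welch(trajectory, bins = bins)
  } else {
    avar_overlapping(trajectory, edf = edf)
  }
  fit <- fit_thermal(est, model = model, kT = kT, fix = fix,
                     cutoffs = cutoffs)
  posterior <- NULL
  if (isTRUE(mcmc)) {
    posterior <- mcmc_sample(fit, seed = seed)
  }
  structure(list(
    schema = "beadcal/calibration-report/v1",
    input = list(file = input_file, n_x = nrow(trajectory),
                 f_s = sampling_rate(trajectory)),
    settings = list(method = method, model = fit$model, bins = bins,
                    edf = edf, kT = kT,
                    fix = as.list(fix),
                    cutoffs = cutoffs, mcmc = isTRUE(mcmc), seed = seed),
    fit = list(estimates = as.list(fit$estimates),
               std_errors = as.list(fit$std_errors),
               covariance = fit$cov,
               cost = fit$cost, logLik = fit$logLik,
               n_y = fit$n_y, K = fit$K,
               diagnostics = fit$diagnostics),
    spectrum = as.data.frame(fit$data),
    posterior = if (!is.null(posterior)) {
      list(summary = as.data.frame(posterior$summary),
           acceptance = posterior$acceptance,
           walkers = posterior$walkers, steps = posterior$steps,
           seed = posterior$seed)
    },
    version = as.character(packageVersion("beadcal"))
  ), class = "calibration_report")
}

#' Serialize / restore a calibration report
#'
#' JSON with 17 significant digits so numeric fields round-trip exactly.
#'
#' @param report A `calibration_report`.
#' @param path Output path.
#' @return `path` invisibly ([write_report()]); a `calibration_report`
#'   ([read_report()]).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(rep, class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration report (%s): %s on %d samples at %g Hz\n",
              x$version, x$settings$method, x$input$n_x, x$input$f_s))
  est <- x$fit$estimates
  se <- x$fit$std_errors
  for (p in names(est)) {
    cat(sprintf("  %-8s %.4g +/- %.2g\n", p, est[[p]],
                if (is.null(se[[p]])) NA else se[[p]]))
  }
  d <- x$fit$diagnostics
  cat(sprintf("  chi2_nu = %.3f, support = %.3f, AIC = %.1f\n",
              d$chi2_nu, d$support, d$AIC))
  invisible(x)
}

#' Bias and error benchmark of the calibration methods
#'
#' Simulates an ensemble of bead trajectories at each requested corner
#' frequency (spring constant \eqn{\kappa = 2\pi\gamma f_c}), calibrates
#' each by both the PSD and AV routes, and reports the median ratio of
#' estimate to truth (bias) and of reported uncertainty to truth (error)
#' per parameter and method.
#'
#' @param f_c Corner frequencies to sweep, Hz.
#' @param replicates Trajectories per corner frequency.
#' @param n,f_s,gamma,kT,oversample Simulation settings (see
#'   [simulate_trajectory()]).
#' @param bins Welch segments for the PSD route.
#' @param fix_gamma Fix \eqn{\gamma} to truth during fitting (isolates
#'   \eqn{\kappa}, removing the parameter correlation that inflates its
#'   error at high corner frequencies).
#' @param seed Base seed; replicate r at sweep point i uses seed
#'   `seed + 1000*i + r`.
#' @return A tibble: `f_c`, `method`, `term`, `bias` (median estimate /
#'   truth), `error` (median reported sd / truth), `n_fail` (replicates
#'   whose fit errored).
#' @export
benchmark_bias <- function(f_c = c(0.2, 1, 5, 20, 100), replicates = 50,
                           n = 4096, f_s = 100, gamma = 1e-5, kT = 4.11,
                           oversample = 1000, bins = 3, fix_gamma = FALSE,
                           seed = 1) {
  purrr::map_dfr(seq_along(f_c), function(i) {
    fc <- f_c[i]
    kappa <- 2 * pi * gamma * fc
    truth <- c(gamma = gamma, kappa = kappa)
    res <- purrr::map(seq_len(replicates), function(r) {
      traj <- simulate_trajectory(n = n, f_s = f_s, gamma = gamma,
                                  kappa = kappa, kT = kT,
                                  oversample = oversample,
                                  seed = seed + 1000L * i + r)
      fx <- if (fix_gamma) c(gamma = gamma) else NULL
      fits <- list(
        psd = tryCatch(fit_thermal(psd_welch(traj, bins = bins), kT = kT,
                                   fix = fx),
                       error = function(e) NULL),
        av = tryCatch(fit_thermal(avar_overlapping(traj), kT = kT,
                                  fix = fx),
                      error = function(e) NULL))
      fits
    })
    purrr::map_dfr(c("psd", "av"), function(meth) {
      fits <- purrr::map(res, meth)
      ok <- !vapply(fits, is.null, logical(1))
      terms <- if (fix_gamma) "kappa" else c("gamma", "kappa")
      purrr::map_dfr(terms, function(p) {
        est <- vapply(fits[ok], function(f) f$estimates[[p]], numeric(1))
        err <- vapply(fits[ok], function(f) f$std_errors[[p]], numeric(1))
        tibble::tibble(f_c = fc, method = meth, term = p,
                       bias = median(est) / truth[[p]],
                       error = median(err, na.rm = TRUE) / truth[[p]],
                       n_fail = sum(!ok))
      })
    })
  })
}
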