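#' Overlapping Allan variance of a bead trajectory
#'
#' Computes the octave-sampled overlapping Allan variance: for bin lengths
#' \eqn{m_k = 2^k}, \eqn{k = 1..\lfloor\log_2(N_x/2)\rfloor}, one half the
#' mean squared difference between averages of adjacent length-\eqn{m_k}
#' windows separated by \eqn{m_k} samples, with start indices sliding one
#' sample at a time (\eqn{M = N_x - 2m_k + 1} window pairs). Observation
#' times are \eqn{\tau_k = m_k/f_s}. Implemented with cumulative sums, so
#' the cost is linear in \eqn{N_x} per observation time.
#'
#' Each AV value is treated as Gamma distributed with shape
#' \eqn{\eta_k = \nu_k/2}, where \eqn{\nu_k} is the equivalent degrees of
#' freedom of the overlapping estimator. By default \eqn{\nu_k} is computed
#' from the dominant power-law noise class at each observation time
#' (lag-1 autocorrelation identification, [identify_noise_lag1()]) and the
#' combined-edf formulas ([edf_empirical()]); points with
#' \eqn{N_x/m_k < 32} inherit the class of the last point with
#' \eqn{N_x/m_k > 32}. If identification fails entirely, a warning is
#' issued and the approximate dof \eqn{N_x/m_k - 1} is used. Set
#' `edf = "approx"` to use the approximate dof throughout.
#'
#' @inheritParams psd_welch
#' @param edf `"empirical"` (default) or `"approx"` — how to compute the
#'   per-point degrees of freedom.
#' @return A `spectrum_estimate` tibble with columns `tau` (s), `m` (bin
#'   length), `value` (nm^2), `shape` (Gamma shape = edf/2), `edf`,
#'   `alpha` (identified power-law exponent), `noise` (class label) and
#'   `noise_method` (`"lag1"` or `"fallback"`); attributes `kind = "av"`,
#'   `f_s`, `n_x`.
#' @examples
#' traj <- simulate_trajectory(n = 4096, seed = 1)
#' avar_overlapping(traj)
#' @export
avar_overlapping <- function(trajectory, edf = c("empirical", "approx"),
                             f_s = NULL) {
  edf <- match.arg(edf)
  traj <- as_bead_trajectory(trajectory, f_s)
  f_s <- sampling_rate(traj)
  x <- traj$position
  n_x <- length(x)
  if (n_x < 16L) {
    abort("Allan variance needs at least 16 samples.",
          class = "beadcal_too_short")
  }
  ks <- seq_len(floor(log2(n_x / 2)))
  ms <- 2L^ks
  S <- c(0, cumsum(x))
  av <- vapply(ms, function(m) {
    d <- (S[(2L * m + 1L):(n_x + 1L)] - 2 * S[(m + 1L):(n_x + 1L - m)] +
            S[1L:(n_x + 1L - 2L * m)]) / m
    sum(d^2) / (2 * length(d))
  }, numeric(1))

  if (edf == "approx") {
    nu <- n_x / ms - 1
    alpha <- rep(NA_integer_, length(ms))
    method <- rep("approx", length(ms))
  } else {
    alpha <- rep(NA_integer_, length(ms))
    method <- rep(NA_character_, length(ms))
    for (i in seq_along(ms)) {
      if (n_x / ms[i] >= 32) {
        a <- tryCatch(identify_noise_lag1(x, ms[i])$alpha,
                      error = function(e) NA_integer_)
        alpha[i] <- a
        method[i] <- "lag1"
      }
    }
    # fallback: points with N_x/m < 32 (or failed id) inherit the last
    # successfully identified class
    last <- NA_integer_
    for (i in seq_along(ms)) {
      if (is.na(alpha[i])) {
        alpha[i] <- last
        method[i] <- "fallback"
      } else {
        last <- alpha[i]
      }
    }
    if (anyNA(alpha)) {
      warn("Noise identification failed; falling back on approximate degrees of freedom N_x/m - 1.")
      nu <- n_x / ms - 1
      method <- rep("approx", length(ms))
    } else {
      nu <- vapply(seq_along(ms), function(i)
        edf_empirical(alpha[i], ms[i], n_x), numeric(1))
    }
  }

  out <- tibble::tibble(tau = ms / f_s, m = ms, value = av,
                        shape = nu / 2, edf = nu,
                        alpha = as.integer(alpha),
                        noise = noise_class_label(alpha),
                        noise_method = method)
  new_spectrum_estimate(out, kind = "av", f_s = f_s, n_x = n_x)
}

noise_class_label <- function(alpha) {
  dplyr::case_when(
    is.na(alpha) ~ NA_character_,
    alpha >= 1 ~ "above-white",
    alpha == 0 ~ "white",
    alpha == -1 ~ "flicker",
    alpha == -2 ~ "random-walk",
    TRUE ~ "drift"
  )
}

#' Approximate Allan-variance degrees of freedom
#'
#' The non-overlapping-bins approximation \eqn{\nu = N_x/m - 1}: the number
#' of independent successive differences of length-`m` bins in the
#' trajectory. Quick and noise-class-free, but it misstates the confidence
#' of the overlapping estimator (see [edf_empirical()]).
#'
#' @param m Bin length in samples.
#' @param n_x Trajectory length in samples (> m).
#' @return Degrees of freedom (real, > 0).
#' @examples
#' edf_approximate(m = 2, n_x = 4096)  # 2047
#' @export
edf_approximate <- function(m, n_x) {
  if (any(n_x <= m)) {
    abort("`n_x` must exceed `m`.", class = "beadcal_invalid_argument")
  }
  n_x / m - 1
}
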