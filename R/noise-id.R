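#' Identify the dominant power-law noise class by lag-1 autocorrelation
#'
#' Classifies the dominant power-law noise of a position series averaged in
#' non-overlapping bins of length `m`, using the lag-1 autocorrelation
#' statistic: the series is differenced until the quantity
#' \eqn{\delta = r_1/(1+r_1)} (with \eqn{r_1} the lag-1 autocorrelation)
#' drops below 1/4 or two differencing rounds have been applied, and the
#' continuous power-law exponent is read off as
#' \eqn{\alpha = -2(\delta + d)}, where `d` is the number of differencing
#' rounds. \eqn{\alpha} is the exponent of the position (frequency-like)
#' power spectrum: 0 for white position noise, -1 for flicker, -2 for
#' random-walk positions (free diffusion), below -2 for drift.
#'
#' Deterministic for a fixed series. Requires \eqn{N_x/m \ge 32}; for
#' shorter averaged series the statistic is too imprecise and the caller is
#' expected to reuse the class of the last observation time that satisfies
#' the bound (done automatically by [avar_overlapping()]).
#'
#' @param trajectory A `bead_trajectory`, data frame with a `position`
#'   column, or bare numeric vector of positions.
#' @param m Averaging bin length in samples (>= 1).
#' @return A one-row tibble: `m`, `alpha` (integer, clamped to
#'   \[-4, 2\]), `alpha_raw` (continuous estimate), `noise` (class label),
#'   `method = "lag1"`.
#' @export
identify_noise_lag1 <- function(trajectory, m = 1) {
  x <- if (is.data.frame(trajectory)) trajectory$position else trajectory
  n_x <- length(x)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m)) {
    abort("`m` must be an integer >= 1.", class = "beadcal_invalid_argument")
  }
  if (n_x / m < 32) {
    abort(sprintf(
      "Noise identification refused: N_x/m = %.1f < 32; reuse the class of the last observation time with N_x/m > 32.",
      n_x / m), class = "beadcal_noise_id_refused")
  }
  m <- as.integer(m)
  z <- if (m == 1L) x else
    colMeans(matrix(x[seq_len(m * (n_x %/% m))], nrow = m))
  d <- 0L
  repeat {
    r1 <- lag1_autocorrelation(z)
    delta <- r1 / (1 + r1)
    if (delta < 0.25 || d >= 2L) break
    z <- diff(z)
    d <- d + 1L
  }
  alpha_raw <- -2 * (delta + d)
  alpha <- as.integer(max(-4, min(2, round(alpha_raw))))
  tibble::tibble(m = m, alpha = alpha, alpha_raw = alpha_raw,
                 noise = noise_class_label(alpha), method = "lag1")
}

lag1_autocorrelation <- function(z) {
  z <- z - mean(z)
  denom <- sum(z^2)
  if (denom == 0) {
    abort("Constant series: lag-1 autocorrelation undefined.",
          class = "beadcal_degenerate_input")
  }
  sum(z[-length(z)] * z[-1]) / denom
}
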