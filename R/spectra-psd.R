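#' Experimental power spectral density by Welch's method
#'
#' Splits the trajectory into `bins` half-overlapping segments, removes each
#' segment's mean, applies a Hann window with the 8/3 power correction,
#' averages the per-segment periodograms frequency by frequency, and drops
#' the zero-frequency point. Each PSD value is (approximately) Gamma
#' distributed with shape equal to the number of segments, which is stored
#' per point for likelihood fitting.
#'
#' Conventions: segment length `L = 2*floor(n/(bins+1))` (even, so segments
#' overlap by exactly `L/2`; up to `L/2` trailing samples are discarded);
#' frequencies `f_k = k f_s/L` for `k = 1..L/2` (DC excluded, Nyquist
#' retained); the reported values are a two-sided spectral density shown on
#' positive frequencies, so a pure white-noise input of variance
#' \eqn{\epsilon^2} has expected level \eqn{\epsilon^2/f_s} at every
#' frequency, and the thermal models [psd_closed_form()] etc. apply
#' verbatim.
#'
#' @param trajectory A `bead_trajectory` (or anything accepted by
#'   [as_bead_trajectory()]).
#' @param bins Number of half-overlapping segments M (>= 1). The default 3
#'   favours low-frequency coverage; more bins reduce scatter at the price
#'   of low-frequency resolution.
#' @param detrend Remove each segment's mean before windowing (default
#'   `TRUE`); suppresses DC leakage from slow drift.
#' @param f_s Sampling rate override when `trajectory` is a bare vector.
#' @return A `spectrum_estimate` tibble with columns `frequency` (Hz),
#'   `value` (nm^2/Hz) and `shape` (Gamma shape, = `bins`), plus attributes
#'   `kind = "psd"`, `f_s`, `n_x`, `n_bins`, `bin_length`.
#' @examples
#' traj <- simulate_trajectory(n = 4096, seed = 1)
#' psd <- psd_welch(traj)
#' head(psd)
#' @export
psd_welch <- function(trajectory, bins = 3, detrend = TRUE, f_s = NULL) {
  traj <- as_bead_trajectory(trajectory, f_s)
  f_s <- sampling_rate(traj)
  x <- traj$position
  n_x <- length(x)
  if (!is.numeric(bins) || length(bins) != 1L || bins < 1 ||
      bins != floor(bins)) {
    abort("`bins` must be an integer >= 1.",
          class = "beadcal_invalid_argument")
  }
  bins <- as.integer(bins)
  L <- 2L * (n_x %/% (bins + 1L))
  if (L < 8L) {
    abort(sprintf(
      "Trajectory too short: %d segments need at least %d samples (segment length >= 8).",
      bins, 4L * (bins + 1L)), class = "beadcal_too_short")
  }
  w <- sqrt(8 / 3) * sin(pi * (0:(L - 1L)) / L)^2  # Hann, power-corrected
  step <- L %/% 2L
  kmax <- L %/% 2L
  acc <- numeric(kmax)
  for (b in seq_len(bins)) {
    seg <- x[((b - 1L) * step + 1L):((b - 1L) * step + L)]
    if (detrend) seg <- seg - mean(seg)
    X <- fft(w * seg)
    acc <- acc + (Mod(X[2:(kmax + 1L)])^2) / (L * f_s)
  }
  out <- tibble::tibble(frequency = (1:kmax) * f_s / L,
                        value = acc / bins,
                        shape = rep(as.numeric(bins), kmax))
  new_spectrum_estimate(out, kind = "psd", f_s = f_s, n_x = n_x,
                        n_bins = bins, bin_length = L)
}

new_spectrum_estimate <- function(df, kind, f_s, n_x, ...) {
  attr(df, "kind") <- kind
  attr(df, "f_s") <- f_s
  attr(df, "n_x") <- n_x
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("spectrum_estimate", class(df))
  df
}

spectrum_kind <- function(estimate) {
  kind <- attr(estimate, "kind")
  if (is.null(kind)) {
    abort("Not a spectrum_estimate (missing `kind` attribute).",
          class = "beadcal_invalid_argument")
  }
  kind
}

abscissa_of <- function(estimate) {
  if (spectrum_kind(estimate) == "psd") estimate$frequency else estimate$tau
}

#' Logarithmically bin a PSD estimate
#'
#' Averages PSD values within logarithmic frequency bins (arithmetic mean
#' of values, sum of Gamma shapes, geometric-mean abscissa); empty bins are
#' dropped. Intended for visualizing power-law behaviour only — binning
#' mixes frequencies with different expectations, so the result is flagged
#' unusable for fitting.
#'
#' @param estimate A PSD `spectrum_estimate` from [psd_welch()].
#' @param bins_per_decade Number of bins per decade of frequency.
#' @return A `spectrum_estimate` with attribute `fit_ok = FALSE`.
#' @export
log_bin_psd <- function(estimate, bins_per_decade = 10) {
  if (spectrum_kind(estimate) != "psd") {
    abort("log_bin_psd() applies to PSD estimates only.",
          class = "beadcal_invalid_argument")
  }
  check_positive_scalar(bins_per_decade, "bins_per_decade")
  binned <- estimate |>
    dplyr::mutate(.bin = floor(log10(.data$frequency) * bins_per_decade)) |>
    dplyr::summarise(frequency = exp(mean(log(.data$frequency))),
                     value = mean(.data$value),
                     shape = sum(.data$shape),
                     .by = ".bin") |>
    dplyr::select(!".bin") |>
    dplyr::arrange(.data$frequency)
  new_spectrum_estimate(binned, kind = "psd", f_s = attr(estimate, "f_s"),
                        n_x = attr(estimate, "n_x"),
                        n_bins = attr(estimate, "n_bins"),
                        fit_ok = FALSE)
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("# %s estimate: %d points from %d samples at %g Hz\n",
              toupper(spectrum_kind(x)), nrow(x), attr(x, "n_x"),
              attr(x, "f_s")))
  NextMethod()
}
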