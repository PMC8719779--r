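# Independent oracles used across the suite.

# Brute-force overlapping Allan variance: direct enumeration of window
# means and squared differences (the definition, no cumulative-sum trick).
avar_brute <- function(x, m) {
  n <- length(x)
  M <- n - 2 * m + 1
  stopifnot(M >= 1)
  d2 <- vapply(seq_len(M), function(i) {
    (mean(x[(i + m):(i + 2 * m - 1)]) - mean(x[i:(i + m - 1)]))^2
  }, numeric(1))
  sum(d2) / (2 * M)
}

# Exact equivalent dof of the overlapping AV estimator under a known data
# covariance: the estimator is a quadratic form y' B'B y / (2M), so
# nu = tr(C)^2 / tr(C^2) with C = B Sigma B'.
exact_edf_cov <- function(Sigma, m) {
  n <- nrow(Sigma)
  M <- n - 2 * m + 1
  B <- matrix(0, M, n)
  for (i in seq_len(M)) {
    B[i, i:(i + m - 1)] <- -1 / m
    B[i, (i + m):(i + 2 * m - 1)] <- 1 / m
  }
  C <- B %*% Sigma %*% t(B)
  sum(diag(C))^2 / sum(C * C)
}

# Covariance of camera-frame averages of a standard Wiener process
# (exposure-averaged free diffusion): unit frames [i-1, i].
cov_averaged_wiener <- function(n) {
  M <- outer(seq_len(n), seq_len(n), function(i, j) pmin(i, j) - 0.5)
  diag(M) <- seq_len(n) - 2 / 3
  M
}

# Draw a synthetic spectrum from the Gamma observation model at a given
# theory curve (parametric bootstrap of the likelihood's own assumptions).
draw_gamma_spectrum <- function(template, y_true) {
  out <- template
  out$value <- rgamma(length(y_true), shape = template$shape,
                      scale = y_true / template$shape)
  out
}

# Rebuild a spectrum_estimate after row subsetting (keeps attributes).
subset_spectrum <- function(estimate, keep) {
  out <- estimate[keep, ]
  for (a in c("kind", "f_s", "n_x", "n_bins", "bin_length")) {
    attr(out, a) <- attr(estimate, a)
  }
  class(out) <- class(estimate)
  out
}
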