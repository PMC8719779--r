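# Equivalent degrees of freedom of the overlapping Allan variance, by the
# combined-edf (generalized autocovariance) machinery. The AV point at bin
# length m is a quadratic form in the data; modelling the identified
# power-law noise, its chi-squared-equivalent dof is
#   nu = 2 E[sigma^2]^2 / Var[sigma^2]
#     = M sz(0)^2 / [ sz(0)^2 + (1-J/M) sz(J/S)^2
#                     + sum_{j=1}^{J-1} 2 (1-j/M) sz(j/S)^2 ],
# with M = N_x - 2m + 1 overlapping pairs, S = m, J = min(M, 3m), and
# sz the autocovariance of the double-differenced phase under the noise
# class. Camera frames are time-averages of the continuous process, so the
# accumulated phase is point-sampled and sz is built from the point-phase
# generalized autocovariances sw(t, alpha + 2); this reproduces the exact
# trace-formula edf for white and exposure-averaged random-walk positions.
# For alpha = +1, +2 (differenced-white-like classes, where the point-phase
# autocovariance degenerates) the published tabulated asymptotics are used.

# Generalized autocovariance sw_alpha(t); overall constants cancel in the
# edf ratio, only the shape in t matters.
gacv_sw <- function(t, alpha) {
  at <- abs(t)
  switch(as.character(alpha),
    "2" = -at,
    "1" = ifelse(at == 0, 0, t^2 * log(at)),
    "0" = at^3,
    "-1" = ifelse(at == 0, 0, -t^4 * log(at)),
    "-2" = -at^5,
    abort(sprintf("No generalized autocovariance for alpha = %s.", alpha),
          class = "beadcal_invalid_argument")
  )
}

# ACV of the averaged phase: F = averaging factor of the phase filter in
# units of m*tau_s; F = Inf is point-sampled phase.
gacv_sx <- function(t, F, alpha) {
  if (is.infinite(F)) return(gacv_sw(t, alpha + 2))
  F^2 * (2 * gacv_sw(t, alpha) - gacv_sw(t - 1 / F, alpha) -
           gacv_sw(t + 1 / F, alpha))
}

# ACV of the d = 2 (Allan) phase difference.
gacv_sz <- function(t, F, alpha) {
  6 * gacv_sx(t, F, alpha) - 4 * gacv_sx(t - 1, F, alpha) -
    4 * gacv_sx(t + 1, F, alpha) + gacv_sx(t - 2, F, alpha) +
    gacv_sx(t + 2, F, alpha)
}

edf_basic_sum <- function(J, M, S, F, alpha) {
  j <- seq_len(max(J - 1, 0))
  gacv_sz(0, F, alpha)^2 + (1 - J / M) * gacv_sz(J / S, F, alpha)^2 +
    sum(2 * (1 - j / M) * gacv_sz(j / S, F, alpha)^2)
}

#' Empirical degrees of freedom of an overlapping Allan-variance point
#'
#' Equivalent chi-squared degrees of freedom of the overlapping AV
#' estimator at bin length `m`, given the dominant power-law noise class
#' `alpha` at that observation time (0 white, -1 flicker, -2 random walk;
#' +1/+2 differenced-white-like; -3/-4 are treated as -2, the steepest
#' class the Allan difference can distinguish). See
#' [identify_noise_lag1()] for obtaining `alpha` and [edf_approximate()]
#' for the cruder non-overlapping approximation.
#'
#' @param alpha Integer power-law exponent of the position spectrum, or a
#'   one-row tibble as returned by [identify_noise_lag1()].
#' @param m Bin length in samples (>= 1).
#' @param n_x Trajectory length in samples (> 2m).
#' @return Degrees of freedom (real, > 0).
#' @examples
#' edf_empirical(0, m = 2, n_x = 4096)   # white positions
#' edf_empirical(-2, m = 2, n_x = 4096)  # free diffusion
#' @export
edf_empirical <- function(alpha, m, n_x) {
  if (is.data.frame(alpha)) alpha <- alpha$alpha
  if (length(alpha) != 1L || is.na(alpha) || alpha != round(alpha) ||
      alpha > 2 || alpha < -4) {
    abort("`alpha` must be a single integer in -4..2.",
          class = "beadcal_unknown_noise_class")
  }
  if (m < 1 || m != floor(m) || n_x < 2 * m) {
    abort("Need n_x >= 2m and integer m >= 1.",
          class = "beadcal_invalid_argument")
  }
  alpha <- max(alpha, -2)  # Allan (d = 2) difference caps the slope it sees
  M <- n_x - 2 * m + 1
  S <- m
  J <- min(M, 3 * m)
  r <- M / S
  if (alpha <= 0) {
    return(M * gacv_sz(0, Inf, alpha)^2 / edf_basic_sum(J, M, S, Inf, alpha))
  }
  if (alpha == 1) {
    if (J <= 100) {
      return(M * gacv_sz(0, m, 1)^2 / edf_basic_sum(J, M, S, m, 1))
    }
    b0 <- 15.23; b1 <- 12.0          # tabulated, d = 2
    if (r > 3) {
      a0 <- 790; a1 <- 410           # tabulated, d = 2
      return((b0 + b1 * log(m))^2 * r / (a0 - a1 / r))
    }
    mp <- 100 / r
    return((b0 + b1 * log(m))^2 * 100 /
             edf_basic_sum(100, 100, mp, mp, 1))
  }
  # alpha == 2: differenced-white positions
  if (ceiling(r) <= 2) {
    # too few pairs for the asymptotic form; fall back on the
    # non-overlapping approximation, floored at 1
    return(max(n_x / m - 1, 1))
  }
  a0 <- choose(8, 4) / choose(4, 2)^2  # 35/18
  a1 <- 1
  M / (a0 - a1 / r)
}
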