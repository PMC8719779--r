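kT <- 4.11

test_that("Lorentzian PSD has the documented plateau, half-power point and diffusive tail", {
  gamma <- 1e-5; kappa <- 1e-3
  f_c <- kappa / (2 * pi * gamma)
  plateau <- 2 * kT * gamma / kappa^2
  expect_equal(psd_lorentzian(0, gamma, kappa, kT), plateau)
  expect_equal(psd_lorentzian(f_c, gamma, kappa, kT), plateau / 2)
  expect_equal(psd_lorentzian(10 * f_c, gamma, kappa, kT),
               kT / (2 * pi^2 * gamma * (10 * f_c)^2), tolerance = 0.01)
})

test_that("exposure filter matches its closed form and limits", {
  tau0 <- 0.01
  expect_identical(exposure_filter(0, tau0), 1)
  expect_equal(exposure_filter(1 / tau0, tau0), 0)
  expect_equal(exposure_filter(1 / (2 * tau0), tau0), 4 / pi^2)
})

test_that("truncated alias sum agrees with the closed form across corner frequencies", {
  f_s <- 100
  withr::with_seed(4, {
    for (ratio in c(0.002, 0.01, 0.05, 0.2, 0.5)) {
      gamma <- 1e-5
      kappa <- 2 * pi * gamma * ratio * f_s
      f <- sort(runif(50, 1e-3 * f_s, 0.499 * f_s))
      s_sum <- psd_aliased_sum(f, gamma, kappa, kT, f_s, tol = 1e-8)
      s_cf <- psd_closed_form(f, gamma, kappa, kT, f_s)
      expect_lt(max(abs(s_sum / s_cf - 1)), 1e-6)
    }
  })
})

test_that("alias-sum truncation tolerance behaves like a convergent series", {
  f_s <- 100; gamma <- 1e-5; kappa <- 2 * pi * gamma * 20
  f <- c(5, 20, 45)
  v6 <- psd_aliased_sum(f, gamma, kappa, kT, f_s, tol = 1e-6)
  v7 <- psd_aliased_sum(f, gamma, kappa, kT, f_s, tol = 1e-7)
  expect_true(all(abs(v7 - v6) < 1e-6 * v6))
})

test_that("pure aliasing (negligible exposure) exceeds the unaliased Lorentzian everywhere", {
  f_s <- 100; gamma <- 1e-5; kappa <- 2 * pi * gamma * 5
  f <- seq(0.5, 49.5, by = 0.5)
  aliased <- psd_aliased_sum(f, gamma, kappa, kT, f_s, tau0 = 0)
  expect_true(all(aliased > psd_lorentzian(f, gamma, kappa, kT)))
})

test_that("closed-form PSD stays finite and positive for extremely stiff traps", {
  f_s <- 100; gamma <- 1e-5
  kappa <- 700 * gamma * f_s   # kappa/(gamma f_s) = 700
  v <- psd_closed_form(c(1, 25, 49.9), gamma, kappa, kT, f_s)
  expect_true(all(is.finite(v) & v > 0))
  kappa2 <- 3000 * gamma * f_s  # beyond sinh overflow without the guard
  v2 <- psd_closed_form(c(1, 25, 49.9), gamma, kappa2, kT, f_s)
  expect_true(all(is.finite(v2) & v2 > 0))
})

test_that("frequencies outside (0, f_s/2] are rejected", {
  expect_error(psd_closed_form(0, 1e-5, 1e-4, kT, 100))
  expect_error(psd_closed_form(51, 1e-5, 1e-4, kT, 100))
  expect_error(psd_aliased_sum(-1, 1e-5, 1e-4, kT, 100))
})

test_that("band variance of the blurred aliased PSD approaches kT/kappa for slow corners", {
  f_s <- 1000; gamma <- 1e-5
  for (ratio in c(0.001, 0.01, 0.1)) {
    kappa <- 2 * pi * gamma * ratio * f_s
    bv <- 2 * stats::integrate(function(f)
      psd_closed_form(f, gamma, kappa, kT, f_s),
      1e-9 * f_s, f_s / 2, rel.tol = 1e-9)$value
    expect_lt(bv, kT / kappa * (1 + 1e-9))
    expect_gt(bv, 0)
    if (ratio == 0.001) expect_equal(bv, kT / kappa, tolerance = 0.01)
  }
})

test_that("thermal AV peaks at 1.89 relaxation times with the documented limits", {
  gamma <- 2e-5; kappa <- 8e-4
  tau_c <- gamma / kappa
  peak <- optimize(function(tau) av_thermal(tau, gamma, kappa, kT),
                   interval = tau_c * c(0.05, 20), maximum = TRUE)$maximum
  expect_equal(peak / tau_c, 1.89, tolerance = 0.01)

  # short-time free-diffusion limit (series branch)
  tau <- tau_c * 1e-6
  expect_equal(av_thermal(tau, gamma, kappa, kT) / (2 * kT * tau / (3 * gamma)),
               1, tolerance = 1e-5)
  # long-time uncorrelated limit
  tau_long <- tau_c * 200
  expect_equal(av_thermal(tau_long, gamma, kappa, kT) /
                 (2 * kT * gamma / (kappa^2 * tau_long)), 1,
               tolerance = 0.02)
  # exact value at one relaxation time
  expect_equal(av_thermal(tau_c, gamma, kappa, kT),
               (kT / kappa) * (4 * exp(-1) - exp(-2) - 1), tolerance = 1e-12)
  # series/direct branches agree at the crossover
  a_cross <- c(0.0099, 0.0101) * tau_c
  direct <- function(tau) {
    a <- kappa * tau / gamma
    (2 * kT * gamma / (kappa^2 * tau)) *
      (1 + (2 / a) * exp(-a) - exp(-2 * a) / (2 * a) - 3 / (2 * a))
  }
  # both branches carry ~1e-9 relative error at the switch (series
  # truncation on one side, O(1/a) cancellation on the other)
  expect_equal(av_thermal(a_cross, gamma, kappa, kT), direct(a_cross),
               tolerance = 1e-7)
  expect_error(av_thermal(-1, gamma, kappa, kT))
})

test_that("thermal AV is unimodal and strictly positive", {
  gamma <- 1e-5; kappa <- 3e-4
  tau <- exp(seq(log(1e-4), log(1e3), length.out = 400)) * gamma / kappa
  v <- av_thermal(tau, gamma, kappa, kT)
  expect_true(all(v > 0))
  d <- diff(v)
  expect_equal(sum(diff(sign(d)) != 0), 1)  # one sign change: single peak
})

test_that("tracking-error terms are exactly additive and scale as documented", {
  gamma <- 1e-5; kappa <- 3e-4; f_s <- 1000
  f <- seq(1, 499, by = 7)
  base <- psd_closed_form(f, gamma, kappa, kT, f_s)
  expect_identical(psd_with_tracking(f, gamma, kappa, 0, kT, f_s), base)
  off10 <- psd_with_tracking(f, gamma, kappa, 10, kT, f_s) - base
  expect_equal(off10, rep(0.1, length(f)))
  off20 <- psd_with_tracking(f, gamma, kappa, 20, kT, f_s) - base
  expect_equal(off20, 4 * off10)

  tau <- 2^(1:8) / f_s
  a_base <- av_thermal(tau, gamma, kappa, kT)
  expect_identical(av_with_tracking(tau, gamma, kappa, 0, kT, f_s), a_base)
  extra <- av_with_tracking(tau, gamma, kappa, 10, kT, f_s) - a_base
  expect_equal(extra, 100 / (f_s * tau))
  expect_equal(av_with_tracking(1 / f_s, gamma, kappa, 10, kT, f_s) -
                 av_thermal(1 / f_s, gamma, kappa, kT), 100)
  # tracking term halves when tau doubles
  expect_equal(extra[2] / extra[1], 0.5)
})

test_that("the model registry exposes the five built-in curves and accepts user models", {
  keys <- list_thermal_models()$key
  expect_true(all(c("psd:lansdorp", "psd:lansdorp+tracking",
                    "psd:lorentzian-aliased", "av:lansdorp",
                    "av:lansdorp+tracking") %in% keys))
  register_thermal_model("av:flat-test", "av", params = "level",
                         fun = function(x, p, kT, f_s) rep(p[["level"]], length(x)))
  expect_true("av:flat-test" %in% list_thermal_models()$key)
  curve <- thermal_model_curve("av:flat-test", x = 1:5,
                               params = c(level = 2.5), f_s = 100)
  expect_equal(curve$value, rep(2.5, 5))
  expect_error(thermal_model_curve("av:lansdorp", 1:3, c(gamma = 1e-5),
                                   f_s = 100), "kappa")
  expect_error(thermal_model_curve("psd:nonexistent", 1:3, c(gamma = 1),
                                   f_s = 100), "Unknown model")
})
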