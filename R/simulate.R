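#' Simulate a trapped-bead trajectory by overdamped Langevin dynamics
#'
#' Generates the position of a bead held in a harmonic trap and subject to
#' thermal forces, as recorded by a video camera: the continuous
#' Ornstein--Uhlenbeck motion is propagated on a fine time grid and each
#' camera frame reports the average of `oversample` consecutive fine-step
#' positions, emulating a shutter that stays open for the whole sampling
#' interval (zero dead time). Optionally adds independent Gaussian
#' per-frame tracking error.
#'
#' The fine-step update is the exact Ornstein--Uhlenbeck transition
#' \deqn{x(t+\delta t) = x(t)\,e^{-\delta t/\tau_c} +
#'   \mathcal{N}\!\big(0,\ (k_BT/\kappa)(1 - e^{-2\delta t/\tau_c})\big),}
#' with \eqn{\tau_c = \gamma/\kappa}, which is distributionally exact at any
#' step size; \eqn{x(0)} is drawn from the stationary distribution
#' \eqn{\mathcal{N}(0, k_BT/\kappa)} so no burn-in is needed. The thermal
#' stream is drawn before the tracking-error stream, so runs that share a
#' seed but differ in `epsilon` share the same thermal noise.
#'
#' @param n Number of output samples (camera frames), at least 2.
#' @param f_s Sampling rate in Hz.
#' @param gamma Drag coefficient in pN s/nm.
#' @param kappa Trap spring constant in pN/nm.
#' @param kT Thermal energy in pN nm (default 4.11, i.e. T = 298 K).
#' @param epsilon Tracking-error standard deviation in nm (>= 0).
#' @param oversample Fine propagation steps per output sample; the fine step
#'   is \eqn{\delta t = 1/(\mathrm{oversample}\, f_s)}. Default 1000.
#'   `oversample = 1` gives instantaneously sampled (unblurred) positions.
#' @param seed Integer seed; when non-`NULL` the trajectory is a
#'   deterministic function of the arguments and the global RNG state is
#'   left untouched.
#'
#' @return A `bead_trajectory`: a tibble with columns `time` (s) and
#'   `position` (nm) and attributes `f_s` and `simulation` (the parameters
#'   used).
#' @examples
#' traj <- simulate_trajectory(n = 2048, f_s = 100, gamma = 1e-5,
#'                             kappa = 3.1e-3, seed = 1)
#' equipartition_kappa(traj)
#' @export
simulate_trajectory <- function(n = 4096, f_s = 100, gamma = 1e-5,
                                kappa = 2 * pi * gamma * 5, kT = 4.11,
                                epsilon = 0, oversample = 1000,
                                seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != floor(n)) {
    abort("`n` must be an integer >= 2.", class = "beadcal_invalid_argument")
  }
  check_positive_scalar(f_s, "f_s")
  check_positive_scalar(gamma, "gamma")
  check_positive_scalar(kappa, "kappa")
  check_positive_scalar(kT, "kT")
  check_positive_scalar(epsilon, "epsilon", strict = FALSE)
  if (!is.numeric(oversample) || length(oversample) != 1L || oversample < 1 ||
      oversample != floor(oversample)) {
    abort("`oversample` must be an integer >= 1.",
          class = "beadcal_invalid_argument")
  }
  n <- as.integer(n)
  oversample <- as.integer(oversample)

  draw <- function() {
    tau_c <- gamma / kappa
    dt <- 1 / (oversample * f_s)
    rho <- exp(-dt / tau_c)
    sd_stat <- sqrt(kT / kappa)
    n_fine <- n * oversample
    x0 <- rnorm(1L, 0, sd_stat)
    innov <- rnorm(n_fine, 0, sd_stat * sqrt(-expm1(-2 * dt / tau_c)))
    fine <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                     init = x0))
    pos <- if (oversample == 1L) fine else
      colMeans(matrix(fine, nrow = oversample))
    if (epsilon > 0) pos <- pos + rnorm(n, 0, epsilon)
    pos
  }
  pos <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  new_bead_trajectory(pos, f_s,
                      simulation = list(n = n, f_s = f_s, gamma = gamma,
                                        kappa = kappa, kT = kT,
                                        epsilon = epsilon,
                                        oversample = oversample, seed = seed))
}

new_bead_trajectory <- function(positions, f_s, simulation = NULL) {
  out <- tibble::tibble(time = (seq_along(positions) - 1) / f_s,
                        position = as.numeric(positions))
  attr(out, "f_s") <- f_s
  if (!is.null(simulation)) attr(out, "simulation") <- simulation
  class(out) <- c("bead_trajectory", class(out))
  out
}

#' Coerce positions to a bead trajectory
#'
#' @param x A numeric vector of positions (nm), or a data frame with a
#'   `position` column (and optionally a uniformly spaced `time` column,
#'   from which `f_s` is inferred).
#' @param f_s Sampling rate in Hz; required when `x` carries no time
#'   information.
#' @return A `bead_trajectory` tibble.
#' @export
as_bead_trajectory <- function(x, f_s = NULL) {
  if (inherits(x, "bead_trajectory") && is.null(f_s)) return(x)
  if (is.data.frame(x)) {
    if (!"position" %in% names(x)) {
      abort("Data frame input needs a `position` column.",
            class = "beadcal_invalid_argument")
    }
    if (is.null(f_s)) {
      if ("time" %in% names(x)) {
        f_s <- infer_sampling_rate(x$time)
      } else if (!is.null(attr(x, "f_s"))) {
        f_s <- attr(x, "f_s")
      } else {
        abort("Supply `f_s` (Hz): input has no time column.",
              class = "beadcal_invalid_argument")
      }
    }
    x <- x$position
  }
  if (is.null(f_s)) {
    abort("Supply `f_s` (Hz) for a bare position vector.",
          class = "beadcal_invalid_argument")
  }
  check_positive_scalar(f_s, "f_s")
  if (!all(is.finite(x))) {
    abort("All positions must be finite.", class = "beadcal_invalid_argument")
  }
  new_bead_trajectory(x, f_s)
}

sampling_rate <- function(traj) {
  f_s <- attr(traj, "f_s")
  if (is.null(f_s)) {
    abort("Trajectory has no `f_s` attribute; use `as_bead_trajectory()`.",
          class = "beadcal_invalid_argument")
  }
  f_s
}

infer_sampling_rate <- function(time, tol = 1e-6) {
  dt <- diff(time)
  if (length(dt) < 1L || any(dt <= 0)) {
    abort("Time column must be strictly increasing.",
          class = "beadcal_invalid_argument")
  }
  dt0 <- median(dt)
  if (any(abs(dt - dt0) > tol * dt0)) {
    abort("Time column is not uniformly spaced (relative tolerance 1e-6).",
          class = "beadcal_nonuniform_time")
  }
  1 / dt0
}

#' Spring constant by the equipartition theorem
#'
#' The stationary variance of a harmonically trapped bead is
#' \eqn{\sigma_x^2 = k_BT/\kappa}, so \eqn{\kappa = k_BT/\sigma_x^2}. This
#' estimator is biased low whenever parasitic noise (tracking error, drift)
#' inflates the variance, which is why spectral fits are preferred for
#' calibration; it remains useful as a quick check and as an initial guess.
#'
#' @param trajectory A `bead_trajectory` (or anything `as_bead_trajectory()`
#'   accepts, with `f_s` irrelevant here).
#' @param kT Thermal energy in pN nm.
#' @return Spring constant estimate in pN/nm.
#' @export
equipartition_kappa <- function(trajectory, kT = 4.11) {
  check_positive_scalar(kT, "kT")
  pos <- if (is.data.frame(trajectory)) trajectory$position else trajectory
  if (length(pos) < 2L) {
    abort("Need at least 2 positions.", class = "beadcal_invalid_argument")
  }
  v <- var(pos)
  if (v == 0) {
    abort("Position variance is zero; equipartition estimate undefined.",
          class = "beadcal_degenerate_input")
  }
  kT / v
}

#' Force on the bead from trap stiffness and tether length
#'
#' In the inverted-pendulum geometry of a magnetic-tweezers experiment the
#' applied force is `kappa * L`, with `L` the height of the bead above the
#' surface.
#'
#' @param kappa Spring constant in pN/nm (>= 0).
#' @param L Tether length / bead height in nm (>= 0).
#' @return Force in pN.
#' @examples
#' trap_force(kappa = 1e-3, L = 1000)  # 1 pN
#' @export
trap_force <- function(kappa, L) {
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    abort("`kappa` must be non-negative.", class = "beadcal_invalid_argument")
  }
  if (any(!is.finite(L)) || any(L < 0)) {
    abort("`L` must be non-negative.", class = "beadcal_invalid_argument")
  }
  kappa * L
}

#' @export
print.bead_trajectory <- function(x, ...) {
  f_s <- attr(x, "f_s")
  cat(sprintf("# Bead trajectory: %d samples at %g Hz (%.3g s)\n",
              nrow(x), f_s, nrow(x) / f_s))
  sim <- attr(x, "simulation")
  if (!is.null(sim)) {
    cat(sprintf(
      "# simulated: gamma = %g pN s/nm, kappa = %g pN/nm, kT = %g pN nm, epsilon = %g nm\n",
      sim$gamma, sim$kappa, sim$kT, sim$epsilon))
  }
  NextMethod()
}
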