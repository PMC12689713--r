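#' DKI signal model
#'
#' Evaluates the diffusional kurtosis imaging signal equation
#' \deqn{S(b) = S_0 \exp(-b D + b^2 D^2 K / 6)}
#' where `S0` is the ideal baseline signal at b = 0, `D` the diffusion
#' coefficient (mm^2/s) and `K` the dimensionless diffusional kurtosis.
#' All arguments are vectorized and recycled.
#'
#' @param b Diffusion weighting(s), s/mm^2, `>= 0`.
#' @param s0 Baseline signal(s), `> 0`.
#' @param d Diffusion coefficient(s) in mm^2/s (unscaled), `> 0`.
#' @param k Diffusional kurtosis value(s), `>= 0`.
#' @return Signal value(s); equals `s0` at `b = 0`.
#' @examples
#' dki_signal(1000, s0 = 1000, d = 1e-3, k = 0)   # 1000 * exp(-1)
#' @export
dki_signal <- function(b, s0, d, k) {
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(s0)) || any(s0 <= 0)) stop("s0 must be finite and > 0", call. = FALSE)
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be finite and > 0", call. = FALSE)
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0", call. = FALSE)
  s0 * exp(-b * d + b^2 * d^2 * k / 6)
}

#' Monotonic signal decay constraint
#'
#' The DKI exponent `-bD + b^2 D^2 K / 6` is decreasing for
#' `b < 3 / (D K)`, so the signal decays monotonically over the whole
#' acquired range exactly when `D * K < 3 / b_max` (strict). Parameter
#' draws violating the bound produce signals that rise again before
#' `b_max` and are rejected during synthesis.
#'
#' @param d Diffusion coefficient(s), mm^2/s, `> 0`.
#' @param k Kurtosis value(s), `>= 0`.
#' @param b_max Largest acquired b-value, s/mm^2, `> 0`.
#' @return Logical vector: `TRUE` where `d * k < 3 / b_max`.
#' @export
monotonic_decay_ok <- function(d, k, b_max) {
  .assert_scalar(b_max, "b_max", positive = TRUE)
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be finite and > 0", call. = FALSE)
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0", call. = FALSE)
  d * k < 3 / b_max
}

#' Rician noise simulation
#'
#' Magnitude-MR noise model: the noisy value is
#' \eqn{S' = \sqrt{S^2 + N(0,\sigma)^2}}, with a single zero-mean Gaussian
#' draw per signal value. The output never falls below the clean signal
#' and equals it exactly for `sigma = 0`. Draws come from R's global RNG
#' stream; seed with `set.seed()` (or the `seed` argument of the
#' higher-level generators) for reproducibility.
#'
#' @param signal Clean signal value(s), `>= 0`.
#' @param sigma Gaussian standard deviation, signal units, `>= 0`.
#' @return Noisy signal value(s), same length as `signal`.
#' @export
add_rician_noise <- function(signal, sigma) {
  .assert_scalar(sigma, "sigma", nonneg = TRUE)
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signal must be finite and >= 0", call. = FALSE)
  if (sigma == 0) return(signal)
  sqrt(signal^2 + rnorm(length(signal), 0, sigma)^2)
}

#' Noise ratio and its inverse
#'
#' The noise level of a simulation is controlled by the noise ratio
#' `NR = sigma / s0_mean`, sigma normalized by the mean baseline signal.
#' `sigma_for_noise_ratio()` is the exact multiplicative inverse.
#'
#' @param sigma Gaussian noise standard deviation, `>= 0`.
#' @param s0_mean Mean baseline signal used for normalization, `> 0`.
#' @return `noise_ratio()`: the dimensionless NR;
#'   `sigma_for_noise_ratio()`: sigma in signal units.
#' @examples
#' noise_ratio(32, 320)            # 0.1
#' sigma_for_noise_ratio(0.1, 320) # 32
#' @export
noise_ratio <- function(sigma, s0_mean) {
  .assert_scalar(sigma, "sigma", nonneg = TRUE)
  .assert_scalar(s0_mean, "s0_mean", positive = TRUE)
  sigma / s0_mean
}

#' @param nr Noise ratio, `>= 0`.
#' @rdname noise_ratio
#' @export
sigma_for_noise_ratio <- function(nr, s0_mean) {
  .assert_scalar(nr, "nr", nonneg = TRUE)
  .assert_scalar(s0_mean, "s0_mean", positive = TRUE)
  nr * s0_mean
}

#' Noise specification
#'
#' Couples sigma, the noise ratio and the normalizing mean baseline signal
#' so that `sigma == nr * s0_mean` always holds. Give either `nr` or
#' `sigma`; the other is derived.
#'
#' @param nr Noise ratio (give this or `sigma`).
#' @param sigma Gaussian SD in signal units.
#' @param s0_mean Mean baseline signal used for normalization.
#' @return An object of class `xq_noise` with fields `sigma`, `nr`,
#'   `s0_mean`.
#' @export
noise_spec <- function(nr = NULL, sigma = NULL, s0_mean) {
  .assert_scalar(s0_mean, "s0_mean", positive = TRUE)
  if (is.null(nr) == is.null(sigma))
    stop("give exactly one of `nr` or `sigma`", call. = FALSE)
  if (is.null(sigma)) sigma <- sigma_for_noise_ratio(nr, s0_mean)
  else nr <- noise_ratio(sigma, s0_mean)
  structure(list(sigma = sigma, nr = nr, s0_mean = s0_mean), class = "xq_noise")
}

#' @export
print.xq_noise <- function(x, ...) {
  cat(sprintf("<xq_noise> sigma = %g (NR = %g at mean S0 = %g)\n",
              x$sigma, x$nr, x$s0_mean))
  invisible(x)
}
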