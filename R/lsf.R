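#' Voxelwise least-squares DKI fitting
#'
#' The conventional baseline: minimizes
#' \eqn{\sum_j (S_j - S_0 e^{-b_j D + b_j^2 D^2 K / 6})^2}
#' over (S0, D, K) by Levenberg-Marquardt nonlinear least squares
#' ([minpack.lm::nls.lm]), initialized from an exact log-domain
#' quadratic solve of \eqn{\ln(S_j / S_0) = -b_j D + b_j^2 D^2 K / 6}.
#' On noise-free model signals the initializer is already exact, and the
#' LM polish is skipped whenever the initializer's residual is at
#' numerical tolerance. K is left unconstrained (negative fitted K is
#' reported as such) unless `clamp = TRUE`.
#'
#' @param signals Numeric vector of length N+1, ordered as the scheme's
#'   b-values; `signals[1]` is the b = 0 measurement and must be > 0.
#' @param scheme An [acquisition_scheme()].
#' @param clamp Constrain the fit to `S0 > 0, D > 0, K >= 0`?
#' @return A list: `s0`, `d` (mm^2/s), `k`, `converged` (logical),
#'   `rss` (residual sum of squares).
#' @export
lsf_fit_voxel <- function(signals, scheme, clamp = FALSE) {
  stopifnot(inherits(scheme, "xq_scheme"))
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme$bvalues))
    stop("signal vector length does not match the scheme", call. = FALSE)
  if (all(signals == 0))
    return(list(s0 = 0, d = 0, k = 0, converged = FALSE, rss = 0))
  if (signals[1L] <= 0)
    stop("b = 0 signal must be positive", call. = FALSE)
  .lsf_fit_one(signals, scheme$bvalues, .lsf_basis(scheme), clamp)
}

## Cached log-domain design matrix [ -b, b^2 ] and its pseudo-inverse.
.lsf_basis <- function(scheme) {
  b <- scheme$bvalues[-1L]
  B <- cbind(-b, b^2)
  list(b = scheme$bvalues, B = B, pinv = solve(crossprod(B), t(B)))
}

.lsf_init <- function(signals, basis) {
  b <- basis$b[-1L]
  y <- log(pmax(signals[-1L], 1e-300) / signals[1L])
  cf <- basis$pinv %*% y
  d0 <- cf[1L]
  k0 <- if (d0 > 0) 6 * cf[2L] / d0^2 else 0
  if (!is.finite(d0) || d0 <= 0) d0 <- 1e-5
  if (!is.finite(k0)) k0 <- 0
  c(s0 = signals[1L], d = d0, k = k0)
}

.lsf_fit_one <- function(signals, bvalues, basis, clamp = FALSE) {
  p0 <- .lsf_init(signals, basis)
  resid_fn <- function(p)
    signals - p[1L] * exp(-bvalues * p[2L] + bvalues^2 * p[2L]^2 * p[3L] / 6)
  r0 <- resid_fn(p0)
  rss0 <- sum(r0^2)
  ## exact-fit short circuit: log-domain solve is the exact solution on
  ## noise-free model signals
  if (rss0 <= (1e-10 * signals[1L])^2 * length(signals))
    return(list(s0 = unname(p0[1L]), d = unname(p0[2L]), k = unname(p0[3L]),
                converged = TRUE, rss = rss0))
  lower <- if (clamp) c(1e-12, 1e-12, 0) else rep(-Inf, 3)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(s0 = unname(p0[1L]), d = unname(p0[2L]), k = unname(p0[3L]),
                converged = FALSE, rss = rss0))
  p <- fit$par
  list(s0 = unname(p[1L]), d = unname(p[2L]), k = unname(p[3L]),
       converged = fit$info %in% 1:4, rss = sum(resid_fn(p)^2))
}

#' Least-squares fitting over a volume
#'
#' Applies [lsf_fit_voxel()] to every foreground voxel of a 4D DWI
#' volume. Background voxels (b = 0 signal below `1e-6 * max`) are
#' skipped and zero-filled.
#'
#' @param dwi 4D array (x, y, z, volume) or `RNifti` image.
#' @param scheme An [acquisition_scheme()].
#' @param clamp Passed to [lsf_fit_voxel()].
#' @return A list of 3D arrays `s0`, `d`, `k`, plus logical `converged`
#'   and `fitted` masks.
#' @export
lsf_fit_volume <- function(dwi, scheme, clamp = FALSE) {
  stopifnot(inherits(scheme, "xq_scheme"))
  dwi <- .as_dwi_array(dwi)
  if (dim(dwi)[4L] != length(scheme$bvalues))
    stop("4th dimension of the volume does not match the scheme", call. = FALSE)
  dm <- dim(dwi)[1:3]
  nv <- prod(dm)
  sig <- matrix(dwi, nv, dim(dwi)[4L])
  eps <- 1e-6 * max(sig[, 1L])
  fg <- which(sig[, 1L] > eps)
  s0 <- d <- k <- numeric(nv)
  conv <- logical(nv)
  basis <- .lsf_basis(scheme)
  bv <- scheme$bvalues
  for (v in fg) {
    f <- .lsf_fit_one(sig[v, ], bv, basis, clamp)
    s0[v] <- f$s0; d[v] <- f$d; k[v] <- f$k; conv[v] <- f$converged
  }
  fitted <- logical(nv)
  fitted[fg] <- TRUE
  list(s0 = array(s0, dm), d = array(d, dm), k = array(k, dm),
       converged = array(conv, dm), fitted = array(fitted, dm))
}
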