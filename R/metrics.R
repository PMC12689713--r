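#' Signed-error statistics over a mask
#'
#' Errors are `est - truth` over the mask; reported as root-mean-square,
#' minimum and maximum (signed, so negative minima indicate
#' underestimation).
#'
#' @param est,truth Numeric arrays of identical shape.
#' @param mask Logical array of the same shape (default: everywhere).
#' @return A list with `rms`, `min`, `max`, `n`.
#' @export
signed_error_stats <- function(est, truth, mask = NULL) {
  if (!identical(dim(est), dim(truth)))
    stop("est and truth shapes differ", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, length(est))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  err <- (est - truth)[mask]
  list(rms = sqrt(mean(err^2)), min = min(err), max = max(err),
       n = length(err))
}

#' Region-wise signal-to-noise ratio of a parameter map
#'
#' Per labelled uniform region, SNR is mean / SD of the map values inside
#' the region; the reported value is the mean of the per-region SNRs.
#' Constant regions (SD = 0) are flagged infinite and excluded from the
#' average (if every region is constant the result is `Inf`).
#'
#' @param map Numeric array.
#' @param labels Integer array of region labels (0 = outside) or a
#'   logical mask (treated as one region).
#' @return A list: `snr` (scalar), `regions` (data.frame with per-region
#'   label, n, mean, sd, snr).
#' @export
region_snr <- function(map, labels) {
  if (is.logical(labels)) labels <- array(as.integer(labels), dim(labels))
  if (!identical(dim(map), dim(labels)))
    stop("map and labels shapes differ", call. = FALSE)
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs)) stop("no labelled voxels", call. = FALSE)
  rows <- lapply(labs, function(l) {
    v <- map[labels == l]
    s <- if (length(v) > 1L) sd(v) else 0
    data.frame(label = l, n = length(v), mean = mean(v), sd = s,
               snr = if (s == 0) Inf else mean(v) / s)
  })
  regions <- do.call(rbind, rows)
  fin <- is.finite(regions$snr)
  list(snr = if (any(fin)) mean(regions$snr[fin]) else Inf,
       regions = regions)
}

#' Contrast-to-noise ratio between two regions
#'
#' Pooled-SD definition:
#' \eqn{CNR = |\mu_{fg} - \mu_{bg}| / \sqrt{\sigma_{fg}^2 + \sigma_{bg}^2}}.
#' Symmetric in the two masks.
#'
#' @param map Numeric array.
#' @param fg,bg Logical masks (foreground / background), non-empty.
#' @return Scalar CNR.
#' @export
cnr <- function(map, fg, bg) {
  if (!any(fg) || !any(bg)) stop("fg/bg mask is empty", call. = FALSE)
  vf <- map[fg]; vb <- map[bg]
  sf <- if (length(vf) > 1L) sd(vf) else 0
  sb <- if (length(vb) > 1L) sd(vb) else 0
  denom <- sqrt(sf^2 + sb^2)
  if (denom == 0) stop("both regions have zero variance", call. = FALSE)
  abs(mean(vf) - mean(vb)) / denom
}

## separable Gaussian filtering with half-sample symmetric boundaries
.gauss_kernel <- function(sigma, truncate = 3.5) {
  r <- as.integer(truncate * sigma + 0.5)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

.filter_rows_sym <- function(m, kern) {
  r <- (length(kern) - 1L) %/% 2L
  n <- nrow(m)
  if (r >= n) stop("image smaller than the filter window", call. = FALSE)
  P <- m[c(r:1, 1:n, n:(n - r + 1L)), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(kern))
    out <- out + kern[t] * P[(t - 1L) + (1:n), , drop = FALSE]
  out
}

.gauss_filter2 <- function(m, kern) {
  t(.filter_rows_sym(t(.filter_rows_sym(m, kern)), kern))
}

## SSIM map of one 2D slice (Gaussian-weighted local statistics,
## biased covariances, standard constants)
.ssim_slice <- function(x, y, data_range, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  kern <- .gauss_kernel(sigma)
  ux <- .gauss_filter2(x, kern)
  uy <- .gauss_filter2(y, kern)
  uxx <- .gauss_filter2(x * x, kern)
  uyy <- .gauss_filter2(y * y, kern)
  uxy <- .gauss_filter2(x * y, kern)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  vxy <- uxy - ux * uy
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
}

#' Structural similarity between two parameter maps
#'
#' Slice-wise 2D SSIM with Gaussian-weighted windows (SD 1.5, truncated
#' at 3.5 SD), constants K1 = 0.01, K2 = 0.03 and, by default, the
#' dynamic range of the truth map. The per-voxel SSIM map is averaged
#' over the mask; a border of the filter radius is excluded from the
#' average in each slice (the local statistics there are
#' boundary-extrapolated).
#'
#' @param est,truth Numeric arrays, 2D or 3D, identical shape.
#' @param mask Optional logical array; average restricted to it.
#' @param data_range Dynamic range L; default `max(truth) - min(truth)`.
#' @param sigma Gaussian window SD in voxels.
#' @return Scalar mean SSIM in `[-1, 1]`.
#' @export
map_ssim <- function(est, truth, mask = NULL, data_range = NULL, sigma = 1.5) {
  if (!identical(dim(est), dim(truth)))
    stop("est and truth shapes differ", call. = FALSE)
  if (is.null(data_range)) data_range <- diff(range(truth))
  if (data_range <= 0) stop("truth map is constant; give data_range", call. = FALSE)
  d <- dim(est)
  if (length(d) == 2L) {
    dim(est) <- c(d, 1L)
    dim(truth) <- c(d, 1L)
    if (!is.null(mask)) dim(mask) <- c(d, 1L)
    d <- dim(est)
  }
  r <- (length(.gauss_kernel(sigma)) - 1L) %/% 2L
  if (d[1L] <= 2L * r || d[2L] <= 2L * r)
    stop("slice smaller than the filter window", call. = FALSE)
  interior <- array(FALSE, d)
  interior[(r + 1L):(d[1L] - r), (r + 1L):(d[2L] - r), ] <- TRUE
  keep <- if (is.null(mask)) interior else (mask & interior)
  if (!any(keep))
    stop("mask is empty after excluding the filter border", call. = FALSE)
  vals <- array(NA_real_, d)
  for (z in seq_len(d[3L]))
    vals[, , z] <- .ssim_slice(est[, , z], truth[, , z], data_range, sigma)
  mean(vals[keep])
}
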