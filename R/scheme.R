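#' Diffusion-weighting acquisition scheme
#'
#' A scheme is the ordered list of b-values of one acquisition. A single
#' `b = 0` volume is assumed, followed by `N >= 2` strictly increasing
#' non-zero b-values (the 1D Q-space sampling used for isotropic DKI).
#'
#' @param bvalues Numeric vector of b-values in s/mm^2. The first entry
#'   must be the single `b = 0` acquisition; the remaining entries must be
#'   strictly positive and strictly increasing.
#' @return An object of class `xq_scheme` with elements `bvalues`,
#'   `n_nonzero` (N) and `b_max`.
#' @examples
#' sch <- acquisition_scheme(c(0, 500, 1000, 2000))
#' sch$b_max
#' @export
acquisition_scheme <- function(bvalues) {
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) < 3L)
    stop("need a b = 0 entry plus at least two non-zero b-values", call. = FALSE)
  if (any(!is.finite(bvalues)))
    stop("b-values must be finite", call. = FALSE)
  if (bvalues[1L] != 0)
    stop("the first b-value must be 0 (single b = 0 acquisition)", call. = FALSE)
  nz <- bvalues[-1L]
  if (any(nz <= 0))
    stop("exactly one zero b-value is allowed, at position 1", call. = FALSE)
  if (any(diff(nz) <= 0))
    stop("non-zero b-values must be strictly increasing", call. = FALSE)
  structure(
    list(bvalues = bvalues,
         n_nonzero = length(nz),
         b_max = bvalues[length(bvalues)]),
    class = "xq_scheme"
  )
}

#' Breast DKI b-value scheme
#'
#' The clinical breast protocol used throughout the package's experiments:
#' b = 0, 50, 850, 1000, 1500, 2000 and 2500 s/mm^2 (N = 6).
#'
#' @return An `xq_scheme`.
#' @export
breast_dki_scheme <- function() {
  acquisition_scheme(c(0, 50, 850, 1000, 1500, 2000, 2500))
}

#' Read / write FSL-style bval files
#'
#' A bval file is a plain-text file of whitespace-separated b-values on one
#' (or more) lines, as written by FSL and most DICOM converters.
#'
#' @param path File path.
#' @return `read_bvals()` returns an [acquisition_scheme()].
#' @export
read_bvals <- function(path) {
  acquisition_scheme(scan(path, what = numeric(), quiet = TRUE))
}

#' @param scheme An `xq_scheme` (or bare numeric vector of b-values).
#' @rdname read_bvals
#' @export
write_bvals <- function(scheme, path) {
  b <- if (inherits(scheme, "xq_scheme")) scheme$bvalues else as.numeric(scheme)
  writeLines(paste(format(b, trim = TRUE, scientific = FALSE), collapse = " "), path)
  invisible(path)
}

#' @export
print.xq_scheme <- function(x, ...) {
  cat("<xq_scheme> b =", paste(x$bvalues, collapse = ", "),
      sprintf("s/mm^2 (N = %d, b_max = %g)\n", x$n_nonzero, x$b_max))
  invisible(x)
}
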