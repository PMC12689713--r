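#' Parameter ranges for DKI synthesis
#'
#' Uniform sampling ranges for the center-voxel parameters and for the
#' basis-combination weights. Defaults are the standard synthesis
#' conditions: S0 in [500, 8000], D in [0.2, 6.0] (scaled), K in
#' [0, 4], weights in [-4000, 4000] for S0 and [-0.5, 0.5] (scaled /
#' dimensionless) for D and K, with the joint bound `D * K < 3 / b_max`.
#'
#' Diffusivity arguments (`d`, `w_d`) are given in the conventional
#' scaled unit of 1e-3 mm^2/s and converted to mm^2/s internally; this
#' constructor is the only place that conversion happens on input.
#'
#' @param s0 Length-2 range for the baseline signal (arbitrary units).
#' @param d Length-2 range for D, scaled units (1e-3 mm^2/s).
#' @param k Length-2 range for K (dimensionless).
#' @param w_s0,w_d,w_k Length-2 weight ranges per basis for the S0, D and
#'   K patterns (`w_d` in scaled units).
#' @return An object of class `xq_ranges`; `d` and `w_d` are stored
#'   unscaled (mm^2/s).
#' @export
dki_ranges <- function(s0 = c(500, 8000),
                       d = c(0.2, 6.0),
                       k = c(0.0, 4.0),
                       w_s0 = c(-4000, 4000),
                       w_d = c(-0.5, 0.5),
                       w_k = c(-0.5, 0.5)) {
  ## degenerate (min == max) ranges are allowed: they pin a parameter or
  ## weight to a constant, which controlled simulations rely on
  chk <- function(r, name) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L])
      stop(sprintf("`%s` must be a finite (min, max) pair with min <= max", name),
           call. = FALSE)
    as.numeric(r)
  }
  structure(
    list(s0 = chk(s0, "s0"),
         d = chk(d, "d") / .D_SCALE,
         k = chk(k, "k"),
         w_s0 = chk(w_s0, "w_s0"),
         w_d = chk(w_d, "w_d") / .D_SCALE,
         w_k = chk(w_k, "w_k")),
    class = "xq_ranges"
  )
}

#' @export
print.xq_ranges <- function(x, ...) {
  cat("<xq_ranges>\n")
  cat(sprintf("  S0 in [%g, %g], D in [%g, %g] x1e-3 mm^2/s, K in [%g, %g]\n",
              x$s0[1], x$s0[2], x$d[1] * .D_SCALE, x$d[2] * .D_SCALE,
              x$k[1], x$k[2]))
  cat(sprintf("  weights: S0 [%g, %g], D [%g, %g] x1e-3, K [%g, %g]\n",
              x$w_s0[1], x$w_s0[2], x$w_d[1] * .D_SCALE, x$w_d[2] * .D_SCALE,
              x$w_k[1], x$w_k[2]))
  invisible(x)
}
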