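#' Digital phantom specification
#'
#' Describes a region-wise constant ground-truth parameter volume used
#' for benchmarking: three slabs with distinct baseline signals S0, each
#' holding a K = 0 backing region plus four K != 0 boxes, giving three
#' S0 levels, three distinct D values and five distinct K values overall
#' (background outside the slabs is S0 = 0). All triples respect
#' positivity and the monotonic-decay bound for the given `b_max`. The
#' region geometry and values are fully configurable; the defaults are
#' the package's benchmark layout.
#'
#' @param dims Integer grid dimensions, default `c(128, 128, 128)`.
#' @param s0_levels Baseline signal per slab (3 values).
#' @param d_background Backing-region D, scaled units (1e-3 mm^2/s).
#' @param dk_boxes 2-column matrix (or data.frame) of `(d, k)` per inner
#'   box, `d` in scaled units; one box per row, recycled over slabs.
#' @param sigma Default Rician noise SD for derived DWI volumes (32
#'   gives NR = 0.1 at the S0 = 320 slab).
#' @param b_max Largest b-value used to check the decay bound.
#' @param margin_frac Fractional margin of S0 = 0 background around each
#'   slab's interior.
#' @param regions Optional pre-built region data.frame (columns `x0`,
#'   `x1`, `y0`, `y1`, `z0`, `z1`, `s0`, `d` in mm^2/s, `k`, `role`,
#'   `slab`); overrides the generated layout entirely. May be empty
#'   (all-zero phantom).
#' @return An object of class `xq_phantom_spec` with a `regions`
#'   data.frame (one row per painted region: bounds, values, role).
#' @export
phantom_spec <- function(dims = c(128, 128, 128),
                         s0_levels = c(240, 320, 400),
                         d_background = 1.0,
                         dk_boxes = cbind(d = c(0.5, 1.0, 2.0, 2.0),
                                          k = c(1.0, 0.75, 0.5, 0.25)),
                         sigma = 32,
                         b_max = 2500,
                         margin_frac = 0.08,
                         regions = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    regions$label <- seq_len(nrow(regions))
    return(structure(list(dims = dims, regions = regions, sigma = sigma,
                          b_max = b_max,
                          s0_levels = sort(unique(regions$s0))),
                     class = "xq_phantom_spec"))
  }
  stopifnot(all(dims >= 8L), length(s0_levels) >= 1L)
  dk_boxes <- as.data.frame(dk_boxes)
  names(dk_boxes) <- c("d", "k")
  dk_boxes$d <- dk_boxes$d / .D_SCALE
  d_background <- d_background / .D_SCALE
  bad <- !monotonic_decay_ok(dk_boxes$d, dk_boxes$k, b_max)
  if (any(bad))
    stop("dk_boxes rows violate D*K < 3/b_max: ",
         paste(which(bad), collapse = ", "), call. = FALSE)

  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  ns <- length(s0_levels)
  my <- max(1L, round(margin_frac * ny))
  mz <- max(1L, round(margin_frac * nz))
  regions <- list()
  for (s in seq_len(ns)) {
    x0 <- floor((s - 1L) * nx / ns) + 1L
    x1 <- floor(s * nx / ns)
    mx <- max(1L, round(margin_frac * (x1 - x0 + 1L)))
    xi <- c(x0 + mx, x1 - mx)
    yi <- c(1L + my, ny - my)
    zi <- c(1L + mz, nz - mz)
    regions[[length(regions) + 1L]] <-
      data.frame(x0 = xi[1], x1 = xi[2], y0 = yi[1], y1 = yi[2],
                 z0 = zi[1], z1 = zi[2],
                 s0 = s0_levels[s], d = d_background, k = 0,
                 role = "background", slab = s)
    ## 2 x 2 inner boxes over (y, z), gap-separated from the backing rim
    hy <- floor((yi[2] - yi[1] + 1L) / 2L)
    hz <- floor((zi[2] - zi[1] + 1L) / 2L)
    gy <- max(1L, round(0.15 * hy))
    gz <- max(1L, round(0.15 * hz))
    box <- 0L
    for (iz in 0:1) for (iy in 0:1) {
      box <- box + 1L
      dk <- dk_boxes[(box - 1L) %% nrow(dk_boxes) + 1L, ]
      regions[[length(regions) + 1L]] <-
        data.frame(x0 = xi[1] + mx, x1 = xi[2] - mx,
                   y0 = yi[1] + iy * hy + gy, y1 = yi[1] + (iy + 1L) * hy - gy,
                   z0 = zi[1] + iz * hz + gz, z1 = zi[1] + (iz + 1L) * hz - gz,
                   s0 = s0_levels[s], d = dk$d, k = dk$k,
                   role = "box", slab = s)
    }
  }
  regions <- do.call(rbind, regions)
  regions$label <- seq_len(nrow(regions))
  ## boxes must not overlap each other (backing regions are painted
  ## first and then carved by the boxes)
  bx <- regions[regions$role == "box", ]
  if (nrow(bx) > 1L) {
    for (i in seq_len(nrow(bx) - 1L)) for (j in (i + 1L):nrow(bx)) {
      if (bx$x0[j] <= bx$x1[i] && bx$x1[j] >= bx$x0[i] &&
          bx$y0[j] <= bx$y1[i] && bx$y1[j] >= bx$y0[i] &&
          bx$z0[j] <= bx$z1[i] && bx$z1[j] >= bx$z0[i])
        stop("phantom boxes overlap", call. = FALSE)
    }
  }
  structure(list(dims = dims, regions = regions, sigma = sigma,
                 b_max = b_max, s0_levels = s0_levels),
            class = "xq_phantom_spec")
}

#' Build the ground-truth parameter volume of a phantom
#'
#' Paints the spec's regions (backing regions first, inner boxes on top)
#' into constant-valued 3D parameter maps plus an integer label map.
#' Everything outside painted regions is S0 = D = K = 0 background.
#'
#' @param spec An [phantom_spec()].
#' @return An object of class `xq_phantom_volume`: 3D arrays `s0`, `d`
#'   (mm^2/s), `k`, integer `labels`, and the `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "xq_phantom_spec"))
  dm <- spec$dims
  s0 <- array(0, dm); d <- array(0, dm); k <- array(0, dm)
  labels <- array(0L, dm)
  rg <- spec$regions
  if (NROW(rg) > 0L)
    rg <- rg[order(rg$role == "box"), ]   # backgrounds first, boxes on top
  for (i in seq_len(NROW(rg))) {
    r <- rg[i, ]
    xs <- r$x0:r$x1; ys <- r$y0:r$y1; zs <- r$z0:r$z1
    s0[xs, ys, zs] <- r$s0
    d[xs, ys, zs] <- r$d
    k[xs, ys, zs] <- r$k
    labels[xs, ys, zs] <- r$label
  }
  structure(list(s0 = s0, d = d, k = k, labels = labels, spec = spec),
            class = "xq_phantom_volume")
}

#' Evaluation masks of a phantom volume
#'
#' * `foreground`: K != 0 regions (RMSE/SNR evaluation);
#' * `background`: K = 0, D != 0 regions (CNR reference);
#' * `support`: S0 > 0 (SSIM evaluation area).
#'
#' @param vol An `xq_phantom_volume`.
#' @return List of three logical 3D arrays.
#' @export
phantom_masks <- function(vol) {
  stopifnot(inherits(vol, "xq_phantom_volume"))
  list(foreground = vol$k != 0,
       background = vol$k == 0 & vol$d != 0,
       support = vol$s0 > 0)
}

#' Forward-simulate a noisy DWI volume from a phantom
#'
#' Per voxel, evaluates the DKI signal at every b-value of the scheme and
#' applies Rician noise (including the b = 0 volume). With the default
#' `sigma = 32` the realized noise ratio at an S0 = 320 region is 0.1.
#' Voxels with S0 = 0 receive pure noise magnitude `|N(0, sigma)|`.
#'
#' @param vol An `xq_phantom_volume`.
#' @param scheme An [acquisition_scheme()].
#' @param sigma Rician noise SD (default from the spec).
#' @param seed Optional integer seed.
#' @return 4D array (x, y, z, volume).
#' @export
phantom_dwi <- function(vol, scheme, sigma = vol$spec$sigma, seed = NULL) {
  stopifnot(inherits(vol, "xq_phantom_volume"), inherits(scheme, "xq_scheme"))
  .assert_scalar(sigma, "sigma", nonneg = TRUE)
  dm <- dim(vol$s0)
  nb <- length(scheme$bvalues)
  out <- array(0, c(dm, nb))
  sup <- vol$s0 > 0
  .with_seed(seed, {
    for (j in seq_len(nb)) {
      b <- scheme$bvalues[j]
      s <- array(0, dm)
      s[sup] <- vol$s0[sup] * exp(-b * vol$d[sup] + b^2 * vol$d[sup]^2 * vol$k[sup] / 6)
      if (sigma > 0) s <- array(sqrt(s^2 + rnorm(length(s), 0, sigma)^2), dm)
      out[, , , j] <- s
    }
  })
  out
}

#' @export
print.xq_phantom_spec <- function(x, ...) {
  cat(sprintf("<xq_phantom_spec> %s, %d regions, S0 levels {%s}, sigma = %g\n",
              paste(x$dims, collapse = "x"), nrow(x$regions),
              paste(x$s0_levels, collapse = ", "), x$sigma))
  invisible(x)
}

#' @export
print.xq_phantom_volume <- function(x, ...) {
  cat(sprintf("<xq_phantom_volume> %s, %d labelled regions\n",
              paste(dim(x$s0), collapse = "x"), max(x$labels)))
  invisible(x)
}
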