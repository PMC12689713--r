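## Vectorized synthesis core. All heavy generation works on n samples at
## once: centers as n-row data.frames, 3x3 grids as n x 9 matrices
## (row-major neighbourhood order), signals as n x 9 x (N+1) arrays.

.MAX_REJECT <- 1e5

## n uniform center draws, rejection-resampled (D, K jointly) until the
## monotonic-decay bound holds; uniform on the accepted region.
.sample_centers <- function(n, ranges, b_max) {
  s0 <- runif(n, ranges$s0[1], ranges$s0[2])
  d <- runif(n, ranges$d[1], ranges$d[2])
  k <- runif(n, ranges$k[1], ranges$k[2])
  lim <- 3 / b_max
  bad <- which(d * k >= lim)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > .MAX_REJECT)
      stop("parameter ranges leave no feasible (D, K) draws under D*K < 3/b_max",
           call. = FALSE)
    d[bad] <- runif(length(bad), ranges$d[1], ranges$d[2])
    k[bad] <- runif(length(bad), ranges$k[1], ranges$k[2])
    bad <- bad[d[bad] * k[bad] >= lim]
  }
  list(s0 = s0, d = d, k = k)
}

## Expand n centers into n local patterns: grid = center + W %*% U per
## parameter, with the whole weight set of a sample redrawn until all
## nine cells are physically valid (positivity + decay bound). Centers
## arbitrarily close to the D*K bound leave (near-)zero acceptance mass
## for the weights, so redraw rounds are capped; still-invalid samples
## are reported in `ok` and handled by the caller (joint center+weight
## resampling during dataset generation, an error for the single-sample
## API).
.expand_patterns <- function(centers, m, ranges, b_max, max_rounds = 200L) {
  n <- length(centers$s0)
  U <- xq_bases(m)
  lim <- 3 / b_max
  draw_w <- function(nn, rng) matrix(runif(nn * m, rng[1], rng[2]), nn, m)
  grid_of <- function(ctr, w) w %*% U + ctr            # recycles ctr down cols
  ## The S0 weight set is valid independently of the (D, K) sets, so the
  ## rejection runs in two stages — S0 alone, then (D, K) jointly — which
  ## draws from exactly the same product distribution as resampling the
  ## entire weight set but wastes far fewer draws.
  w_s0 <- draw_w(n, ranges$w_s0)
  g_s0 <- grid_of(centers$s0, w_s0)
  bad <- which(.rowSums(g_s0 > 0, n, 9L) < 9L)
  tries <- 0L
  while (length(bad) && tries < max_rounds) {
    tries <- tries + 1L
    nw <- draw_w(length(bad), ranges$w_s0)
    ng <- grid_of(centers$s0[bad], nw)
    w_s0[bad, ] <- nw
    g_s0[bad, ] <- ng
    bad <- bad[.rowSums(ng > 0, nrow(ng), 9L) < 9L]
  }
  ok <- rep(TRUE, n)
  ok[bad] <- FALSE

  dk_ok <- function(d, k) {
    cond <- d > 0 & k >= 0 & d * k < lim
    .rowSums(cond, nrow(cond), 9L) == 9L
  }
  w_d <- draw_w(n, ranges$w_d)
  w_k <- draw_w(n, ranges$w_k)
  g_d <- grid_of(centers$d, w_d)
  g_k <- grid_of(centers$k, w_k)
  bad <- which(!dk_ok(g_d, g_k))
  tries <- 0L
  while (length(bad) && tries < max_rounds) {
    tries <- tries + 1L
    nw_d <- draw_w(length(bad), ranges$w_d)
    nw_k <- draw_w(length(bad), ranges$w_k)
    ng_d <- grid_of(centers$d[bad], nw_d)
    ng_k <- grid_of(centers$k[bad], nw_k)
    w_d[bad, ] <- nw_d; w_k[bad, ] <- nw_k
    g_d[bad, ] <- ng_d; g_k[bad, ] <- ng_k
    bad <- bad[!dk_ok(ng_d, ng_k)]
  }
  ok[bad] <- FALSE
  list(s0 = g_s0, d = g_d, k = g_k,
       weights = list(s0 = w_s0, d = w_d, k = w_k), ok = ok)
}

## centers + patterns with joint resampling of samples whose center
## admits no valid weight set within the round cap
.sample_patterns <- function(n, m, ranges, b_max) {
  centers <- .sample_centers(n, ranges, b_max)
  grids <- .expand_patterns(centers, m, ranges, b_max)
  rounds <- 0L
  while (any(!grids$ok)) {
    rounds <- rounds + 1L
    if (rounds > .MAX_REJECT)
      stop("ranges admit no valid 3x3 patterns", call. = FALSE)
    bad <- which(!grids$ok)
    redraw <- .sample_centers(length(bad), ranges, b_max)
    for (f in c("s0", "d", "k")) centers[[f]][bad] <- redraw[[f]]
    g2 <- .expand_patterns(redraw, m, ranges, b_max)
    for (f in c("s0", "d", "k")) {
      grids[[f]][bad, ] <- g2[[f]]
      grids$weights[[f]][bad, ] <- g2$weights[[f]]
    }
    grids$ok[bad] <- g2$ok
  }
  list(centers = centers, grids = grids)
}

## Forward-model + noise for n patterns: returns signals (n x 9 x (N+1))
## and decay-ratio features (n x 9N, location-major then b-value).
.synthesize_batch <- function(grids, scheme, sigma) {
  n <- nrow(grids$s0)
  b <- scheme$bvalues
  nb <- length(b)
  sig <- array(NA_real_, c(n, 9L, nb))
  for (j in seq_len(nb)) {
    s <- grids$s0 * exp(-b[j] * grids$d + b[j]^2 * grids$d^2 * grids$k / 6)
    if (sigma > 0) s <- sqrt(s^2 + matrix(rnorm(n * 9L, 0, sigma), n, 9L)^2)
    sig[, , j] <- s
  }
  ## Rician output is positive almost surely; guard against exact-zero
  ## degenerate b=0 values all the same (re-noise the offending rows).
  guard <- which(apply(sig[, , 1L, drop = FALSE] < 1e-12, 1L, any))
  while (length(guard)) {
    for (j in seq_len(nb)) {
      s <- grids$s0[guard, , drop = FALSE] *
        exp(-b[j] * grids$d[guard, , drop = FALSE] +
              b[j]^2 * grids$d[guard, , drop = FALSE]^2 * grids$k[guard, , drop = FALSE] / 6)
      if (sigma > 0)
        s <- sqrt(s^2 + matrix(rnorm(length(guard) * 9L, 0, sigma), length(guard), 9L)^2)
      sig[guard, , j] <- s
    }
    guard <- guard[apply(sig[guard, , 1L, drop = FALSE] < 1e-12, 1L, any)]
  }
  feats <- matrix(NA_real_, n, 9L * scheme$n_nonzero)
  for (i in 1:9) for (j in seq_len(scheme$n_nonzero))
    feats[, (i - 1L) * scheme$n_nonzero + j] <- sig[, i, j + 1L] / sig[, i, 1L]
  colnames(feats) <- feature_names(scheme)
  list(signals = sig, features = feats)
}

#' Decay-ratio feature names
#'
#' Canonical feature ordering of X-Q samples: location-major (row-major
#' over the 3x3 neighbourhood, center = location 5), then b-value. This
#' descriptor is recorded in datasets and trained models, and train/infer
#' consistency is enforced against it.
#'
#' @param scheme An [acquisition_scheme()].
#' @return Character vector of length `9 N`, e.g. `"loc1.b50"`.
#' @export
feature_names <- function(scheme) {
  as.vector(t(outer(1:9, scheme$bvalues[-1L],
                    function(i, b) sprintf("loc%d.b%g", i, b))))
}

#' Sample center-voxel DKI parameters
#'
#' Draws `n` parameter triples uniformly on the configured ranges,
#' rejection-resampling (D, K) jointly until the monotonic-decay bound
#' `D * K < 3 / b_max` holds, so accepted draws are uniform on the
#' truncated region. These center draws are the gold-standard regression
#' targets of synthesis.
#'
#' @param ranges An [dki_ranges()].
#' @param scheme An [acquisition_scheme()] (supplies `b_max`).
#' @param n Number of draws.
#' @param seed Optional integer seed (local to this call).
#' @return A data.frame with columns `s0`, `d` (mm^2/s), `k`.
#' @export
sample_center_params <- function(ranges, scheme, n = 1, seed = NULL) {
  stopifnot(inherits(ranges, "xq_ranges"), inherits(scheme, "xq_scheme"))
  as.data.frame(.with_seed(seed, .sample_centers(n, ranges, scheme$b_max)))
}

#' Expand a center triple into a 3x3 local pattern
#'
#' Builds per-parameter 3x3 grids as the center-constant grid plus a
#' random linear combination of the basis patterns ([xq_bases()]),
#' weights drawn independently per parameter and per basis. The whole
#' weight set is redrawn until every one of the nine cells is physically
#' valid (S0 > 0, D > 0, K >= 0 and the decay bound); because all bases
#' have a zero center element the center cell always equals the input
#' triple exactly.
#'
#' @param center A 1-row data.frame (or named vector) with `s0`, `d`
#'   (mm^2/s), `k`; must itself satisfy the decay bound.
#' @param mode Basis mode: 1, 3 or 6 (or `"flat"/"linear"/"quadratic"`).
#' @param ranges,scheme,seed As in [sample_center_params()].
#' @return An object of class `xq_pattern`: 9-vectors `s0`, `d`, `k`
#'   (row-major), realized `weights`, `mode`, and the gold-standard
#'   `center`.
#' @export
expand_to_pattern <- function(center, mode, ranges, scheme, seed = NULL) {
  stopifnot(inherits(ranges, "xq_ranges"), inherits(scheme, "xq_scheme"))
  center <- as.data.frame(as.list(unlist(center)))[c("s0", "d", "k")]
  if (!monotonic_decay_ok(center$d, center$k, scheme$b_max))
    stop("center triple violates the monotonic-decay bound", call. = FALSE)
  m <- basis_mode(mode)
  g <- .with_seed(seed,
                  .expand_patterns(center, m, ranges, scheme$b_max,
                                   max_rounds = 5000L))
  if (!g$ok[1L])
    stop("no valid 3x3 pattern found for this center within the rejection cap",
         call. = FALSE)
  structure(
    list(s0 = g$s0[1L, ], d = g$d[1L, ], k = g$k[1L, ],
         weights = lapply(g$weights, function(w) w[1L, ]),
         mode = m,
         center = c(s0 = center$s0, d = center$d, k = center$k)),
    class = "xq_pattern"
  )
}

#' @param pattern An `xq_pattern`.
#' @param param One of `"s0"`, `"d"`, `"k"`.
#' @return `pattern_grid()`: the 3x3 matrix of that parameter.
#' @rdname expand_to_pattern
#' @export
pattern_grid <- function(pattern, param = c("s0", "d", "k")) {
  param <- match.arg(param)
  matrix(pattern[[param]], 3L, 3L, byrow = TRUE)
}

#' Synthesize one noisy X-Q space sample from a local pattern
#'
#' Evaluates the DKI model at all nine locations and all b-values
#' (including b = 0), applies Rician noise to every signal, and computes
#' the decay-ratio features `E_ij = S_ij / S_i0` — each location's
#' signals normalized by its own noisy b = 0 value. Targets are the
#' pattern's center (D, K).
#'
#' @param pattern An `xq_pattern`.
#' @param scheme An [acquisition_scheme()].
#' @param noise An [noise_spec()] (or `NULL` for noise-free).
#' @param seed Optional integer seed.
#' @return An object of class `xq_sample`: `signals` (9 x (N+1) matrix),
#'   `features` (named length-9N vector), `targets` (`d`, `k`), `noise`.
#' @export
synthesize_sample <- function(pattern, scheme, noise = NULL, seed = NULL) {
  stopifnot(inherits(pattern, "xq_pattern"), inherits(scheme, "xq_scheme"))
  sigma <- if (is.null(noise)) 0 else noise$sigma
  grids <- list(s0 = matrix(pattern$s0, 1L), d = matrix(pattern$d, 1L),
                k = matrix(pattern$k, 1L))
  out <- .with_seed(seed, .synthesize_batch(grids, scheme, sigma))
  sig <- matrix(out$signals[1L, , ], 9L, length(scheme$bvalues),
                dimnames = list(paste0("loc", 1:9), paste0("b", scheme$bvalues)))
  structure(
    list(signals = sig,
         features = stats::setNames(out$features[1L, ], colnames(out$features)),
         targets = c(d = unname(pattern$center["d"]), k = unname(pattern$center["k"])),
         noise = noise),
    class = "xq_sample"
  )
}

#' Generate a labelled X-Q space dataset
#'
#' The full synthesis pipeline at scale: center draws, basis-pattern
#' expansion, signal synthesis and Rician noise, decay-ratio features.
#' Noise sigma is `nr` times the midpoint of the S0 range (the mean
#' baseline signal of the synthesis distribution). Output is
#' deterministic for a fixed seed and configuration.
#'
#' @param n Number of samples.
#' @param scheme An [acquisition_scheme()].
#' @param ranges An [dki_ranges()].
#' @param mode Basis mode (1, 3, 6 or name); default quadratic.
#' @param nr Noise ratio; 0 gives noise-free signals.
#' @param seed Optional integer seed (strongly recommended).
#' @param split Free-form tag (`"train"`, `"validation"`, `"test"`, ...).
#' @param keep_signals Keep the raw `n x 9 x (N+1)` signal array
#'   (memory-heavy; features and targets are always kept).
#' @return An object of class `xq_dataset`: `features` (n x 9N matrix),
#'   `targets` (data.frame `s0`, `d`, `k` — center gold standard),
#'   `meta` (seed, nr, sigma, mode, split, ranges, scheme,
#'   feature_order), optionally `signals`.
#' @export
generate_dataset <- function(n, scheme, ranges = dki_ranges(), mode = 6,
                             nr = 0.1, seed = NULL, split = "train",
                             keep_signals = FALSE) {
  stopifnot(n >= 1, inherits(scheme, "xq_scheme"), inherits(ranges, "xq_ranges"))
  m <- basis_mode(mode)
  .assert_scalar(nr, "nr", nonneg = TRUE)
  s0_mean <- mean(ranges$s0)
  sigma <- sigma_for_noise_ratio(nr, s0_mean)
  .with_seed(seed, {
    sp <- .sample_patterns(n, m, ranges, scheme$b_max)
    centers <- as.data.frame(sp$centers)
    syn <- .synthesize_batch(sp$grids, scheme, sigma)
    structure(
      list(features = syn$features,
           targets = centers,
           signals = if (keep_signals) syn$signals,
           meta = list(n = as.integer(n), seed = seed, nr = nr, sigma = sigma,
                       s0_mean = s0_mean, mode = m, split = split,
                       ranges = ranges, scheme = scheme,
                       feature_order = colnames(syn$features))),
      class = "xq_dataset"
    )
  })
}

#' @export
print.xq_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<xq_dataset> %d samples (%s), mode M = %d, NR = %g (sigma = %g)\n",
              m$n, m$split, m$mode, m$nr, m$sigma))
  cat(sprintf("  features: %d x %d (9N, N = %d)\n",
              nrow(x$features), ncol(x$features), m$scheme$n_nonzero))
  invisible(x)
}

#' Save / load an X-Q dataset
#'
#' Serializes the dataset container (RDS) alongside a human-readable JSON
#' metadata sidecar, and optionally a CSV export of features + targets
#' for external inspection.
#'
#' @param dataset An `xq_dataset`.
#' @param dir Output directory (created if needed).
#' @param csv Also write `samples.csv` (features + targets)?
#' @return The directory, invisibly. `read_xq_dataset()` returns the
#'   dataset.
#' @export
write_xq_dataset <- function(dataset, dir, csv = FALSE) {
  stopifnot(inherits(dataset, "xq_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset, file.path(dir, "dataset.rds"))
  m <- dataset$meta
  meta <- list(n = m$n, seed = m$seed, nr = m$nr, sigma = m$sigma,
               s0_mean = m$s0_mean, mode = m$mode, split = m$split,
               bvalues = m$scheme$bvalues, feature_order = m$feature_order)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (csv)
    utils::write.csv(cbind(as.data.frame(dataset$features), dataset$targets),
                     file.path(dir, "samples.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_xq_dataset
#' @export
read_xq_dataset <- function(dir) {
  readRDS(file.path(dir, "dataset.rds"))
}
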