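#' Cross-noise train/test experiment
#'
#' Trains one regressor per training noise ratio (optionally with a
#' brute-force hyperparameter search) and evaluates its RMSE on test
#' sets generated at every test noise ratio, producing the full
#' (train NR x test NR) matrix. Test sets are generated once per test
#' level and shared by every trained model (and by both window modes),
#' so comparisons across cells are on common data.
#'
#' @param scheme An [acquisition_scheme()].
#' @param nr_levels Noise ratios, used for both axes; default
#'   `c(0, 0.001, 0.01, 0.1)`.
#' @param n_train,n_test Sample counts per dataset.
#' @param n_val Validation samples (only generated when `grid` is given).
#' @param mode Basis mode for synthesis (default quadratic, M = 6).
#' @param target `"D"` or `"K"`.
#' @param windows Character vector from `c("synxqsl", "synqsl")`.
#' @param hyper Fixed [hyper_config()] used when `grid` is `NULL`.
#' @param grid Optional [hyper_grid()]; triggers per-train-level search.
#' @param ranges An [dki_ranges()].
#' @param seed Integer seed; all datasets and trainings derive sub-seeds
#'   from it, so a run is fully reproducible.
#' @param verbose Print progress.
#' @return An object of class `xq_cross_test`: `rmse` (3D array
#'   `[window, train, test]`, units: scaled D or raw K), `models`,
#'   `config`.
#' @export
run_cross_test <- function(scheme, nr_levels = c(0, 0.001, 0.01, 0.1),
                           n_train = 1e5, n_test = 1e4, n_val = 1e4,
                           mode = 6, target = c("K", "D"),
                           windows = "synxqsl",
                           hyper = hyper_config(), grid = NULL,
                           ranges = dki_ranges(), seed = 1,
                           verbose = FALSE) {
  target <- match.arg(target)
  stopifnot(all(windows %in% c("synxqsl", "synqsl")), length(nr_levels) >= 1L)
  nn <- length(nr_levels)
  lab <- paste0("nr", nr_levels)
  tests <- lapply(seq_len(nn), function(i)
    generate_dataset(n_test, scheme, ranges, mode, nr_levels[i],
                     seed = .derive_seed(seed, 1000L + i), split = "test"))
  rmse <- array(NA_real_, c(length(windows), nn, nn),
                dimnames = list(windows, train = lab, test = lab))
  models <- list()
  for (i in seq_len(nn)) {
    if (verbose) message(sprintf("train NR = %g ...", nr_levels[i]))
    train <- generate_dataset(n_train, scheme, ranges, mode, nr_levels[i],
                              seed = .derive_seed(seed, 100L + i),
                              split = "train")
    val <- if (!is.null(grid))
      generate_dataset(n_val, scheme, ranges, mode, nr_levels[i],
                       seed = .derive_seed(seed, 500L + i),
                       split = "validation")
    for (w in windows) {
      mdl <- if (is.null(grid))
        train_mlp(train, target, w, hyper = hyper,
                  seed = .derive_seed(seed, 10L + i))
      else
        grid_search(train, val, grid, target, w,
                    seed = .derive_seed(seed, 10L + i),
                    verbose = verbose)$model
      models[[paste(w, lab[i], sep = ".")]] <- mdl
      for (j in seq_len(nn))
        rmse[w, i, j] <- estimation_rmse(mdl, tests[[j]])
    }
  }
  structure(
    list(rmse = rmse, models = models,
         config = list(nr_levels = nr_levels, n_train = n_train,
                       n_test = n_test, n_val = n_val, mode = basis_mode(mode),
                       target = target, windows = windows, seed = seed,
                       hyper = hyper, searched = !is.null(grid),
                       bvalues = scheme$bvalues)),
    class = "xq_cross_test"
  )
}

#' @export
print.xq_cross_test <- function(x, ...) {
  cat(sprintf("<xq_cross_test> target %s, M = %d, n_train = %g, n_test = %g\n",
              x$config$target, x$config$mode, x$config$n_train,
              x$config$n_test))
  for (w in dimnames(x$rmse)[[1L]]) {
    cat(sprintf("  RMSE matrix (%s; rows = train NR, cols = test NR):\n", w))
    print(round(x$rmse[w, , ], 4))
  }
  invisible(x)
}

#' Digital-phantom benchmark of estimation methods
#'
#' Builds the phantom, simulates a noisy DWI volume, estimates D and K
#' maps with least-squares fitting and every supplied regressor pair,
#' and reports signed-error statistics per S0 level (over the K != 0
#' mask) plus SNR, CNR and SSIM per map. If no models are supplied,
#' desk-scale synXQSL (M = 6) and synQSL models are trained in-line at
#' the phantom's noise ratio.
#'
#' @param spec An [phantom_spec()].
#' @param scheme An [acquisition_scheme()].
#' @param models Named list of methods; each entry is a list with
#'   elements `D` and `K` (trained `xq_regressor`s). `NULL` trains
#'   defaults in-line.
#' @param include_lsf Include the least-squares baseline?
#' @param sigma Noise SD of the simulated DWI (default from spec).
#' @param seed Integer seed (DWI noise and in-line training).
#' @param n_train In-line training set size per model.
#' @param hyper In-line training configuration.
#' @param wilcoxon Add a Wilcoxon signed-rank p-value comparing each
#'   method's absolute errors against the first method (paired over a
#'   fixed voxel subsample).
#' @return A list of class `xq_phantom_benchmark`: `errors` (data.frame:
#'   method, parameter, s0_level, rms, min, max; D rows in scaled
#'   units), `quality` (data.frame: method, parameter, snr, cnr, ssim),
#'   `maps` (per method: `d`, `k` 3D arrays, native units), `truth`,
#'   `masks`, `config`.
#' @export
run_phantom_benchmark <- function(spec = phantom_spec(), scheme = breast_dki_scheme(),
                                  models = NULL, include_lsf = TRUE,
                                  sigma = spec$sigma, seed = 1,
                                  n_train = 5e4, hyper = hyper_config(),
                                  wilcoxon = FALSE) {
  stopifnot(inherits(spec, "xq_phantom_spec"), inherits(scheme, "xq_scheme"))
  vol <- build_phantom(spec)
  masks <- phantom_masks(vol)
  dwi <- phantom_dwi(vol, scheme, sigma, seed = .derive_seed(seed, 1L))
  nr <- noise_ratio(sigma, mean(range(spec$s0_levels)))

  if (is.null(models)) {
    nr_train <- if (sigma > 0) 0.1 else 0
    mk <- function(window, target, off) {
      train <- generate_dataset(n_train, scheme, mode = if (window == "synqsl") 1 else 6,
                                nr = nr_train, seed = .derive_seed(seed, off),
                                split = "train")
      train_mlp(train, target, window, hyper = hyper,
                seed = .derive_seed(seed, off + 1L))
    }
    models <- list(
      synqsl = list(D = mk("synqsl", "D", 20L), K = mk("synqsl", "K", 30L)),
      synxqsl_m6 = list(D = mk("synxqsl", "D", 40L), K = mk("synxqsl", "K", 50L)))
  }

  maps <- list()
  if (include_lsf) {
    fit <- lsf_fit_volume(dwi, scheme)
    maps$lsf <- list(d = fit$d, k = fit$k)
  }
  for (nm in names(models)) {
    maps[[nm]] <- list(
      d = predict_volume(dwi, scheme, models[[nm]]$D)$map,
      k = predict_volume(dwi, scheme, models[[nm]]$K)$map)
  }

  s0_levels <- spec$s0_levels
  errors <- list()
  quality <- list()
  truth <- list(d = vol$d, k = vol$k)
  fg_labels <- vol$labels * (masks$foreground + 0L)
  for (nm in names(maps)) {
    for (par in c("d", "k")) {
      est <- maps[[nm]][[par]]
      tru <- truth[[par]]
      scl <- if (par == "d") .D_SCALE else 1
      for (s0l in s0_levels) {
        msk <- masks$foreground & vol$s0 == s0l
        st <- signed_error_stats(est * scl, tru * scl, msk)
        errors[[length(errors) + 1L]] <-
          data.frame(method = nm, parameter = toupper(par), s0_level = s0l,
                     rms = st$rms, min = st$min, max = st$max, n = st$n)
      }
      quality[[length(quality) + 1L]] <-
        data.frame(method = nm, parameter = toupper(par),
                   snr = region_snr(est, fg_labels)$snr,
                   cnr = cnr(est, masks$foreground, masks$background),
                   ssim = map_ssim(est, tru, mask = masks$support))
    }
  }
  errors <- do.call(rbind, errors)
  quality <- do.call(rbind, quality)

  if (wilcoxon && length(maps) > 1L) {
    ref <- names(maps)[1L]
    idx <- which(masks$foreground)
    if (length(idx) > 5000L)
      idx <- idx[round(seq(1L, length(idx), length.out = 5000L))]
    quality$p_wilcoxon <- NA_real_
    for (i in seq_len(nrow(quality))) {
      nm <- quality$method[i]; par <- tolower(quality$parameter[i])
      if (nm == ref) next
      quality$p_wilcoxon[i] <- wilcox.test(
        abs(maps[[nm]][[par]] - truth[[par]])[idx],
        abs(maps[[ref]][[par]] - truth[[par]])[idx],
        paired = TRUE)$p.value
    }
  }

  structure(
    list(errors = errors, quality = quality, maps = maps, truth = truth,
         masks = masks, volume = vol,
         config = list(sigma = sigma, nr_mid = nr, seed = seed,
                       bvalues = scheme$bvalues, dims = spec$dims)),
    class = "xq_phantom_benchmark"
  )
}

#' @export
print.xq_phantom_benchmark <- function(x, ...) {
  cat(sprintf("<xq_phantom_benchmark> %s, sigma = %g\n",
              paste(x$config$dims, collapse = "x"), x$config$sigma))
  cat("signed errors per S0 level (D in 1e-3 mm^2/s):\n")
  print(x$errors, row.names = FALSE, digits = 3)
  cat("map quality:\n")
  print(x$quality, row.names = FALSE, digits = 3)
  invisible(x)
}
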