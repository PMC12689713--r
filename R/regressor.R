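#' Hyperparameter configuration and search grid
#'
#' `hyper_config()` describes one training configuration;
#' `hyper_grid()` builds the brute-force search grid. The default grid
#' axes are: 3/4/5 mid-layers, 64/128/256 units per layer, dropout
#' 0/0.01/0.1, 50/100/150 epochs and batch size 1000/10000/100000
#' (3^5 = 243 points). Pass shorter vectors for a reduced,
#' desk-scale search.
#'
#' @param mid_layers Number of mid-layers.
#' @param units Units per mid-layer.
#' @param dropout Dropout probability.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @return `hyper_config()`: a one-row data.frame; `hyper_grid()`: a
#'   data.frame with one row per grid point.
#' @export
hyper_config <- function(mid_layers = 3, units = 64, dropout = 0,
                         epochs = 50, batch_size = 1000) {
  data.frame(mid_layers = as.integer(mid_layers), units = as.integer(units),
             dropout = dropout, epochs = as.integer(epochs),
             batch_size = as.integer(batch_size))
}

#' @rdname hyper_config
#' @export
hyper_grid <- function(mid_layers = c(3, 4, 5), units = c(64, 128, 256),
                       dropout = c(0, 0.01, 0.1), epochs = c(50, 100, 150),
                       batch_size = c(1000, 10000, 100000)) {
  expand.grid(mid_layers = as.integer(mid_layers), units = as.integer(units),
              dropout = dropout, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              KEEP.OUT.ATTRS = FALSE)
}

## Feature extraction per window mode. synXQSL uses all 9 locations
## (9N features); synQSL only the center voxel's N decay ratios.
.window_columns <- function(scheme, window) {
  n <- scheme$n_nonzero
  switch(window,
         synxqsl = seq_len(9L * n),
         synqsl = (.CENTER_IDX - 1L) * n + seq_len(n),
         stop("unknown window mode: ", window, call. = FALSE))
}

#' Extract regression features from a dataset
#'
#' @param dataset An `xq_dataset`.
#' @param window `"synxqsl"` (3x3 neighbourhood, 9N features) or
#'   `"synqsl"` (center voxel only, N features).
#' @return Numeric feature matrix.
#' @export
dataset_features <- function(dataset, window = c("synxqsl", "synqsl")) {
  window <- match.arg(window)
  dataset$features[, .window_columns(dataset$meta$scheme, window), drop = FALSE]
}

## Target vector in training units (D is scaled by 1e3 for conditioning
## and display convention; predictions are mapped back to mm^2/s).
.target_values <- function(dataset, target) {
  switch(target,
         D = dataset$targets$d * .D_SCALE,
         K = dataset$targets$k,
         stop("target must be 'D' or 'K'", call. = FALSE))
}

#' Train a single-parameter regressor on synthetic X-Q data
#'
#' Fits one MLP that maps decay-ratio features to a single DKI parameter
#' (D or K), the synXQSL/synQSL estimation core. The model records its
#' window mode, feature-ordering descriptor, training noise ratio and
#' scheme fingerprint; [predict_volume()] and [predict.xq_regressor()]
#' enforce consistency against them.
#'
#' @param train An `xq_dataset`.
#' @param target `"D"` or `"K"`.
#' @param window `"synxqsl"` (default) or `"synqsl"`.
#' @param hyper A one-row [hyper_config()] data.frame.
#' @param seed Optional integer seed for training.
#' @param validation Optional `xq_dataset`; if given, the validation RMSE
#'   (in reporting units: D scaled by 1e3, K raw) is recorded.
#' @return An object of class `xq_regressor`.
#' @export
train_mlp <- function(train, target = c("D", "K"),
                      window = c("synxqsl", "synqsl"),
                      hyper = hyper_config(), seed = NULL,
                      validation = NULL) {
  stopifnot(inherits(train, "xq_dataset"))
  target <- match.arg(target)
  window <- match.arg(window)
  stopifnot(is.data.frame(hyper), nrow(hyper) == 1L)
  x <- dataset_features(train, window)
  y <- .target_values(train, target)
  mlp <- mlp_fit(x, y,
                 layers = rep(hyper$units, hyper$mid_layers),
                 dropout = hyper$dropout, epochs = hyper$epochs,
                 batch_size = hyper$batch_size, seed = seed)
  if (!all(is.finite(unlist(mlp$W))))
    stop(sprintf("training diverged (non-finite weights) for config: %s",
                 paste(names(hyper), unlist(hyper), sep = "=", collapse = ", ")),
         call. = FALSE)
  model <- structure(
    list(mlp = mlp, target = target, window = window, hyper = hyper,
         feature_order = colnames(x),
         train_nr = train$meta$nr,
         scheme = train$meta$scheme, seed = seed),
    class = "xq_regressor"
  )
  if (!is.null(validation))
    model$val_rmse <- estimation_rmse(model, validation)
  model
}

#' @param object An `xq_regressor`.
#' @param newdata An `xq_dataset` or a feature matrix whose columns match
#'   the model's feature descriptor.
#' @param ... Unused.
#' @return `predict()`: estimates in native units (D in mm^2/s, K
#'   dimensionless).
#' @rdname train_mlp
#' @export
predict.xq_regressor <- function(object, newdata, ...) {
  if (inherits(newdata, "xq_dataset")) {
    if (!identical(newdata$meta$scheme$bvalues, object$scheme$bvalues))
      stop("dataset b-value scheme does not match the model's", call. = FALSE)
    newdata <- dataset_features(newdata, object$window)
  } else {
    newdata <- as.matrix(newdata)
    cn <- colnames(newdata)
    if (!is.null(cn) && !identical(cn, object$feature_order)) {
      if (!setequal(cn, object$feature_order))
        stop("feature columns do not match the model's descriptor", call. = FALSE)
      newdata <- newdata[, object$feature_order, drop = FALSE]
    }
  }
  pred <- predict(object$mlp, newdata)
  if (object$target == "D") pred / .D_SCALE else pred
}

#' RMSE of a regressor on a labelled dataset
#'
#' Reported in conventional units: scaled (1e-3 mm^2/s) for D, raw for K.
#'
#' @param model An `xq_regressor`.
#' @param dataset An `xq_dataset` with gold-standard targets.
#' @return Scalar RMSE.
#' @export
estimation_rmse <- function(model, dataset) {
  stopifnot(inherits(model, "xq_regressor"), inherits(dataset, "xq_dataset"))
  pred <- predict(model, dataset)
  truth <- if (model$target == "D") dataset$targets$d else dataset$targets$k
  scale <- if (model$target == "D") .D_SCALE else 1
  .rmse(pred * scale, truth * scale)
}

#' Brute-force hyperparameter search
#'
#' Trains one model per grid point and returns the point with minimal
#' validation RMSE. Ties are broken by fewer total weights, then lower
#' dropout (smaller model preferred).
#'
#' @param train,validation Disjoint `xq_dataset`s generated under the
#'   same configuration.
#' @param grid A [hyper_grid()] data.frame.
#' @param target,window As in [train_mlp()].
#' @param seed Optional integer seed; each grid point trains with a
#'   sub-seed derived from it.
#' @param verbose Print per-config progress.
#' @return A list: `best` (hyper row), `model` (retained best
#'   `xq_regressor`), `results` (grid with `val_rmse` and `n_weights`).
#' @export
grid_search <- function(train, validation, grid = hyper_grid(),
                        target = c("D", "K"),
                        window = c("synxqsl", "synqsl"),
                        seed = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  target <- match.arg(target)
  window <- match.arg(window)
  res <- grid
  res$val_rmse <- NA_real_
  res$n_weights <- NA_integer_
  best <- NULL
  best_key <- c(Inf, Inf, Inf)
  for (i in seq_len(nrow(grid))) {
    mdl <- train_mlp(train, target, window, hyper = grid[i, , drop = FALSE],
                     seed = .derive_seed(seed, i), validation = validation)
    res$val_rmse[i] <- mdl$val_rmse
    res$n_weights[i] <- n_weights(mdl)
    key <- c(mdl$val_rmse, n_weights(mdl), grid$dropout[i])
    if (is.null(best) ||
        key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] && key[3] < best_key[3])) {
      best <- mdl
      best_key <- key
    }
    if (verbose)
      message(sprintf("[grid %d/%d] %s -> val RMSE %.5g", i, nrow(grid),
                      paste(names(grid), unlist(grid[i, ]), sep = "=",
                            collapse = " "), mdl$val_rmse))
  }
  list(best = best$hyper, model = best, results = res)
}

#' Estimate a parameter map from a DWI volume
#'
#' Voxelwise inference: for every voxel the in-slice 3x3 neighbourhood is
#' gathered (replicate-padded at volume edges), each neighbour's signals
#' are normalized by that neighbour's own b = 0 value, and the model
#' predicts the center parameter. synQSL models use only the center
#' voxel's N ratios. Voxels whose b = 0 signal falls below
#' `1e-6 * max(b0)` are emitted as 0 and flagged in the guard mask.
#'
#' @param dwi 4D numeric array (x, y, z, volume) or an `RNifti` image;
#'   4th-axis length must be `N + 1`.
#' @param scheme The [acquisition_scheme()] of the volume.
#' @param model A trained `xq_regressor`.
#' @return An object of class `xq_param_map`: `map` (3D array, native
#'   units), `guard` (3D logical: low-signal voxels forced to 0),
#'   `target`, `window`.
#' @export
predict_volume <- function(dwi, scheme, model) {
  stopifnot(inherits(model, "xq_regressor"), inherits(scheme, "xq_scheme"))
  dwi <- .as_dwi_array(dwi)
  if (dim(dwi)[4L] != length(scheme$bvalues))
    stop("4th dimension of the volume does not match the scheme", call. = FALSE)
  if (!identical(scheme$bvalues, model$scheme$bvalues))
    stop("scheme does not match the model's training scheme", call. = FALSE)
  dm <- dim(dwi)[1:3]
  nvol <- scheme$n_nonzero
  b0 <- dwi[, , , 1L, drop = FALSE]
  dim(b0) <- dm
  eps <- 1e-6 * max(b0)
  guard <- b0 <= eps
  safe_b0 <- ifelse(guard, 1, b0)
  ratios <- vector("list", nvol)
  for (j in seq_len(nvol)) {
    r <- dwi[, , , j + 1L, drop = FALSE]
    dim(r) <- dm
    ratios[[j]] <- r / safe_b0
  }
  map <- array(0, dm)
  nx <- dm[1L]; ny <- dm[2L]
  offs <- expand.grid(dc = -1:1, dr = -1:1)   # row-major: rows outer
  for (z in seq_len(dm[3L])) {
    if (model$window == "synqsl") {
      X <- matrix(NA_real_, nx * ny, nvol)
      for (j in seq_len(nvol)) X[, j] <- as.vector(ratios[[j]][, , z])
    } else {
      X <- matrix(NA_real_, nx * ny, 9L * nvol)
      for (j in seq_len(nvol)) {
        pad <- matrix(NA_real_, nx + 2L, ny + 2L)
        pad[2:(nx + 1L), 2:(ny + 1L)] <- ratios[[j]][, , z]
        pad[1L, ] <- pad[2L, ]; pad[nx + 2L, ] <- pad[nx + 1L, ]
        pad[, 1L] <- pad[, 2L]; pad[, ny + 2L] <- pad[, ny + 1L]
        for (loc in 1:9) {
          dr <- offs$dr[loc]; dc <- offs$dc[loc]
          X[, (loc - 1L) * nvol + j] <-
            as.vector(pad[(1:nx) + 1L + dr, (1:ny) + 1L + dc])
        }
      }
    }
    pred <- predict(model$mlp, X)
    if (model$target == "D") pred <- pred / .D_SCALE
    slice <- matrix(pred, nx, ny)
    slice[guard[, , z]] <- 0
    map[, , z] <- slice
  }
  structure(list(map = map, guard = guard, target = model$target,
                 window = model$window),
            class = "xq_param_map")
}

#' @export
print.xq_param_map <- function(x, ...) {
  cat(sprintf("<xq_param_map> %s map %s, %d guarded voxels (%s window)\n",
              x$target, paste(dim(x$map), collapse = "x"), sum(x$guard),
              x$window))
  invisible(x)
}

#' Save / load a trained regressor
#'
#' Persists the model as an RDS archive plus a JSON metadata sidecar
#' (target, window, hyperparameters, feature ordering, training NR,
#' scheme).
#'
#' @param model An `xq_regressor`.
#' @param path Output `.rds` path; the sidecar gets extension `.json`.
#' @return `path`, invisibly; `read_regressor()` returns the model.
#' @export
write_regressor <- function(model, path) {
  stopifnot(inherits(model, "xq_regressor"))
  saveRDS(model, path)
  meta <- list(target = model$target, window = model$window,
               hyper = as.list(model$hyper), train_nr = model$train_nr,
               bvalues = model$scheme$bvalues,
               feature_order = model$feature_order,
               val_rmse = model$val_rmse)
  jsonlite::write_json(meta, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_regressor
#' @export
read_regressor <- function(path) readRDS(path)

#' @export
print.xq_regressor <- function(x, ...) {
  cat(sprintf("<xq_regressor> target %s, window %s, trained at NR = %g\n",
              x$target, x$window, x$train_nr))
  print(x$mlp)
  if (!is.null(x$val_rmse)) cat(sprintf("  validation RMSE: %.5g\n", x$val_rmse))
  invisible(x)
}
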