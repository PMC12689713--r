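test_that("window modes select the documented feature columns", {
  ds <- generate_dataset(20, test_scheme, mode = 6, nr = 0, seed = 50)
  full <- dataset_features(ds, "synxqsl")
  ctr <- dataset_features(ds, "synqsl")
  expect_equal(ncol(full), 54)
  expect_equal(ncol(ctr), 6)
  expect_equal(colnames(ctr),
               paste0("loc5.b", c(50, 850, 1000, 1500, 2000, 2500)))
  expect_equal(ctr, full[, 25:30])
})

test_that("noise-free flat features determine D to grid accuracy", {
  # noise-free M = 1 training: the decay ratios identify (D, K)
  # exactly, so a trained D regressor should approach the LSF oracle
  train <- generate_dataset(1e4, test_scheme, mode = 1, nr = 0, seed = 51)
  val <- generate_dataset(2000, test_scheme, mode = 1, nr = 0, seed = 52,
                          split = "validation", keep_signals = TRUE)
  mdl <- train_mlp(train, "D", "synxqsl", hyper = hyper_config(epochs = 50),
                   seed = 53, validation = val)
  expect_lt(mdl$val_rmse, 0.1)      # scaled units (1e-3 mm^2/s)

  # LSF on the same held-out center signals recovers D exactly —
  # the fit error is entirely the regressor's
  lsf_d <- vapply(seq_len(50), function(i)
    lsf_fit_voxel(val$signals[i, 5, ], test_scheme)$d, 1.0)
  expect_equal(lsf_d, val$targets$d[1:50], tolerance = 1e-9)
})

test_that("training is reproducible and divergence is reported", {
  ds <- generate_dataset(2000, test_scheme, mode = 6, nr = 0.1, seed = 54)
  val <- generate_dataset(500, test_scheme, mode = 6, nr = 0.1, seed = 55)
  m1 <- train_mlp(ds, "K", hyper = hyper_config(epochs = 5), seed = 7,
                  validation = val)
  m2 <- train_mlp(ds, "K", hyper = hyper_config(epochs = 5), seed = 7,
                  validation = val)
  expect_identical(m1$val_rmse, m2$val_rmse)
  expect_identical(m1$mlp$W, m2$mlp$W)
})

test_that("grid search returns the validation argmin", {
  ds <- generate_dataset(3000, test_scheme, mode = 6, nr = 0.05, seed = 56)
  val <- generate_dataset(800, test_scheme, mode = 6, nr = 0.05, seed = 57)

  single <- hyper_grid(mid_layers = 3, units = 64, dropout = 0,
                       epochs = 5, batch_size = 1000)
  gs1 <- grid_search(ds, val, single, "K", seed = 58)
  expect_equal(nrow(gs1$results), 1L)
  expect_equal(gs1$best$units, 64L)

  grid <- hyper_grid(mid_layers = c(2, 3), units = c(16, 32), dropout = 0,
                     epochs = 5, batch_size = 1000)
  gs <- grid_search(ds, val, grid, "K", seed = 59)
  expect_equal(nrow(gs$results), 4L)
  expect_true(all(gs$model$val_rmse <= gs$results$val_rmse))
  chosen <- gs$results$val_rmse == gs$model$val_rmse
  expect_true(any(chosen))
})

test_that("volume prediction matches hand-built neighbourhood features", {
  ds <- generate_dataset(4000, test_scheme, mode = 6, nr = 0, seed = 60)
  mdl <- quick_model(ds, target = "K", epochs = 15)

  # build a 3x3x1 volume with distinct voxel parameters
  set.seed(61)
  p <- sample_center_params(dki_ranges(), test_scheme, n = 9)
  nb <- length(test_scheme$bvalues)
  dwi <- array(0, c(3, 3, 1, nb))
  for (v in 1:9) {
    ix <- (v - 1) %% 3 + 1; iy <- (v - 1) %/% 3 + 1
    dwi[ix, iy, 1, ] <- dki_signal(test_scheme$bvalues, p$s0[v], p$d[v], p$k[v])
  }
  pred <- predict_volume(dwi, test_scheme, mdl)
  expect_equal(dim(pred$map), c(3, 3, 1))
  expect_false(any(pred$guard))

  # interior voxel (2,2): its 3x3 in-slice neighbourhood needs no padding;
  # assemble the feature row by hand in the documented order
  ratio <- function(ix, iy) dwi[ix, iy, 1, -1] / dwi[ix, iy, 1, 1]
  ## documented order is row-major: row offset outer, column offset inner
  feats <- c()
  for (dr in -1:1) for (dc in -1:1) feats <- c(feats, ratio(2 + dr, 2 + dc))
  manual <- predict(mdl$mlp, matrix(feats, 1))
  expect_equal(pred$map[2, 2, 1], manual, tolerance = 1e-12)

  # corner voxel (1,1): replicate padding duplicates edge neighbours
  feats_c <- c()
  for (dr in -1:1) for (dc in -1:1)
    feats_c <- c(feats_c, ratio(max(1, 1 + dr), max(1, 1 + dc)))
  manual_c <- predict(mdl$mlp, matrix(feats_c, 1))
  expect_equal(pred$map[1, 1, 1], manual_c, tolerance = 1e-12)
})

test_that("uniform volumes give uniform maps near the truth", {
  truth <- list(s0 = 2000, d = 1.1e-3, k = 0.6)
  nb <- length(test_scheme$bvalues)
  vol <- array(rep(dki_signal(test_scheme$bvalues, truth$s0, truth$d, truth$k),
                   each = 6 * 6 * 2), c(6, 6, 2, nb))
  train <- generate_dataset(1e4, test_scheme, mode = 1, nr = 0, seed = 62)
  mdl <- train_mlp(train, "K", "synxqsl", hyper = hyper_config(epochs = 25),
                   seed = 63,
                   validation = generate_dataset(2000, test_scheme, mode = 1,
                                                 nr = 0, seed = 64))
  pred <- predict_volume(vol, test_scheme, mdl)
  expect_lt(max(abs(pred$map - truth$k)), max(3 * mdl$val_rmse, 0.05))

  # synQSL sees identical features at every voxel of a uniform image
  mdl_q <- train_mlp(train, "K", "synqsl", hyper = hyper_config(epochs = 10),
                     seed = 65)
  pred_q <- predict_volume(vol, test_scheme, mdl_q)
  expect_lt(diff(range(pred_q$map)), 1e-10)   # identical features everywhere
})

test_that("low-signal voxels are guarded and feature order round-trips", {
  ds <- generate_dataset(2000, test_scheme, mode = 6, nr = 0.05, seed = 66)
  mdl <- quick_model(ds, epochs = 5)

  nb <- length(test_scheme$bvalues)
  vol <- array(500, c(4, 4, 1, nb))
  vol[2, 2, 1, ] <- 0                       # dead voxel
  pred <- predict_volume(vol, test_scheme, mdl)
  expect_true(pred$guard[2, 2, 1])
  expect_identical(pred$map[2, 2, 1], 0)

  # permuting named feature columns must not change predictions
  x <- dataset_features(ds, "synxqsl")[1:20, ]
  perm <- sample(ncol(x))
  expect_equal(predict(mdl, x[, perm]), predict(mdl, x))
  expect_error(predict(mdl, x[, 1:10]), "feature")

  # persistence round trip
  path <- withr::local_tempfile(fileext = ".rds")
  write_regressor(mdl, path)
  back <- read_regressor(path)
  expect_equal(predict(back, x), predict(mdl, x))
  expect_true(file.exists(sub("rds$", "json", path)))
})
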