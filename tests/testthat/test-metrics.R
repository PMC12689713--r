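test_that("signed-error statistics match a brute-force loop oracle", {
  x <- array(1:24, c(4, 3, 2))
  expect_equal(signed_error_stats(x, x)[c("rms", "min", "max")],
               list(rms = 0, min = 0, max = 0))
  st <- signed_error_stats(x + 0.5, x)
  expect_equal(st[c("rms", "min", "max")], list(rms = 0.5, min = 0.5, max = 0.5))

  set.seed(90)
  est <- array(rnorm(1000), c(10, 10, 10))
  tru <- array(rnorm(1000), c(10, 10, 10))
  msk <- array(runif(1000) > 0.4, c(10, 10, 10))
  st <- signed_error_stats(est, tru, msk)
  # longhand voxel loop
  errs <- c()
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    if (msk[i, j, k]) errs <- c(errs, est[i, j, k] - tru[i, j, k])
  expect_equal(st$rms, sqrt(mean(errs^2)), tolerance = 1e-12)
  expect_equal(st$min, min(errs), tolerance = 1e-12)
  expect_equal(st$max, max(errs), tolerance = 1e-12)

  # mask-order invariance: permuting voxels does not change the stats
  perm <- sample(1000)
  st_p <- signed_error_stats(array(est[perm], dim(est)),
                             array(tru[perm], dim(tru)),
                             array(msk[perm], dim(msk)))
  expect_equal(st_p[c("rms", "min", "max")], st[c("rms", "min", "max")])
  expect_error(signed_error_stats(est, tru, msk & FALSE), "empty")
})

test_that("region SNR averages per-region mean/SD ratios", {
  labels <- array(0L, c(50, 20, 10))
  labels[1:25, , ] <- 1L
  labels[26:50, , ] <- 2L
  set.seed(91)
  map <- array(0, c(50, 20, 10))
  map[labels == 1] <- rnorm(5000, 10, 2)      # SNR ~ 5
  map[labels == 2] <- rnorm(5000, 30, 3)      # SNR ~ 10
  rs <- region_snr(map, labels)
  expect_lt(abs(rs$regions$snr[1] - 5) / 5, 0.05)
  # reported value is the hand-computed mean of per-region SNRs
  expect_equal(rs$snr, mean(rs$regions$snr))

  # constant region flagged infinite and excluded from the average
  map[labels == 2] <- 7
  rs2 <- region_snr(map, labels)
  expect_true(is.infinite(rs2$regions$snr[2]))
  expect_equal(rs2$snr, rs2$regions$snr[1])
  expect_true(is.infinite(region_snr(array(5, c(4, 4, 1)),
                                     array(1L, c(4, 4, 1)))$snr))
})

test_that("CNR follows the pooled-SD definition and is symmetric", {
  map <- array(0, c(6, 1, 1))
  map[1:3] <- c(1, 2, 3)        # mean 2, sd 1
  map[4:6] <- c(0, 1, 2)        # mean 1, sd 1
  fg <- array(c(rep(TRUE, 3), rep(FALSE, 3)), c(6, 1, 1))
  bg <- !fg
  expect_equal(cnr(map, fg, bg), 1 / sqrt(2))
  expect_equal(cnr(map, bg, fg), cnr(map, fg, bg))   # symmetry

  map2 <- map; map2[4:6] <- c(1, 2, 3)               # equal means
  expect_equal(cnr(map2, fg, bg), 0)
  expect_error(cnr(map, fg & FALSE, bg), "empty")
})

test_that("SSIM identities and monotonic degradation hold", {
  set.seed(92)
  truth <- array(0, c(40, 40, 2))
  truth[10:30, 10:30, ] <- 1
  truth <- truth + array(rnorm(3200, 0, 0.05), dim(truth))
  expect_equal(map_ssim(truth, truth), 1)

  # anti-correlated map scores strictly below 1
  expect_lt(map_ssim(-truth, truth), 1 - 0.1)

  # SSIM decreases monotonically with noise amplitude
  vals <- vapply(c(0.05, 0.2, 0.5), function(a) {
    set.seed(93)
    map_ssim(truth + array(rnorm(3200, 0, a), dim(truth)), truth)
  }, 1.0)
  expect_true(all(diff(vals) < 0))
  expect_error(map_ssim(truth[1:8, 1:8, , drop = FALSE],
                        truth[1:8, 1:8, , drop = FALSE]),
               "window|empty")

  # anti-correlated comparison also matches the reference cross-check
  # (covered numerically in the scikit-image test below)
})

test_that("SSIM agrees with the scikit-image reference implementation", {
  set.seed(94)
  a <- matrix(runif(48 * 40), 48, 40)
  b <- a + matrix(rnorm(48 * 40, 0, 0.15), 48, 40)
  dr <- diff(range(a))
  ours <- map_ssim(b, a, data_range = dr)

  td <- withr::local_tempdir()
  write.table(a, file.path(td, "a.csv"), row.names = FALSE, col.names = FALSE, sep = ",")
  write.table(b, file.path(td, "b.csv"), row.names = FALSE, col.names = FALSE, sep = ",")
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from skimage.metrics import structural_similarity as ssim\n",
    "a = np.loadtxt('%s/a.csv', delimiter=',')\n",
    "b = np.loadtxt('%s/b.csv', delimiter=',')\n",
    "print(float(ssim(b, a, gaussian_weights=True, sigma=1.5,\n",
    "      use_sample_covariance=False, data_range=%.17g)))\n"),
    td, td, dr)
  ref <- as.numeric(system2("python", "-", stdout = TRUE, input = script))
  expect_equal(ours, ref, tolerance = 1e-6)
})
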