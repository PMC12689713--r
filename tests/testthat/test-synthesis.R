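test_that("basis vectors are the canonical 3x3 patterns with zero centers", {
  U <- xq_bases(6)
  expected <- rbind(
    u1 = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    u2 = c(-1, 0, 1, -1, 0, 1, -1, 0, 1),
    u3 = c(-1, -1, -1, 0, 0, 0, 1, 1, 1),
    u4 = c(1, 0, 1, 1, 0, 1, 1, 0, 1),
    u5 = c(1, 1, 1, 0, 0, 0, 1, 1, 1),
    u6 = c(1, 0, -1, 0, 0, 0, -1, 0, 1))
  expect_equal(U, expected)
  expect_true(all(U[, 5] == 0))                       # zero center, all bases
  expect_equal(xq_bases("linear"), U[1:3, ])          # nested mode subsets
  expect_equal(xq_bases("flat"), U[1, , drop = FALSE])
  expect_error(xq_bases(4), "mode")
})

test_that("center sampling is uniform on the constraint-truncated region", {
  rng <- dki_ranges()
  p <- sample_center_params(rng, test_scheme, n = 1e4, seed = 5)
  expect_true(all(monotonic_decay_ok(p$d, p$k, test_scheme$b_max)))
  expect_true(all(p$s0 >= 500 & p$s0 <= 8000))
  expect_true(all(p$d >= 0.2e-3 & p$d <= 6.0e-3))

  # joint truncation: K marginal is no longer uniform on [0, 4] —
  # compare against a brute-force accept/reject oracle
  set.seed(6)
  ok <- ko <- numeric(0)
  while (length(ko) < 1e4) {
    d <- runif(2e4, 0.2e-3, 6e-3)
    k <- runif(2e4, 0, 4)
    keep <- d * k < 3 / 2500
    ko <- c(ko, k[keep])
  }
  expect_gt(stats::ks.test(p$k, sample(ko, 1e4))$p.value, 0.01)
  expect_lt(stats::ks.test(p$k, runif(1e4, 0, 4))$p.value, 0.01)

  # K pinned to 0 makes the constraint vacuous: D is plain uniform
  p0 <- sample_center_params(dki_ranges(k = c(0, 0)), test_scheme,
                             n = 1e4, seed = 7)
  expect_gt(stats::ks.test(p0$d, "punif", 0.2e-3, 6e-3)$p.value, 0.01)
})

test_that("pattern expansion reproduces the linear-combination algebra", {
  rng <- dki_ranges()
  ctr <- data.frame(s0 = 2000, d = 1.5e-3, k = 0.5)

  # flat mode: nine identical cells equal to the center
  pat1 <- expand_to_pattern(ctr, 1, rng, test_scheme, seed = 8)
  expect_true(all(pat1$s0 == 2000) && all(pat1$d == 1.5e-3) && all(pat1$k == 0.5))

  # any mode: the center cell is the sampled triple, bit-exactly
  for (m in c(1, 3, 6)) {
    pat <- expand_to_pattern(ctr, m, rng, test_scheme, seed = 8 + m)
    expect_identical(pat$d[5], 1.5e-3)
    expect_identical(pat$s0[5], 2000)
    # grid reconstructs exactly from center + sum of weighted bases
    U <- xq_bases(m)
    for (par in c("s0", "d", "k")) {
      ctr_val <- pat$center[[par]]
      expect_equal(pat[[par]],
                   as.vector(ctr_val + pat$weights[[par]] %*% U))
    }
    # all nine cells physically valid
    expect_true(all(pat$s0 > 0 & pat$d > 0 & pat$k >= 0))
    expect_true(all(monotonic_decay_ok(pat$d, pat$k, test_scheme$b_max)))
  }

  # hand-evaluated u2 geometry: weight 0.1e-3 on u2 for D gives grid
  # columns (D0 - 0.1e-3, D0, D0 + 0.1e-3) in every row
  d0 <- 1.5e-3
  grid <- matrix(d0 + 0.1e-3 * xq_bases(3)[2, ], 3, 3, byrow = TRUE)
  expect_equal(grid[, 1], rep(d0 - 0.1e-3, 3))
  expect_equal(grid[, 2], rep(d0, 3))
  expect_equal(grid[, 3], rep(d0 + 0.1e-3, 3))

  # a center violating the decay bound is refused
  expect_error(expand_to_pattern(data.frame(s0 = 1000, d = 2e-3, k = 1),
                                 6, rng, test_scheme), "bound")

  # pinning all weights to zero collapses any mode to the flat pattern
  rng0 <- dki_ranges(w_s0 = c(0, 0), w_d = c(0, 0), w_k = c(0, 0))
  pat0 <- expand_to_pattern(ctr, 6, rng0, test_scheme, seed = 9)
  expect_true(all(pat0$d == 1.5e-3) && all(pat0$s0 == 2000))
})

test_that("noise-free features are S0-free decay ratios", {
  ctr <- data.frame(s0 = 3000, d = 1.2e-3, k = 0.9)
  pat <- expand_to_pattern(ctr, 1, dki_ranges(), test_scheme, seed = 10)
  smp <- synthesize_sample(pat, test_scheme)
  expect_length(smp$features, 9 * test_scheme$n_nonzero)
  b <- test_scheme$bvalues[-1]
  expected_block <- exp(-b * 1.2e-3 + b^2 * (1.2e-3)^2 * 0.9 / 6)
  expect_equal(unname(smp$features), rep(expected_block, 9))

  # features are independent of S0 entirely (ratio invariance)
  ctr2 <- ctr; ctr2$s0 <- 123
  pat2 <- expand_to_pattern(ctr2, 1, dki_ranges(), test_scheme, seed = 10)
  smp2 <- synthesize_sample(pat2, test_scheme)
  expect_equal(smp$features, smp2$features)
  expect_equal(unname(smp$targets), c(1.2e-3, 0.9))
})

test_that("noisy decay ratios carry the Rician bias of an independent oracle", {
  # fixed flat triple, NR = 0.1: mean feature at each b deviates upward
  # from the noise-free ratio, matching brute-force Monte Carlo
  rngs <- fixed_triple_ranges(s0 = 1000, d_scaled = 1.0, k = 0.8)
  ds <- generate_dataset(5e3, test_scheme, rngs, mode = 1, nr = 0.1, seed = 12)
  sigma <- ds$meta$sigma
  b <- test_scheme$bvalues[-1]
  clean <- oracle_dki_signal(b, 1000, 1e-3, 0.8)

  set.seed(13)
  n_mc <- 5e3 * 9
  for (j in c(1, 6)) {             # lowest and highest non-zero b
    cols <- seq(j, 54, by = test_scheme$n_nonzero)
    got <- mean(ds$features[, cols])
    mc <- sqrt(clean[j]^2 + rnorm(n_mc, 0, sigma)^2) /
      sqrt(1000^2 + rnorm(n_mc, 0, sigma)^2)
    expect_gt(got, clean[j] / 1000)          # upward Rician bias
    expect_lt(abs(got - mean(mc)), 3 * sd(mc) / sqrt(n_mc) + 3 * sd(mc) / sqrt(n_mc))
  }
})

test_that("dataset generation is deterministic and correctly shaped", {
  ds1 <- generate_dataset(300, test_scheme, mode = 6, nr = 0.05, seed = 14,
                          keep_signals = TRUE)
  ds2 <- generate_dataset(300, test_scheme, mode = 6, nr = 0.05, seed = 14,
                          keep_signals = TRUE)
  expect_identical(ds1$features, ds2$features)
  expect_identical(ds1$targets, ds2$targets)
  expect_identical(ds1$signals, ds2$signals)

  expect_equal(ncol(ds1$features), 54)       # 9N with N = 6
  expect_equal(ds1$meta$feature_order[1:2], c("loc1.b50", "loc1.b850"))
  expect_equal(ds1$meta$sigma, 0.05 * 4250)  # NR x midpoint of S0 range

  # NR = 0: every signal equals the forward model of its cell
  ds0 <- generate_dataset(50, test_scheme, mode = 1, nr = 0, seed = 15,
                          keep_signals = TRUE)
  for (j in seq_along(test_scheme$bvalues)) {
    expect_equal(ds0$signals[, 5, j],
                 oracle_dki_signal(test_scheme$bvalues[j], ds0$targets$s0,
                                   ds0$targets$d, ds0$targets$k))
  }

  # serialization round trip
  dir <- withr::local_tempdir()
  write_xq_dataset(ds1, dir, csv = FALSE)
  back <- read_xq_dataset(dir)
  expect_identical(back$features, ds1$features)
  expect_true(file.exists(file.path(dir, "meta.json")))
})
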