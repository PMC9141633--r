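# The four pairwise FC estimators.

test_that("pcor is the absolute correlation of the mean series", {
  x <- region_activity(matrix(c(1, 2, 3, 4), 1))
  y <- region_activity(matrix(c(1, 2, 3, 5), 1))
  expect_equal(fc_pcor(x, y), abs(pearson_by_hand(c(1, 2, 3, 4),
                                                  c(1, 2, 3, 5))),
               tolerance = 1e-12)
  expect_equal(fc_pcor(x, y), 0.9827, tolerance = 1e-4)

  # perfect linear and perfect anticorrelated both give 1 (absolute value)
  set.seed(21)
  s <- rnorm(50)
  a <- region_activity(rbind(s, s))
  expect_equal(fc_pcor(a, region_activity(matrix(3 * s + 2, 1))), 1)
  expect_equal(fc_pcor(a, region_activity(matrix(-s, 1))), 1)
  expect_error(fc_pcor(a, region_activity(matrix(rep(1, 50), 1))),
               "zero-variance")
})

test_that("svd measure reduces to pcor on homogeneous regions", {
  set.seed(23)
  sx <- rnorm(80)
  sy <- 0.7 * sx + 0.3 * rnorm(80)
  x <- region_activity(rbind(sx, sx, sx))
  y <- region_activity(rbind(sy, sy))
  expect_equal(fc_svd(x, y), fc_pcor(x, y), tolerance = 1e-8)

  # invariant under voxel permutation within each region
  x2 <- region_activity(matrix(rnorm(400), 5, 80))
  expect_equal(fc_svd(x2, y),
               fc_svd(region_activity(x2$data[c(4, 1, 5, 2, 3), ]), y),
               tolerance = 1e-10)
})

test_that("uvmi is rank-invariant in the mean series and tracks r", {
  set.seed(25)
  n <- 10000
  s <- rnorm(n)
  y <- region_activity(matrix(0.8 * s + 0.6 * rnorm(n), 1))
  x <- region_activity(matrix(s, 1))
  # monotone transform of the (single-voxel) series leaves the value alone
  expect_identical(fc_uvmi(region_activity(matrix(exp(s), 1)), y),
                   fc_uvmi(x, y))
  # jointly Gaussian means with r = 0.8 recover ~0.8 after rescaling
  expect_equal(fc_uvmi(x, y), 0.8, tolerance = 0.02)
})

test_that("mvmi detects deterministic multivoxel dependence", {
  set.seed(27)
  x <- region_activity(matrix(rnorm(8 * 200), 8, 200))
  y <- region_activity(x$data[sample(8), ] + 0.01 * rnorm(8 * 200))
  v <- fc_mvmi(x, y, n_components = 3)
  expect_gt(v, 0.9)
  # voxel reordering leaves the value essentially unchanged
  y2 <- region_activity(y$data[sample(8), ])
  expect_equal(fc_mvmi(x, y2, n_components = 3), v, tolerance = 1e-6)
  expect_error(fc_mvmi(region_activity(matrix(rnorm(33), 3, 11)),
                       region_activity(matrix(rnorm(33), 3, 11))),
               "more than 11 timepoints")
})

test_that("all measures are symmetric and within range", {
  set.seed(29)
  for (i in 1:5) {
    x <- region_activity(matrix(rnorm(6 * 80), 6, 80))
    y <- region_activity(matrix(rnorm(9 * 80), 9, 80))
    for (m in fc_measure_names()) {
      v1 <- fc_measure(x, y, m, n_components = 2)
      v2 <- fc_measure(y, x, m, n_components = 2)
      expect_equal(v1, v2, tolerance = 1e-10)
      expect_gte(v1, 0)
      expect_lte(v1, 1)
    }
  }
})

test_that("single-voxel regions collapse mvmi to uvmi and svd to pcor", {
  set.seed(31)
  x <- region_activity(matrix(rnorm(60), 1))
  y <- region_activity(matrix(0.5 * x$data + rnorm(60), 1))
  expect_equal(fc_svd(x, y), fc_pcor(x, y), tolerance = 1e-12)
  expect_equal(suppressWarnings(fc_mvmi(x, y, n_components = 1)),
               fc_uvmi(x, y), tolerance = 1e-12)
})
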