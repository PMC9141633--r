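# Covariance regimes and the two-region scenario generator.

test_that("covariance regimes match their defining formulas", {
  expect_identical(make_covariance("independent", 3), diag(3))
  expect_equal(make_covariance("homogeneous", 2),
               matrix(c(1, 0.9, 0.9, 1), 2))
  m <- make_covariance("mixed", 4, strength = 0.9)
  expect_equal(m[1, 2], 0.9)    # within first half
  expect_equal(m[3, 4], 0.9)    # within second half
  expect_equal(m[1, 3], -0.9)   # across halves
  # eigenvalues {1 - c (x3), 1 + 3c} via an independent eigensolver
  expect_equal(sort(eigen(m, symmetric = TRUE)$values),
               sort(c(rep(0.1, 3), 3.7)), tolerance = 1e-10)
  expect_error(make_covariance("homogeneous", 2, strength = 1.2), "0, 1")
})

test_that("noiseless linear scenario is an identity mapping", {
  sp <- scenario_spec("linear", "homogeneous", n_x = 10, n_y = 15,
                      n_timepoints = 100, mapping_noise_sd = 0,
                      measurement_noise_sd = 0)
  p <- simulate_pair(sp, seed = 1)
  expect_equal(p$y$data[1:10, ], p$x$data, tolerance = 1e-12)
  expect_equal(fc_pcor(p$x, p$y), 1, tolerance = 1e-12)
})

test_that("simulation is deterministic given the seed", {
  sp <- scenario_spec("multivariate", "mixed", n_x = 8, n_y = 12,
                      n_timepoints = 50, seed = 42)
  p1 <- simulate_pair(sp)
  p2 <- simulate_pair(sp)
  expect_identical(p1$x$data, p2$x$data)
  expect_identical(p1$y$data, p2$y$data)
  p3 <- simulate_pair(sp, seed = 43)
  expect_false(identical(p1$x$data, p3$x$data))
})

test_that("source region covariance matches its regime empirically", {
  for (regime in c("homogeneous", "independent", "mixed")) {
    sp <- scenario_spec("linear", regime, n_x = 6, n_y = 6,
                        n_timepoints = 2000, measurement_noise_sd = 0)
    p <- simulate_pair(sp, seed = 7)
    emp <- cov(t(p$x$data))
    expect_lt(max(abs(emp - make_covariance(regime, 6))), 0.1)
  }
})

test_that("structural noise adds one shared series to every voxel of Y", {
  sp0 <- scenario_spec("structural_noise", "independent", n_x = 5, n_y = 5,
                       n_timepoints = 80, mapping_noise_sd = 0,
                       measurement_noise_sd = 0, structural_noise_sd = 0)
  sp1 <- scenario_spec("structural_noise", "independent", n_x = 5, n_y = 5,
                       n_timepoints = 80, mapping_noise_sd = 0,
                       measurement_noise_sd = 0, structural_noise_sd = 2)
  y0 <- simulate_pair(sp0, seed = 5)$y$data
  y1 <- simulate_pair(sp1, seed = 5)$y$data
  added <- y1 - y0
  # identical series on all voxels, with the configured scale
  expect_lt(max(abs(sweep(added, 2, added[1, ]))), 1e-12)
  expect_gt(sd(added[1, ]), 1)
})

test_that("null shuffling preserves voxel marginals but breaks coupling", {
  sp <- scenario_spec("linear", "homogeneous", n_x = 6, n_y = 8,
                      n_timepoints = 500, mapping_noise_sd = 0,
                      measurement_noise_sd = 0)
  p <- simulate_pair(sp, seed = 9)
  np <- null_pair(p, seed = 1)
  for (i in 1:6) {
    expect_identical(sort(np$x$data[i, ]), sort(p$x$data[i, ]))
  }
  expect_false(identical(np$x$data, null_pair(p, seed = 2)$x$data))
  # coupling destroyed: gcmi of the mean series near zero
  expect_lt(gcmi(colMeans(np$x$data), colMeans(np$y$data)), 0.05)
  expect_lt(fc_pcor(np$x, np$y), 0.2)
})
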