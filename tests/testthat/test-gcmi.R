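# Copula transform and Gaussian(-copula) entropy/MI building blocks.

test_that("copula transform maps ranks to the normal quantile grid", {
  out <- copula_transform(c(10, 20, 30))
  expect_equal(as.numeric(out), qnorm(c(1, 2, 3) / 4), tolerance = 1e-12)

  # invariance under strictly increasing per-dimension transforms, exact
  set.seed(41)
  x <- matrix(rnorm(60), 3, 20)
  x2 <- rbind(exp(x[1, ]), atan(x[2, ]), x[3, ]^3)
  expect_identical(copula_transform(x), copula_transform(x2))

  # tied entries share a value under average ranks
  out <- copula_transform(c(1, 2, 2, 5), tie_rule = "average")
  expect_identical(out[2], out[3])

  # transformed rows are marginally standard-normal on the rank grid
  g <- copula_transform(matrix(runif(200), 2, 100))
  expect_equal(rowMeans(g), c(0, 0), tolerance = 1e-12)
  expect_equal(sort(g[1, ]), qnorm(seq_len(100) / 101))
})

test_that("copula transform rejects degenerate input", {
  expect_error(copula_transform(matrix(c(1, 1, 1, 2, 3, 4), 2, 3,
                                       byrow = TRUE)),
               "dimension 1")
  expect_error(copula_transform(c(1, NA, 3)), "missing")
  expect_error(copula_transform(c(1, 2)), "at least 3")
})

test_that("Gaussian entropy matches the closed form", {
  h1 <- 0.5 * log2(2 * pi * exp(1))
  expect_equal(gaussian_entropy(1), h1, tolerance = 1e-12)
  expect_equal(gaussian_entropy(diag(2)), 2 * h1, tolerance = 1e-12)
  expect_equal(gaussian_entropy(4), h1 + 1, tolerance = 1e-12)
  expect_error(gaussian_entropy(matrix(c(1, 2, 2, 1), 2)),
               "not positive-definite")
  expect_error(gaussian_entropy(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("Gaussian MI matches the univariate closed form and entropy sum", {
  expect_equal(gaussian_mi(1, 1, diag(2)), 0, tolerance = 1e-12)
  for (r in c(0.2, 0.5, 0.8)) {
    sj <- matrix(c(1, r, r, 1), 2)
    expect_equal(gaussian_mi(1, 1, sj), -0.5 * log2(1 - r^2),
                 tolerance = 1e-12)
    sj_neg <- matrix(c(1, -r, -r, 1), 2)
    expect_identical(gaussian_mi(1, 1, sj), gaussian_mi(1, 1, sj_neg))
  }
  expect_error(gaussian_mi(1, 2, diag(2)), "diagonal blocks")
})

test_that("MI via determinants equals H(X)+H(Y)-H(X,Y) on random covariances", {
  set.seed(7)
  for (i in 1:25) {
    kx <- sample(1:3, 1)
    ky <- sample(1:3, 1)
    a <- matrix(rnorm((kx + ky)^2), kx + ky)
    sj <- crossprod(a) + diag(0.5, kx + ky)
    sx <- sj[seq_len(kx), seq_len(kx), drop = FALSE]
    sy <- sj[kx + seq_len(ky), kx + seq_len(ky), drop = FALSE]
    expect_equal(gaussian_mi(sx, sy, sj),
                 gaussian_entropy(sx) + gaussian_entropy(sy) -
                   gaussian_entropy(sj),
                 tolerance = 1e-10)
  }
})

test_that("gcmi is rank-invariant, consistent and validates its inputs", {
  set.seed(11)
  x <- matrix(rnorm(400), 2, 200)
  y <- matrix(rnorm(400), 2, 200)
  expect_identical(gcmi(exp(x), y), gcmi(x, y))

  # near-zero on independent data, close to the generating MI on coupled data
  expect_lt(gcmi(x[1, ], y[1, ]), 0.05)
  n <- 10000
  z <- rnorm(n)
  w <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)
  expect_lt(abs(gcmi(z, w) - (-0.5 * log2(1 - 0.25))), 0.03)

  expect_error(gcmi(x, y[, 1:100]), "same number of observations")
  expect_error(gcmi(matrix(rnorm(50), 5, 10), matrix(rnorm(50), 5, 10)),
               "rank-deficient")
  expect_gte(gcmi(x, y), 0)
})

test_that("bias correction lowers the estimate and can trigger clipping", {
  set.seed(13)
  x <- matrix(rnorm(300), 3, 100)
  y <- matrix(rnorm(300), 3, 100)
  raw <- gcmi(x, y)
  corrected <- suppressWarnings(gcmi(x, y, bias_correction = TRUE))
  expect_lt(corrected, raw)
  expect_gte(corrected, 0)
  # on independent data the corrected estimate is much closer to zero
  expect_lt(corrected, 0.05)
})

test_that("gcmi does not exceed a KSG estimate on heavy-tailed copula data", {
  # Gaussian-copula MI is a lower bound on the true MI; compare against an
  # independent nearest-neighbour estimator on t-copula data
  set.seed(17)
  g <- k <- numeric(3)
  for (i in 1:3) {
    s <- rtcopula(800, rho = 0.7, df = 3)
    g[i] <- gcmi(s[1, ], s[2, ])
    k[i] <- ksg_mi(s[1, ], s[2, ])
  }
  expect_lt(mean(g), mean(k) + 2 * sd(k))
})

test_that("rescale_mi inverts the Gaussian MI-correlation relation", {
  expect_identical(rescale_mi(0), 0)
  expect_equal(rescale_mi(-0.5 * log2(1 - 0.25)), 0.5, tolerance = 1e-12)
  expect_equal(rescale_mi(-0.5 * log2(1 - 0.81)), 0.9, tolerance = 1e-12)
  mi <- sort(runif(10, 0, 5))
  r <- rescale_mi(mi)
  expect_true(all(diff(r) > 0))        # strictly increasing
  expect_true(all(r >= 0 & r < 1))
  expect_error(rescale_mi(-0.1), "non-negative")
})
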