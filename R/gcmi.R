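#' Rank-based Gaussian copula transform
#'
#' Maps each dimension (row) of a multivariate sample to standard-normal
#' quantiles of its empirical ranks: value -> rank -> rank/(n+1) ->
#' \code{qnorm}. The transform depends on the data only through the
#' per-dimension orderings, so it is invariant under any strictly increasing
#' transform applied to a dimension, and the transformed rows are marginally
#' standard-normal by construction. The rank/(n+1) convention keeps all
#' quantiles finite.
#'
#' @param x numeric matrix, dimensions x observations, or a numeric vector
#'   (treated as one dimension). At least 3 observations.
#' @param tie_rule how tied values are ranked: \code{"average"} (tied entries
#'   receive equal output values; the default) or \code{"ordinal"}
#'   (first-occurrence order, which keeps the output set of quantiles exactly
#'   rank-determined even under ties).
#' @return numeric matrix of the same shape; each row marginally
#'   standard-normal on the rank grid.
#' @examples
#' copula_transform(c(10, 20, 30))          # qnorm(c(.25, .5, .75))
#' x <- rnorm(50)
#' identical(copula_transform(x), copula_transform(exp(x)))
#' @seealso [gcmi()]
#' @export
copula_transform <- function(x, tie_rule = c("average", "ordinal")) {
  tie_rule <- match.arg(tie_rule)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (dimensions x observations) or vector")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("`x` contains missing or non-finite values")
  }
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 observations, got ", n)
  method <- if (tie_rule == "average") "average" else "first"
  out <- x
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    if (max(row) == min(row)) {
      stop("dimension ", i, " is constant (all values tied); ",
           "ranks are undefined")
    }
    out[i, ] <- qnorm(rank(row, ties.method = method) / (n + 1))
  }
  out
}

# log2-determinant via Cholesky with a single jitter retry.
# Policy: if the smallest eigenvalue is below 1e-10 * trace, add
# 1e-10 * trace * I once; if still not positive-definite, fail and report
# the smallest eigenvalue.
logdet2 <- function(sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    tr <- sum(diag(sigma))
    sigma2 <- sigma + diag(1e-10 * tr, nrow(sigma))
    ch <- tryCatch(chol(sigma2), error = function(e) NULL)
    if (is.null(ch)) {
      ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
      stop("covariance matrix is not positive-definite after jitter ",
           "(smallest eigenvalue ", format(ev), ")")
    }
  }
  2 * sum(log2(diag(ch)))
}

#' Closed-form entropy of a multivariate Gaussian
#'
#' \eqn{H = \tfrac12 \log_2\{(2\pi e)^k |\Sigma|\}} bits, where
#' \eqn{k} is the dimension and \eqn{|\Sigma|} the covariance determinant.
#' A covariance that is numerically singular (smallest eigenvalue below
#' 1e-10 of the trace) receives one diagonal jitter of 1e-10 * trace before
#' failing.
#'
#' @param sigma symmetric positive-definite covariance matrix (or a scalar
#'   variance).
#' @return entropy in bits.
#' @examples
#' gaussian_entropy(1)              # 0.5 * log2(2*pi*e) ~ 2.047
#' gaussian_entropy(diag(2))        # twice the univariate value
#' @export
gaussian_entropy <- function(sigma) {
  if (is_scalar_number(sigma)) sigma <- matrix(sigma, 1L, 1L)
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    stop("`sigma` must be a square matrix")
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("`sigma` must be symmetric")
  }
  k <- nrow(sigma)
  0.5 * (k * log2(2 * pi * exp(1)) + logdet2(sigma))
}

#' Mutual information between jointly Gaussian variables
#'
#' For jointly Gaussian \eqn{X} (dimension \eqn{k_X}) and \eqn{Y}
#' (dimension \eqn{k_Y}):
#' \eqn{MI = \tfrac12 \log_2(|\Sigma_X||\Sigma_Y|/|\Sigma_{XY}|)} bits,
#' identically \eqn{H(X)+H(Y)-H(X,Y)}. In the univariate case this reduces
#' to \eqn{-\tfrac12 \log_2(1-r^2)} with \eqn{r} the correlation.
#'
#' @param sigma_x,sigma_y marginal covariance matrices (or scalar variances).
#' @param sigma_joint joint covariance of \code{c(X, Y)}; its diagonal blocks
#'   must equal \code{sigma_x} and \code{sigma_y}.
#' @return mutual information in bits (non-negative for any valid joint
#'   covariance).
#' @examples
#' r <- 0.5
#' gaussian_mi(1, 1, matrix(c(1, r, r, 1), 2))  # -0.5 * log2(1 - 0.25)
#' @export
gaussian_mi <- function(sigma_x, sigma_y, sigma_joint) {
  if (is_scalar_number(sigma_x)) sigma_x <- matrix(sigma_x, 1L, 1L)
  if (is_scalar_number(sigma_y)) sigma_y <- matrix(sigma_y, 1L, 1L)
  kx <- nrow(sigma_x)
  ky <- nrow(sigma_y)
  if (!is.matrix(sigma_joint) || nrow(sigma_joint) != kx + ky) {
    stop("`sigma_joint` must be a ", kx + ky, " x ", kx + ky, " matrix")
  }
  tol <- 1e-8 * max(1, max(abs(sigma_joint)))
  if (max(abs(sigma_joint[seq_len(kx), seq_len(kx)] - sigma_x)) > tol ||
      max(abs(sigma_joint[kx + seq_len(ky), kx + seq_len(ky)] - sigma_y)) > tol) {
    stop("diagonal blocks of `sigma_joint` do not match `sigma_x`/`sigma_y`")
  }
  0.5 * (logdet2(sigma_x) + logdet2(sigma_y) - logdet2(sigma_joint))
}

# Finite-sample bias of the Gaussian-copula MI estimate, in bits.
# Digamma-series correction for log-determinants of Wishart-distributed
# sample covariances (dimension-count terms cancel between the three
# entropies, leaving only the digamma sums).
gcmi_bias_bits <- function(kx, ky, n) {
  psi_terms <- digamma((n - seq_len(kx + ky)) / 2) / 2
  (sum(psi_terms[seq_len(kx)]) + sum(psi_terms[seq_len(ky)]) -
      sum(psi_terms)) / log(2)
}

#' Gaussian-copula mutual information estimator
#'
#' Estimates MI between two (possibly multivariate) samples by transforming
#' every dimension to standard-normal rank quantiles
#' ([copula_transform()]), fitting a joint Gaussian to the transformed data,
#' and evaluating the closed-form Gaussian MI of its covariance blocks. The
#' copula (and hence the MI) does not depend on the marginal distributions,
#' so the estimate is exactly invariant under strictly monotone
#' per-dimension transforms of the inputs. Because the Gaussian has maximum
#' entropy for a given covariance, the estimate is a lower bound on the true
#' MI.
#'
#' @param x,y numeric matrices (dimensions x observations) or vectors with
#'   the same number of aligned observations \code{n};
#'   \code{nrow(x) + nrow(y)} must be below \code{n}.
#' @param bias_correction logical; apply the digamma finite-sample
#'   correction to the log-determinant entropies. Default \code{FALSE}, so
#'   the value is the literal plug-in Gaussian MI of the copula covariance.
#' @param tie_rule passed to [copula_transform()].
#' @return mutual information in bits, clipped at 0 (clipping can only
#'   trigger when \code{bias_correction = TRUE}; a warning is emitted).
#' @examples
#' n <- 2000
#' x <- rnorm(n)
#' y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
#' gcmi(x, y)                 # ~ -0.5 * log2(1 - 0.25) = 0.2075 bits
#' gcmi(exp(x), y) == gcmi(x, y)   # rank invariance, exact
#' @export
gcmi <- function(x, y, bias_correction = FALSE,
                 tie_rule = c("average", "ordinal")) {
  tie_rule <- match.arg(tie_rule)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(y) && is.numeric(y)) y <- matrix(y, nrow = 1L)
  n <- ncol(x)
  if (ncol(y) != n) {
    stop("`x` and `y` must share the same number of observations (",
         n, " vs ", ncol(y), ")")
  }
  kx <- nrow(x)
  ky <- nrow(y)
  if (kx + ky >= n) {
    stop("joint dimension ", kx + ky, " must be below the sample size ", n,
         " (covariance would be rank-deficient)")
  }
  gx <- copula_transform(x, tie_rule)
  gy <- copula_transform(y, tie_rule)
  sigma <- cov(t(rbind(gx, gy)))   # 1/(n-1) normalisation
  mi <- gaussian_mi(sigma[seq_len(kx), seq_len(kx), drop = FALSE],
                    sigma[kx + seq_len(ky), kx + seq_len(ky), drop = FALSE],
                    sigma)
  if (bias_correction) mi <- mi - gcmi_bias_bits(kx, ky, n)
  if (mi < 0) {
    warning("negative MI estimate (", format(mi), " bits) clipped to 0")
    mi <- 0
  }
  mi
}

#' Rescale mutual information to a correlation-scale magnitude in [0, 1)
#'
#' Inverts the univariate Gaussian relation \eqn{MI = -\tfrac12\log_2(1-r^2)}
#' back to \eqn{r = \sqrt{1 - 2^{-2 MI}}}: a power transformation that maps
#' 0 bits to 0, is strictly increasing, and approaches 1 as MI grows. For
#' univariate Gaussian data it recovers the absolute correlation, making MI
#' values directly comparable with absolute Pearson correlations.
#'
#' @param mi non-negative mutual information in bits (vectorised).
#' @return value(s) in \code{[0, 1)}.
#' @examples
#' rescale_mi(0)                      # 0
#' rescale_mi(-0.5 * log2(1 - 0.25))  # 0.5
#' @export
rescale_mi <- function(mi) {
  if (!is.numeric(mi) || anyNA(mi)) stop("`mi` must be numeric and non-NA")
  if (any(mi < 0)) stop("`mi` must be non-negative")
  sqrt(1 - 2^(-2 * mi))
}
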