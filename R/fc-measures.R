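#' Pairwise functional-connectivity measures
#'
#' The four region-pair estimators compared throughout the package:
#' \describe{
#'   \item{\code{fc_pcor}}{absolute Pearson correlation between the two
#'     voxel-average time series ("PCor"). Linear, univariate.}
#'   \item{\code{fc_svd}}{absolute Pearson correlation between the first
#'     temporal singular vectors of the voxel-centered matrices ("SVD").
#'     Linear, but robust to inhomogeneous voxel signs; singular-vector
#'     sign indeterminacy is absorbed by the absolute value.}
#'   \item{\code{fc_uvmi}}{Gaussian-copula MI between the two average
#'     series, rescaled to \code{[0, 1)} via [rescale_mi()] ("uvMI").
#'     Nonlinear, univariate.}
#'   \item{\code{fc_mvmi}}{Gaussian-copula MI between the two regions'
#'     top-\code{n_components} (default 5) PCA score sets, rescaled to
#'     \code{[0, 1)} ("mvMI"). Nonlinear and multivariate: the two score
#'     blocks form one joint covariance of dimension \code{2*n_components}.}
#' }
#' All four are symmetric in their arguments and return values in
#' \code{[0, 1]} (MI-based ones in \code{[0, 1)}). When both regions have a
#' single voxel, \code{fc_svd} equals \code{fc_pcor} and \code{fc_mvmi}
#' equals \code{fc_uvmi}.
#'
#' @param x,y [region_activity()] objects (or bare voxels x timepoints
#'   matrices) with equal numbers of timepoints.
#' @param n_components PCA components per region for \code{fc_mvmi};
#'   requires \code{n_timepoints > 2 * n_components + 1}.
#' @param bias_correction passed to [gcmi()] for the MI-based measures.
#' @return a single FC value.
#' @examples
#' x <- region_activity(matrix(rnorm(500), 5, 100))
#' y <- region_activity(x$data[sample(5), ] + 0.1 * rnorm(500))
#' fc_pcor(x, y)
#' fc_mvmi(x, y, n_components = 3)
#' @name fc_measures
NULL

check_pair <- function(x, y) {
  x <- as_region(x)
  y <- as_region(y)
  if (x$n_timepoints != y$n_timepoints) {
    stop("regions have different numbers of timepoints (",
         x$n_timepoints, " vs ", y$n_timepoints, ")")
  }
  list(x = x, y = y)
}

abs_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero-variance summary series; correlation undefined")
  }
  abs(cor(a, b))
}

#' @rdname fc_measures
#' @export
fc_pcor <- function(x, y) {
  p <- check_pair(x, y)
  abs_cor(colMeans(p$x$data), colMeans(p$y$data))
}

#' @rdname fc_measures
#' @export
fc_svd <- function(x, y) {
  p <- check_pair(x, y)
  abs_cor(summarize_region(p$x, "svd_first")[1, ],
          summarize_region(p$y, "svd_first")[1, ])
}

#' @rdname fc_measures
#' @export
fc_uvmi <- function(x, y, bias_correction = FALSE) {
  p <- check_pair(x, y)
  rescale_mi(gcmi(colMeans(p$x$data), colMeans(p$y$data),
                  bias_correction = bias_correction))
}

#' @rdname fc_measures
#' @export
fc_mvmi <- function(x, y, n_components = 5L, bias_correction = FALSE) {
  p <- check_pair(x, y)
  nt <- p$x$n_timepoints
  if (nt <= 2L * n_components + 1L) {
    stop("mvMI with ", n_components, " components needs more than ",
         2L * n_components + 1L, " timepoints, got ", nt)
  }
  sx <- summarize_region(p$x, "pca_k", n_components)
  sy <- summarize_region(p$y, "pca_k", n_components)
  rescale_mi(gcmi(sx, sy, bias_correction = bias_correction))
}

#' Evaluate a named FC measure on a region pair
#'
#' Dispatcher over the four measures in [fc_measures]; the `measure` tag is
#' the one used throughout the simulator, the permutation-null machinery and
#' the pipeline.
#'
#' @param x,y regions as in [fc_measures].
#' @param measure one of \code{"pcor"}, \code{"svd"}, \code{"uvmi"},
#'   \code{"mvmi"}.
#' @param n_components,bias_correction routed to the measures that use
#'   them (\code{n_components} only affects \code{"mvmi"};
#'   \code{bias_correction} the two MI-based measures).
#' @return a single FC value.
#' @export
fc_measure <- function(x, y, measure = c("pcor", "svd", "uvmi", "mvmi"),
                       n_components = 5L, bias_correction = FALSE) {
  measure <- match.arg(measure)
  switch(measure,
         pcor = fc_pcor(x, y),
         svd  = fc_svd(x, y),
         uvmi = fc_uvmi(x, y, bias_correction = bias_correction),
         mvmi = fc_mvmi(x, y, n_components = n_components,
                        bias_correction = bias_correction))
}

#' @rdname fc_measure
#' @export
fc_measure_names <- function() c("pcor", "svd", "uvmi", "mvmi")
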