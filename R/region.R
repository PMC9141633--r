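#' Region activity container
#'
#' One brain region observed as a voxels x timepoints matrix of activity
#' (e.g. preprocessed BOLD). The container is the unit all FC measures,
#' the simulator and the pipeline operate on.
#'
#' @param data numeric matrix, voxels x timepoints, finite values, at least
#'   1 voxel and 3 timepoints.
#' @param region_id optional identifier.
#' @return an object of class \code{"region_activity"} with elements
#'   \code{data}, \code{region_id}, \code{n_voxels}, \code{n_timepoints}.
#' @examples
#' r <- region_activity(matrix(rnorm(50), 5, 10), "V1")
#' r$n_voxels
#' @export
region_activity <- function(data, region_id = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (voxels x timepoints)")
  }
  if (any(!is.finite(data))) stop("`data` contains non-finite values")
  if (nrow(data) < 1L) stop("need at least 1 voxel")
  if (ncol(data) < 3L) stop("need at least 3 timepoints, got ", ncol(data))
  structure(
    list(data = data, region_id = region_id,
         n_voxels = nrow(data), n_timepoints = ncol(data)),
    class = "region_activity"
  )
}

#' @export
print.region_activity <- function(x, ...) {
  cat("<region_activity", if (!is.null(x$region_id)) paste0("'", x$region_id, "'"),
      ">", x$n_voxels, "voxels x", x$n_timepoints, "timepoints\n")
  invisible(x)
}

as_region <- function(x) {
  if (inherits(x, "region_activity")) x else region_activity(x)
}

# Voxel-centered data and its eigen-decomposition over voxels.
# Returns the top-k temporal principal component scores (k x timepoints)
# and the first temporal singular vector. Works through the voxel x voxel
# cross-product so cost scales with the smaller of the two dimensions in
# the usual regime (voxels << timepoints handled fine either way).
region_pca <- function(data, k) {
  xc <- data - rowMeans(data)
  nv <- nrow(xc)
  es <- eigen(tcrossprod(xc), symmetric = TRUE)
  keep <- seq_len(min(k, nv))
  u <- es$vectors[, keep, drop = FALSE]
  # sign convention: largest-magnitude voxel loading positive
  for (j in seq_along(keep)) {
    i_max <- which.max(abs(u[, j]))
    if (u[i_max, j] < 0) u[, j] <- -u[, j]
  }
  scores <- crossprod(u, xc)            # k x timepoints, variance-ordered
  list(scores = scores, loadings = u, eigenvalues = es$values[keep])
}

#' Summarize a region's voxel activity
#'
#' Reduces a voxels x timepoints matrix to the representation each FC
#' measure consumes: the voxel-average time series (\code{"mean"}), the
#' first temporal singular vector of the voxel-centered matrix
#' (\code{"svd_first"}), or the leading temporal principal-component score
#' series (\code{"pca_k"}, default 5 components, ordered by decreasing
#' explained variance). PCA/SVD center each voxel over time but do not
#' rescale voxel variances. Component signs are fixed so each component's
#' largest-magnitude voxel loading is positive.
#'
#' @param region a [region_activity()] (or bare matrix).
#' @param method one of \code{"mean"}, \code{"svd_first"}, \code{"pca_k"}.
#' @param n_components number of components for \code{"pca_k"}; shrunk with
#'   a warning when the region cannot support it.
#' @return numeric matrix, components x timepoints (1 x T for \code{mean}
#'   and \code{svd_first}).
#' @examples
#' reg <- region_activity(matrix(rnorm(200), 10, 20))
#' dim(summarize_region(reg, "pca_k"))   # 5 x 20
#' @export
summarize_region <- function(region, method = c("mean", "svd_first", "pca_k"),
                             n_components = 5L) {
  method <- match.arg(method)
  region <- as_region(region)
  data <- region$data
  if (method == "mean") {
    return(matrix(colMeans(data), nrow = 1L))
  }
  if (method == "svd_first") {
    p <- region_pca(data, 1L)
    s1 <- sqrt(max(p$eigenvalues[1], 0))
    v1 <- if (s1 > 0) p$scores[1, ] / s1 else p$scores[1, ]
    return(matrix(v1, nrow = 1L))
  }
  k_max <- min(region$n_voxels, region$n_timepoints - 1L)
  k <- min(n_components, k_max)
  if (k < n_components) {
    warning("region supports only ", k, " principal components (requested ",
            n_components, "); using ", k)
  }
  region_pca(data, k)$scores
}
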