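#' Voxel covariance regimes
#'
#' Builds the covariance matrix that controls the homogeneity of the first
#' region's voxel activity:
#' \describe{
#'   \item{\code{homogeneous}}{\eqn{(1-c)I + c\,11^T} -- all voxels highly
#'     positively correlated (correlated activity).}
#'   \item{\code{independent}}{the identity -- uncorrelated voxels.}
#'   \item{\code{mixed}}{\eqn{(1-c)I + c\,vv^T} with \eqn{v = +1} on the
#'     first half of the voxels and \eqn{-1} on the rest -- two blocks,
#'     positively correlated within and anticorrelated across.}
#' }
#'
#' @param regime one of \code{"homogeneous"}, \code{"independent"},
#'   \code{"mixed"}.
#' @param size number of voxels.
#' @param strength off-diagonal magnitude \code{c} in \code{(0, 1)};
#'   default 0.9.
#' @return a symmetric positive-definite \code{size x size} matrix
#'   (verified by Cholesky).
#' @examples
#' make_covariance("homogeneous", 2)        # [[1, .9], [.9, 1]]
#' make_covariance("independent", 3)        # identity
#' @export
make_covariance <- function(regime = c("homogeneous", "independent", "mixed"),
                            size, strength = 0.9) {
  regime <- match.arg(regime)
  if (!is_scalar_number(size) || size < 1) stop("`size` must be >= 1")
  size <- as.integer(size)
  if (regime != "independent" &&
      (!is_scalar_number(strength) || strength <= 0 || strength >= 1)) {
    stop("`strength` must lie in (0, 1)")
  }
  sigma <- switch(regime,
    independent = diag(size),
    homogeneous = {
      m <- matrix(strength, size, size)
      diag(m) <- 1
      m
    },
    mixed = {
      v <- rep(c(1, -1), c(ceiling(size / 2), floor(size / 2)))
      m <- strength * tcrossprod(v)
      diag(m) <- 1
      m
    })
  chol(sigma)  # fails if not positive-definite
  sigma
}

covariance_regimes <- function() c("homogeneous", "independent", "mixed")
scenario_names <- function() {
  c("linear", "nonlinear_square", "multivariate", "structural_noise")
}

#' Two-region simulation scenario
#'
#' Full description of one simulated interaction condition between a source
#' region X (\code{n_x} voxels) and a target region Y (\code{n_y} voxels)
#' over \code{n_timepoints} timepoints. X is drawn i.i.d. over time from a
#' zero-mean multivariate normal with the chosen covariance regime; Y is a
#' mapped version of X plus noise, \eqn{Y_t = f(X_t T) + w_t}:
#' \describe{
#'   \item{\code{linear}}{\eqn{f} = identity; mapping matrix \code{T} has an
#'     identity \code{n_x x n_x} block (one-to-one voxel coupling) and
#'     N(0, mapping_noise_sd^2) entries elsewhere.}
#'   \item{\code{nonlinear_square}}{same \code{T}; \eqn{f} squares
#'     elementwise, \eqn{Y_t = (X_t T)^2 + w_t}.}
#'   \item{\code{multivariate}}{\eqn{f} = identity; every entry of \code{T}
#'     drawn N(0, 1/n_x) so each Y voxel mixes all X voxels at O(1)
#'     variance.}
#'   \item{\code{structural_noise}}{the linear scenario plus one shared
#'     N(0, structural_noise_sd^2) time series added to every voxel of Y --
#'     a global artifact such as motion.}
#' }
#' Independent N(0, measurement_noise_sd^2) measurement noise is added to
#' the observed X and Y (set \code{noise_on_x = FALSE} to restrict it to Y).
#'
#' @param scenario one of \code{"linear"}, \code{"nonlinear_square"},
#'   \code{"multivariate"}, \code{"structural_noise"}.
#' @param regime covariance regime of X, see [make_covariance()].
#' @param n_x,n_y voxels in each region (defaults 100 and 150).
#' @param n_timepoints timepoints (default 500).
#' @param strength covariance regime off-diagonal magnitude (default 0.9).
#' @param mapping_noise_sd sd of the non-identity entries of \code{T}
#'   (default 0.1).
#' @param measurement_noise_sd sd of the i.i.d. measurement noise
#'   (default 0.5).
#' @param structural_noise_sd sd of the shared Y time series in the
#'   \code{structural_noise} scenario (default 2).
#' @param noise_on_x add measurement noise to the observed X as well as Y
#'   (default \code{TRUE}).
#' @param seed default RNG seed consumed by [simulate_pair()].
#' @return an object of class \code{"scenario_spec"}.
#' @examples
#' spec <- scenario_spec("linear", "homogeneous", n_x = 10, n_y = 15,
#'                       n_timepoints = 100, seed = 1)
#' simulate_pair(spec)
#' @export
scenario_spec <- function(scenario = scenario_names(),
                          regime = covariance_regimes(),
                          n_x = 100L, n_y = 150L, n_timepoints = 500L,
                          strength = 0.9,
                          mapping_noise_sd = 0.1,
                          measurement_noise_sd = 0.5,
                          structural_noise_sd = 2,
                          noise_on_x = TRUE,
                          seed = NULL) {
  scenario <- match.arg(scenario)
  regime <- match.arg(regime)
  for (v in c(n_x, n_y, n_timepoints)) {
    if (!is_scalar_number(v) || v < 1) stop("sizes must be positive")
  }
  for (v in c(mapping_noise_sd, measurement_noise_sd, structural_noise_sd)) {
    if (!is_scalar_number(v) || v < 0) stop("noise sds must be >= 0")
  }
  structure(
    list(scenario = scenario, regime = regime,
         n_x = as.integer(n_x), n_y = as.integer(n_y),
         n_timepoints = as.integer(n_timepoints), strength = strength,
         mapping_noise_sd = mapping_noise_sd,
         measurement_noise_sd = measurement_noise_sd,
         structural_noise_sd = structural_noise_sd,
         noise_on_x = isTRUE(noise_on_x), seed = seed),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$scenario, "/", x$regime, "regime\n")
  cat("  regions:", x$n_x, "and", x$n_y, "voxels,", x$n_timepoints,
      "timepoints; c =", x$strength, "\n")
  cat("  noise sd: mapping", x$mapping_noise_sd,
      "| measurement", x$measurement_noise_sd,
      if (x$scenario == "structural_noise")
        paste("| structural", x$structural_noise_sd), "\n")
  invisible(x)
}

# mapping matrix per scenario (n_x x n_y)
make_mapping <- function(spec) {
  if (spec$scenario == "multivariate") {
    matrix(rnorm(spec$n_x * spec$n_y, sd = 1 / sqrt(spec$n_x)),
           spec$n_x, spec$n_y)
  } else {
    # identity n_x x n_x block (one-to-one voxel coupling); columns beyond
    # n_x are pure mapping noise
    tm <- matrix(rnorm(spec$n_x * spec$n_y, sd = spec$mapping_noise_sd),
                 spec$n_x, spec$n_y)
    k <- min(spec$n_x, spec$n_y)
    tm[seq_len(spec$n_x), seq_len(k)] <- diag(1, spec$n_x, k)
    tm
  }
}

#' Simulate a coupled two-region pair
#'
#' Draws one realisation of the scenario described by a [scenario_spec()]:
#' the latent source activity X (i.i.d. multivariate normal over time),
#' the mapped target Y, and the observation noise. Deterministic given the
#' seed.
#'
#' @param spec a [scenario_spec()].
#' @param seed RNG seed; defaults to \code{spec$seed}.
#' @return an object of class \code{"simulated_pair"}: list with
#'   [region_activity()] elements \code{x}, \code{y} and the generating
#'   \code{spec}.
#' @export
simulate_pair <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(seed, {
    tt <- spec$n_timepoints
    cov_x <- make_covariance(spec$regime, spec$n_x, spec$strength)
    x_lat <- matrix(rnorm(tt * spec$n_x), tt, spec$n_x) %*% chol(cov_x)
    tmap <- make_mapping(spec)
    y_lat <- x_lat %*% tmap
    if (spec$scenario == "nonlinear_square") y_lat <- y_lat^2
    x_obs <- x_lat
    if (spec$noise_on_x && spec$measurement_noise_sd > 0) {
      x_obs <- x_obs + matrix(rnorm(length(x_obs),
                                    sd = spec$measurement_noise_sd),
                              nrow = tt)
    }
    y_obs <- y_lat
    if (spec$measurement_noise_sd > 0) {
      y_obs <- y_obs + matrix(rnorm(length(y_obs),
                                    sd = spec$measurement_noise_sd),
                              nrow = tt)
    }
    if (spec$scenario == "structural_noise" && spec$structural_noise_sd > 0) {
      shared <- rnorm(tt, sd = spec$structural_noise_sd)
      y_obs <- y_obs + shared   # recycled down columns: same series per voxel
    }
    structure(
      list(x = region_activity(t(x_obs), "X"),
           y = region_activity(t(y_obs), "Y"),
           spec = spec),
      class = "simulated_pair"
    )
  })
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat("<simulated_pair>", x$spec$scenario, "/", x$spec$regime, ":",
      x$x$n_voxels, "+", x$y$n_voxels, "voxels x",
      x$x$n_timepoints, "timepoints\n")
  invisible(x)
}

# independently permute each voxel's time series (both regions share the
# call but every voxel gets its own permutation)
shuffle_region <- function(data) {
  tt <- ncol(data)
  for (i in seq_len(nrow(data))) data[i, ] <- data[i, sample.int(tt)]
  data
}

#' Null (shuffled) version of a simulated pair
#'
#' Independently permutes every voxel's time series over time, in both
#' regions, destroying all temporal alignment within and across regions
#' while leaving each voxel's marginal distribution (its sorted values)
#' unchanged. This is the null model behind the permutation significance
#' test.
#'
#' @param pair a \code{"simulated_pair"}.
#' @param seed RNG seed (optional).
#' @return a \code{"simulated_pair"} with shuffled regions.
#' @export
null_pair <- function(pair, seed = NULL) {
  stopifnot(inherits(pair, "simulated_pair"))
  with_seed(seed, {
    pair$x <- region_activity(shuffle_region(pair$x$data), pair$x$region_id)
    pair$y <- region_activity(shuffle_region(pair$y$data), pair$y$region_id)
    pair
  })
}
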