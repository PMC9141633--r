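#' Synthetic multi-subject cohort specification
#'
#' Describes a cohort that emulates the structure of resting-state FC data:
#' a shared backbone of network-level signals (stronger coupling within a
#' resting-state network than between networks), subject-specific
#' deviations, voxel-level noise with subject-varying voxel loadings
#' (so regional homogeneity differs across subjects, as it does in real
#' data), and an optional monotone nonlinear distortion per region.
#'
#' @param n_subjects subjects (default 10).
#' @param n_regions regions (default 35), split as evenly as possible into
#'   \code{n_networks} labelled networks.
#' @param n_networks resting-state networks (default 7).
#' @param voxels_range inclusive range of voxels per region (default
#'   \code{c(8, 12)}).
#' @param n_timepoints timepoints (default 200).
#' @param within_strength weight of a region's own network signal
#'   (default 0.8); must exceed \code{between_strength}.
#' @param between_strength weight of the global signal shared by all
#'   networks (default 0.3).
#' @param subject_noise_sd sd of the subject-specific region deviation
#'   (default 0.5).
#' @param voxel_noise_sd sd of independent voxel noise (default 1).
#' @param loading_sd sd of the voxel loadings around 1, drawn per subject
#'   and region (default 0.6; occasional negative loadings make the
#'   voxel-average a poor regional representative for some subjects).
#' @param nonlinear apply a region-specific monotone cubic distortion
#'   \eqn{x + a x^3}, \eqn{a \sim U(0, 0.5)}, to every voxel series
#'   (default \code{TRUE}).
#' @param seed default RNG seed consumed by [generate_cohort()].
#' @return an object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_subjects = 10L, n_regions = 35L, n_networks = 7L,
                        voxels_range = c(8L, 12L), n_timepoints = 200L,
                        within_strength = 0.8, between_strength = 0.3,
                        subject_noise_sd = 0.5, voxel_noise_sd = 1,
                        loading_sd = 0.6, nonlinear = TRUE, seed = NULL) {
  for (v in c(n_subjects, n_regions, n_networks, n_timepoints)) {
    if (!is_scalar_number(v) || v < 1) stop("sizes must be positive")
  }
  if (n_regions < n_networks) stop("need at least one region per network")
  if (within_strength <= between_strength) {
    stop("`within_strength` must exceed `between_strength`")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_regions = as.integer(n_regions),
         n_networks = as.integer(n_networks),
         voxels_range = as.integer(voxels_range),
         n_timepoints = as.integer(n_timepoints),
         within_strength = within_strength,
         between_strength = between_strength,
         subject_noise_sd = subject_noise_sd,
         voxel_noise_sd = voxel_noise_sd,
         loading_sd = loading_sd,
         nonlinear = isTRUE(nonlinear), seed = seed),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_subjects, "subjects,", x$n_regions, "regions in",
      x$n_networks, "networks,", x$n_timepoints, "timepoints\n")
  cat("  backbone within/between:", x$within_strength, "/",
      x$between_strength, "| subject sd", x$subject_noise_sd,
      "| voxel sd", x$voxel_noise_sd,
      "| nonlinear:", x$nonlinear, "\n")
  invisible(x)
}

#' Generate a synthetic multi-subject cohort
#'
#' Draws the cohort described by a [cohort_spec()]. One global signal and
#' one signal per network are shared across subjects; region \eqn{r} in
#' network \eqn{g} has latent series
#' \eqn{z_{s,r} = w_b s_0 + w_w s_g + \sigma_s \eta_{s,r}} for subject
#' \eqn{s}, and voxel \eqn{v} observes
#' \eqn{\lambda_{s,r,v} z_{s,r} + \sigma_v \epsilon} (loadings
#' \eqn{\lambda \sim N(1, loading\_sd^2)} redrawn per subject), optionally
#' passed through the region's monotone cubic distortion. Deterministic
#' given the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; defaults to \code{spec$seed}.
#' @return an object of class \code{"cohort"}: list with \code{subjects}
#'   (list of per-subject lists of [region_activity()]), \code{assignment}
#'   (data.frame \code{region}, \code{network}) and \code{spec}.
#' @examples
#' ch <- generate_cohort(cohort_spec(n_subjects = 3, n_regions = 7,
#'                                   n_timepoints = 60, seed = 1))
#' length(ch$subjects)
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    tt <- spec$n_timepoints
    nets <- paste0("N", seq_len(spec$n_networks))
    assignment <- data.frame(
      region = paste0("R", seq_len(spec$n_regions)),
      network = rep_len(nets, spec$n_regions),
      stringsAsFactors = FALSE
    )
    n_vox <- sample(seq(spec$voxels_range[1], spec$voxels_range[2]),
                    spec$n_regions, replace = TRUE)
    s_global <- rnorm(tt)
    s_net <- matrix(rnorm(tt * spec$n_networks), spec$n_networks, tt)
    distort_a <- if (spec$nonlinear) runif(spec$n_regions, 0, 0.5)
                 else rep(0, spec$n_regions)
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
      regions <- lapply(seq_len(spec$n_regions), function(r) {
        g <- match(assignment$network[r], nets)
        z <- spec$between_strength * s_global +
          spec$within_strength * s_net[g, ] +
          spec$subject_noise_sd * rnorm(tt)
        lam <- rnorm(n_vox[r], mean = 1, sd = spec$loading_sd)
        vox <- tcrossprod(lam, z) +
          matrix(rnorm(n_vox[r] * tt, sd = spec$voxel_noise_sd),
                 n_vox[r], tt)
        if (distort_a[r] > 0) vox <- vox + distort_a[r] * vox^3
        region_activity(vox, assignment$region[r])
      })
      names(regions) <- assignment$region
      regions
    })
    names(subjects) <- paste0("S", seq_len(spec$n_subjects))
    structure(list(subjects = subjects, assignment = assignment,
                   spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(x$subjects), "subjects x",
      nrow(x$assignment), "regions (",
      length(unique(x$assignment$network)), "networks ),",
      x$spec$n_timepoints, "timepoints\n")
  invisible(x)
}
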