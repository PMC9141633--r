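# End-to-end orchestration: every run_* function is a file-level wrapper
# over the in-memory API, writes delimited tables plus a provenance YAML,
# and is deterministic given its seed. The CLI in inst/cli/gcmifc.R is a
# thin argument parser over these functions.

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

pipeline_log <- function(..., quiet = FALSE) {
  if (!quiet) message("[gcmifc] ", ...)
}

#' Simulate scenario repetitions to disk
#'
#' Writes one region matrix per region per repetition plus a manifest
#' (subject column holds the repetition id) and a provenance file.
#'
#' @param out_dir output directory (created if needed).
#' @param scenario,regime,reps,seed simulation condition; remaining
#'   scenario parameters via \code{...} (see [scenario_spec()]).
#' @param ... passed to [scenario_spec()].
#' @param quiet suppress progress messages.
#' @return the manifest data.frame, invisibly.
#' @export
run_simulate <- function(out_dir, scenario = "linear",
                         regime = "homogeneous", reps = 1L, seed = 1L,
                         ..., quiet = FALSE) {
  ensure_dir(out_dir)
  spec <- scenario_spec(scenario = scenario, regime = regime, ...)
  rows <- list()
  seeds <- with_seed(seed, draw_seeds(reps))
  for (i in seq_len(reps)) {
    pair <- simulate_pair(spec, seed = seeds[i])
    rep_id <- sprintf("rep%03d", i)
    for (side in c("x", "y")) {
      f <- sprintf("%s_region_%s.tsv", rep_id, side)
      write_region_matrix(pair[[side]], file.path(out_dir, f))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = rep_id, region = side, file = f,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  write_provenance(out_dir, "simulate",
                   c(unclass(spec)[names(unclass(spec)) != "seed"],
                     list(reps = reps, seed = seed)))
  pipeline_log("simulate: ", reps, " repetition(s) of ", scenario, "/",
               regime, " -> ", out_dir, quiet = quiet)
  invisible(manifest)
}

#' Generate a synthetic cohort to disk
#'
#' Writes one region matrix per subject and region, a manifest, the
#' region-to-network assignment table and a provenance file.
#'
#' @param out_dir output directory.
#' @param spec a [cohort_spec()] (default [cohort_spec()] defaults).
#' @param seed RNG seed.
#' @param quiet suppress progress messages.
#' @return the manifest data.frame, invisibly.
#' @export
run_cohort <- function(out_dir, spec = cohort_spec(), seed = 1L,
                       quiet = FALSE) {
  ensure_dir(out_dir)
  cohort <- generate_cohort(spec, seed = seed)
  rows <- list()
  for (s in names(cohort$subjects)) {
    for (r in names(cohort$subjects[[s]])) {
      f <- sprintf("%s_%s.tsv", s, r)
      write_region_matrix(cohort$subjects[[s]][[r]], file.path(out_dir, f))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, region = r, file = f, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  write_network_assignment(cohort$assignment,
                           file.path(out_dir, "assignment.tsv"))
  write_provenance(out_dir, "cohort",
                   c(unclass(spec)[names(unclass(spec)) != "seed"],
                     list(seed = seed)))
  pipeline_log("cohort: ", spec$n_subjects, " subjects x ",
               spec$n_regions, " regions -> ", out_dir, quiet = quiet)
  invisible(manifest)
}

#' Compute connectivity matrices for every subject in a data directory
#'
#' Reads the manifest in \code{dir}, assembles one [fc_matrix()] per
#' subject with the requested measure and writes it as
#' \code{fc_<measure>_<subject>.tsv} in \code{out_dir}.
#'
#' @param dir directory containing \code{manifest.tsv} and region files.
#' @param measure FC measure tag.
#' @param out_dir output directory (default \code{dir}).
#' @param ... passed to the measure.
#' @param quiet suppress progress messages.
#' @return named list of [fc_matrix()] objects, invisibly.
#' @export
run_fc <- function(dir, measure = "pcor", out_dir = dir, ...,
                   quiet = FALSE) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  ensure_dir(out_dir)
  subjects <- unique(manifest$subject)
  fcs <- lapply(subjects, function(s) {
    regions <- read_subject_regions(manifest, dir, s)
    fc <- assemble_fc(regions, measure, subject_id = s, ...)
    write_fc_matrix(fc, file.path(out_dir,
                                  sprintf("fc_%s_%s.tsv", measure, s)))
    fc
  })
  names(fcs) <- subjects
  write_provenance(out_dir, paste0("fc_", measure),
                   list(measure = measure, dir = dir,
                        subjects = length(subjects)))
  pipeline_log("fc: ", measure, " for ", length(subjects),
               " subject(s) -> ", out_dir, quiet = quiet)
  invisible(fcs)
}

#' Permutation-null table for one region pair on disk
#'
#' @param x_file,y_file region matrix files.
#' @param measure FC measure tag.
#' @param n_perm permutations (default 100).
#' @param seed RNG seed.
#' @param out_file optional TSV destination for the tidy table.
#' @param ... passed to the measure.
#' @return data.frame with columns \code{measure}, \code{fc},
#'   \code{threshold95}, \code{performance}, \code{significant}, and the
#'   null values in attribute \code{"null_values"}.
#' @export
run_null <- function(x_file, y_file, measure = "pcor", n_perm = 100L,
                     seed = 1L, out_file = NULL, ...) {
  x <- read_region_matrix(x_file, "x")
  y <- read_region_matrix(y_file, "y")
  fc <- fc_measure(x, y, measure, ...)
  nl <- build_null(x, y, measure, n_perm = n_perm, seed = seed, ...)
  verdict <- fc_performance(fc, nl)
  out <- data.frame(measure = measure, fc = fc,
                    threshold95 = verdict$threshold95,
                    performance = verdict$performance,
                    significant = verdict$significant)
  attr(out, "null_values") <- nl$values
  if (!is.null(out_file)) {
    write.table(out, out_file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Scenario benchmark table
#'
#' Reproduces the simulation benchmark: for every scenario x regime x
#' measure cell, runs [scenario_performance()] and emits one tidy row per
#' repetition (\code{scenario}, \code{regime}, \code{measure}, \code{rep},
#' \code{fc}, \code{threshold95}, \code{performance}).
#'
#' @param out_file optional TSV destination.
#' @param scenarios,regimes,measures condition grid (defaults: all four
#'   scenarios, all three regimes, all four measures).
#' @param reps repetitions per cell (default 20).
#' @param n_perm permutations per repetition (default 100).
#' @param seed RNG seed.
#' @param ... passed to [scenario_spec()] (sizes, noise sds, ...).
#' @param quiet suppress progress messages.
#' @return the tidy data.frame, invisibly when written to file.
#' @export
run_bench <- function(out_file = NULL, scenarios = scenario_names(),
                      regimes = covariance_regimes(),
                      measures = fc_measure_names(),
                      reps = 20L, n_perm = 100L, seed = 1L, ...,
                      quiet = FALSE) {
  grid <- expand.grid(scenario = scenarios, regime = regimes,
                      measure = measures, stringsAsFactors = FALSE)
  cell_seeds <- with_seed(seed, draw_seeds(nrow(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- scenario_spec(scenario = grid$scenario[i],
                        regime = grid$regime[i], ...)
    res <- scenario_performance(sp, grid$measure[i], reps = reps,
                                n_perm = n_perm, seed = cell_seeds[i])
    pipeline_log("bench: ", grid$scenario[i], "/", grid$regime[i], "/",
                 grid$measure[i], " mean perf ",
                 format(res$mean, digits = 3), quiet = quiet)
    data.frame(scenario = grid$scenario[i], regime = grid$regime[i],
               measure = grid$measure[i], rep = seq_len(reps),
               fc = res$fc_values, threshold95 = res$thresholds,
               performance = res$performances, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_file)) {
    write.table(out, out_file, sep = "\t", row.names = FALSE, quote = FALSE)
    write_provenance(dirname(out_file), "bench",
                     list(scenarios = scenarios, regimes = regimes,
                          measures = measures, reps = reps,
                          n_perm = n_perm, seed = seed))
    return(invisible(out))
  }
  out
}

#' Graph-level analysis of a cohort directory
#'
#' Runs the full analysis stack on a cohort produced by [run_cohort()]
#' (region files + manifest + assignment): per-subject FC matrices for the
#' requested measures, within/between edge partitioning, pairwise measure
#' similarity (Spearman), per-edge permutation significance counts (on the
#' first \code{significance_subjects} subjects), spectral nonrandomness of
#' each subject's graph, and between-subject similarity -- overall and per
#' threshold level. Results are written as tidy TSV tables.
#'
#' @param dir cohort directory.
#' @param out_dir output directory (default \code{file.path(dir,
#'   "analysis")}).
#' @param measures measures to analyse (default \code{c("pcor", "mvmi")}).
#' @param density,k nonrandomness graph density and eigenvector count.
#' @param thresholds fractions of the maximum used for thresholded
#'   subject-similarity (default \code{c(0.1, 0.2, 0.3)}).
#' @param n_perm permutations for significance counts (default 100).
#' @param significance_subjects how many subjects get per-edge significance
#'   testing (default 1; it is the expensive stage).
#' @param seed RNG seed.
#' @param ... passed to the measures.
#' @param quiet suppress progress messages.
#' @return named list of result data.frames, invisibly.
#' @export
run_analyze <- function(dir, out_dir = file.path(dir, "analysis"),
                        measures = c("pcor", "mvmi"),
                        density = 0.10, k = 7L,
                        thresholds = c(0.1, 0.2, 0.3),
                        n_perm = 100L, significance_subjects = 1L,
                        seed = 1L, ..., quiet = FALSE) {
  ensure_dir(out_dir)
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  assignment <- read_network_assignment(file.path(dir, "assignment.tsv"))
  subjects <- unique(manifest$subject)
  fcs <- lapply(measures, function(m) {
    run_fc(dir, m, out_dir = out_dir, ..., quiet = quiet)
  })
  names(fcs) <- measures

  part <- partition_edges(fcs[[1]][[1]], assignment)
  partition_tab <- data.frame(class = c("within", "between"),
                              n_edges = c(part$n_within, part$n_between))
  # scopes with fewer than 2 edges carry no correlation statistic
  scopes <- c("all", "within", "between")[c(TRUE, part$n_within >= 2,
                                            part$n_between >= 2)]

  sim_rows <- list()
  if (length(measures) >= 2L) {
    for (i in seq_len(length(measures) - 1L)) {
      for (j in seq((i + 1L), length(measures))) {
        for (s in subjects) {
          for (scope in scopes) {
            sim_rows[[length(sim_rows) + 1L]] <- data.frame(
              subject = s, measure_a = measures[i], measure_b = measures[j],
              scope = scope[[1]],
              spearman = measure_similarity(fcs[[i]][[s]], fcs[[j]][[s]],
                                            scope, assignment))
          }
        }
      }
    }
  }
  similarity_tab <- if (length(sim_rows)) do.call(rbind, sim_rows)
                    else data.frame()

  sig_subjects <- utils::head(subjects, significance_subjects)
  seeds <- with_seed(seed, draw_seeds(length(sig_subjects) *
                                        length(measures)))
  sig_rows <- list()
  si <- 0L
  for (s in sig_subjects) {
    regions <- read_subject_regions(manifest, dir, s)
    ids <- names(regions)
    for (m in measures) {
      si <- si + 1L
      n_sig <- 0L
      n_tot <- 0L
      edge_seeds <- with_seed(seeds[si],
                              draw_seeds(length(ids) * (length(ids) - 1) / 2))
      e <- 0L
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq((i + 1L), length(ids))) {
          e <- e + 1L
          fcv <- fcs[[m]][[s]]$values[ids[i], ids[j]]
          nl <- build_null(regions[[i]], regions[[j]], m, n_perm = n_perm,
                           seed = edge_seeds[e], ...)
          n_sig <- n_sig + (fcv > percentile95(nl))
          n_tot <- n_tot + 1L
        }
      }
      sig_rows[[length(sig_rows) + 1L]] <- data.frame(
        subject = s, measure = m, n_edges = n_tot,
        n_significant = n_sig, n_insignificant = n_tot - n_sig)
      pipeline_log("analyze: significance ", s, "/", m, ": ",
                   n_sig, "/", n_tot, " significant", quiet = quiet)
    }
  }
  significance_tab <- do.call(rbind, sig_rows)

  nr_rows <- list()
  for (m in measures) {
    for (s in subjects) {
      nr <- nonrandomness(fcs[[m]][[s]], density = density, k = k)
      nr_rows[[length(nr_rows) + 1L]] <- data.frame(
        subject = s, measure = m, nonrandomness = nr$total,
        n_nodes = nr$n_nodes, n_edges = nr$n_edges,
        density = density, k = nr$k)
    }
  }
  nonrandomness_tab <- do.call(rbind, nr_rows)

  ss_rows <- list()
  for (m in measures) {
    for (scope in scopes) {
      sims <- subject_similarity(fcs[[m]], scope[[1]], assignment)
      ss_rows[[length(ss_rows) + 1L]] <- data.frame(
        subject = names(sims), measure = m, scope = scope[[1]],
        threshold = 0, similarity = unname(sims))
    }
    for (th in thresholds) {
      thr_fcs <- lapply(fcs[[m]], threshold_fc, fraction = th)
      sims <- subject_similarity(thr_fcs, "all", assignment)
      ss_rows[[length(ss_rows) + 1L]] <- data.frame(
        subject = names(sims), measure = m, scope = "all",
        threshold = th, similarity = unname(sims))
    }
  }
  subject_similarity_tab <- do.call(rbind, ss_rows)

  results <- list(partition = partition_tab,
                  measure_similarity = similarity_tab,
                  significance = significance_tab,
                  nonrandomness = nonrandomness_tab,
                  subject_similarity = subject_similarity_tab)
  for (nm in names(results)) {
    if (nrow(results[[nm]])) {
      write.table(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  write_provenance(out_dir, "analyze",
                   list(measures = measures, density = density, k = k,
                        thresholds = thresholds, n_perm = n_perm,
                        significance_subjects = significance_subjects,
                        seed = seed))
  pipeline_log("analyze: wrote ", length(results), " tables -> ", out_dir,
               quiet = quiet)
  invisible(results)
}
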