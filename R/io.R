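# File formats: everything is delimited text.
#  - region matrix: TSV, rows voxels, columns timepoints, no headers
#  - manifest: TSV with header, columns subject, region, file
#  - FC matrix: TSV with header row and leading region-id column
#  - network assignment: TSV with header, columns region, network
#  - config / provenance: YAML

#' Read and write region activity matrices
#'
#' A region is stored as one tab-delimited matrix, rows voxels and columns
#' timepoints, without headers. A manifest (TSV with columns
#' \code{subject}, \code{region}, \code{file}; paths relative to the
#' manifest) maps subject/region ids to files.
#'
#' @param region a [region_activity()].
#' @param path file path.
#' @param region_id id attached on read.
#' @return \code{read_region_matrix} returns a [region_activity()];
#'   writers return the path invisibly.
#' @name region_io
#' @export
write_region_matrix <- function(region, path) {
  region <- as_region(region)
  write.table(region$data, path, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname region_io
#' @export
read_region_matrix <- function(path, region_id = NULL) {
  if (!file.exists(path)) stop_data("region file not found: ", path)
  m <- tryCatch(
    as.matrix(read.table(path, sep = "\t", header = FALSE)),
    error = function(e) stop_data("malformed region matrix in ", path,
                                  ": ", conditionMessage(e))
  )
  if (!is.numeric(m)) stop_data("non-numeric values in region matrix ", path)
  dimnames(m) <- NULL
  region_activity(m, region_id)
}

#' @rdname region_io
#' @param manifest data.frame with columns \code{subject}, \code{region},
#'   \code{file}.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("subject", "region", "file") %in% names(manifest)))
  write.table(manifest, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname region_io
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_data("manifest not found: ", path)
  m <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("subject", "region", "file") %in% names(m))) {
    stop_data("manifest ", path,
              " must have columns subject, region, file")
  }
  m
}

# read all regions of one subject from a manifest, in manifest order
read_subject_regions <- function(manifest, manifest_dir, subject) {
  rows <- manifest[manifest$subject == subject, , drop = FALSE]
  if (!nrow(rows)) stop_data("subject ", subject, " not in manifest")
  regions <- lapply(seq_len(nrow(rows)), function(i) {
    read_region_matrix(file.path(manifest_dir, rows$file[i]),
                       rows$region[i])
  })
  names(regions) <- rows$region
  nt <- unique(vapply(regions, function(r) r$n_timepoints, integer(1)))
  if (length(nt) != 1L) {
    stop_data("subject ", subject, ": regions disagree on timepoints (",
              paste(nt, collapse = ", "), ")")
  }
  regions
}

#' Read and write connectivity matrices and network assignments
#'
#' FC matrices are square TSV tables with a header row and a leading
#' region-id column; assignments are two-column TSV tables
#' (\code{region}, \code{network}).
#'
#' @param fc an [fc_matrix()].
#' @param path file path.
#' @param measure,subject_id metadata attached on read.
#' @param assignment data.frame with columns \code{region}, \code{network}.
#' @return readers return an [fc_matrix()] / data.frame; writers the path,
#'   invisibly.
#' @name fc_io
#' @export
write_fc_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  df <- data.frame(region = fc$region_ids, fc$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname fc_io
#' @export
read_fc_matrix <- function(path, measure = "unknown", subject_id = NULL) {
  if (!file.exists(path)) stop_data("FC matrix not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop_data("FC matrix in ", path, " is not square (",
              nrow(m), " x ", ncol(m), ")")
  }
  dimnames(m) <- list(ids, ids)
  fc_matrix(m, measure = measure, subject_id = subject_id, region_ids = ids)
}

#' @rdname fc_io
#' @export
write_network_assignment <- function(assignment, path) {
  stopifnot(all(c("region", "network") %in% names(assignment)))
  write.table(assignment[, c("region", "network")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname fc_io
#' @export
read_network_assignment <- function(path) {
  if (!file.exists(path)) stop_data("assignment file not found: ", path)
  a <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("region", "network") %in% names(a))) {
    stop_data("assignment ", path, " must have columns region, network")
  }
  if (anyDuplicated(a$region)) {
    stop_data("assignment ", path, " lists some regions more than once")
  }
  a
}

#' Run configuration files
#'
#' Configurations are flat YAML key/value files; they round-trip
#' losslessly and every pipeline output directory carries a provenance
#' file echoing the full configuration plus its hash, so unprinted
#' defaults are always recoverable from outputs.
#'
#' @param config named list of parameters.
#' @param path file path.
#' @return \code{read_config} returns the named list; \code{config_hash}
#'   an md5 string over the canonical YAML form.
#' @name config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_data("config not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname config_io
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

# provenance sidecar written by every pipeline command
write_provenance <- function(dir, command, params) {
  params <- params[order(names(params))]
  prov <- list(
    package = "gcmifc",
    version = as.character(utils::packageVersion("gcmifc")),
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash(params),
    parameters = params
  )
  write_config(prov, file.path(dir, paste0(command, "_provenance.yaml")))
}
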