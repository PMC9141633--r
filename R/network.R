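#' Connectivity matrix container
#'
#' A symmetric region x region matrix of FC values for one measure (and
#' optionally one subject), with a zero diagonal. The diagonal is excluded
#' from every statistic computed on the matrix.
#'
#' @param values symmetric numeric matrix; the diagonal is forced to zero.
#' @param measure measure tag (see [fc_measure()]), or any label.
#' @param subject_id optional subject identifier.
#' @param region_ids optional region identifiers (defaults to existing
#'   dimnames or \code{R1..Rn}).
#' @return an object of class \code{"fc_matrix"} wrapping the matrix.
#' @export
fc_matrix <- function(values, measure = "pcor", subject_id = NULL,
                      region_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values) ||
      nrow(values) != ncol(values)) {
    stop("`values` must be a square numeric matrix")
  }
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    stop("`values` must be symmetric")
  }
  region_ids <- region_ids %||% rownames(values) %||%
    paste0("R", seq_len(nrow(values)))
  dimnames(values) <- list(region_ids, region_ids)
  diag(values) <- 0
  structure(list(values = values, measure = measure,
                 subject_id = subject_id, region_ids = region_ids),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  v <- x$values[upper_mask(nrow(x$values))]
  cat("<fc_matrix>", x$measure,
      if (!is.null(x$subject_id)) paste0("(subject ", x$subject_id, ")"),
      ":", nrow(x$values), "regions,",
      length(v), "edges; median", format(median(v), digits = 4), "\n")
  invisible(x)
}

fc_values <- function(fc) {
  if (inherits(fc, "fc_matrix")) fc$values else fc
}

#' Assemble a whole-network connectivity matrix
#'
#' Evaluates one FC measure on every unordered pair of regions; the result
#' is symmetric by construction with a zero diagonal.
#'
#' @param regions list of [region_activity()] objects (named or with
#'   \code{region_id}s).
#' @param measure FC measure tag.
#' @param subject_id optional label carried on the result.
#' @param ... passed to the measure.
#' @return an [fc_matrix()].
#' @export
assemble_fc <- function(regions, measure = c("pcor", "svd", "uvmi", "mvmi"),
                        subject_id = NULL, ...) {
  measure <- match.arg(measure)
  regions <- lapply(regions, as_region)
  nr <- length(regions)
  if (nr < 2L) stop("need at least 2 regions")
  ids <- names(regions) %||% vapply(seq_len(nr), function(i) {
    regions[[i]]$region_id %||% paste0("R", i)
  }, character(1))
  m <- matrix(0, nr, nr, dimnames = list(ids, ids))
  for (i in seq_len(nr - 1L)) {
    for (j in seq((i + 1L), nr)) {
      m[i, j] <- m[j, i] <- fc_measure(regions[[i]], regions[[j]],
                                       measure, ...)
    }
  }
  fc_matrix(m, measure = measure, subject_id = subject_id, region_ids = ids)
}

check_assignment <- function(assignment, region_ids = NULL) {
  if (is.data.frame(assignment)) {
    if (!all(c("region", "network") %in% names(assignment))) {
      stop("`assignment` needs columns `region` and `network`")
    }
    map <- stats::setNames(as.character(assignment$network),
                           as.character(assignment$region))
  } else if (!is.null(names(assignment))) {
    map <- stats::setNames(as.character(assignment), names(assignment))
  } else {
    stop("`assignment` must be a region/network data.frame or named vector")
  }
  if (anyDuplicated(names(map))) stop("regions assigned more than once")
  if (!is.null(region_ids)) {
    missing <- setdiff(region_ids, names(map))
    if (length(missing)) {
      stop("regions without a network assignment: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    map <- map[region_ids]
  }
  map
}

#' Partition connections into within- and between-network edges
#'
#' A connection is a within-network edge when both endpoint regions carry
#' the same network label, otherwise a between-network edge. Counts always
#' satisfy \code{within + between == R*(R-1)/2}.
#'
#' @param fc an [fc_matrix()] (or a character vector of region ids).
#' @param assignment region -> network map: a data.frame with columns
#'   \code{region}, \code{network}, or a named character vector.
#' @return an object of class \code{"edge_partition"}: data.frame
#'   \code{edges} with columns \code{region_a}, \code{region_b},
#'   \code{network_a}, \code{network_b}, \code{class} (\code{"within"} /
#'   \code{"between"}) and, when \code{fc} carries values, \code{value};
#'   plus the per-class counts.
#' @export
partition_edges <- function(fc, assignment) {
  ids <- if (inherits(fc, "fc_matrix")) fc$region_ids else as.character(fc)
  map <- check_assignment(assignment, ids)
  nr <- length(ids)
  idx <- which(upper_mask(nr), arr.ind = TRUE)
  edges <- data.frame(
    region_a = ids[idx[, 1]], region_b = ids[idx[, 2]],
    network_a = unname(map[idx[, 1]]), network_b = unname(map[idx[, 2]]),
    stringsAsFactors = FALSE
  )
  edges$class <- ifelse(edges$network_a == edges$network_b,
                        "within", "between")
  if (inherits(fc, "fc_matrix")) edges$value <- fc$values[upper_mask(nr)]
  structure(
    list(edges = edges,
         n_within = sum(edges$class == "within"),
         n_between = sum(edges$class == "between"),
         networks = sort(unique(unname(map)))),
    class = "edge_partition"
  )
}

#' @export
print.edge_partition <- function(x, ...) {
  cat("<edge_partition>", x$n_within, "within +", x$n_between,
      "between edges over", length(x$networks), "networks\n")
  invisible(x)
}

# logical upper-triangle mask restricted to a scope:
#   "all", "within", "between", or c(networkA, networkB)
scope_mask <- function(region_ids, scope, assignment = NULL) {
  nr <- length(region_ids)
  mask <- upper_mask(nr)
  if (identical(scope, "all")) return(mask)
  map <- check_assignment(assignment, region_ids)
  net <- unname(map)
  same <- outer(net, net, "==")
  if (identical(scope, "within")) return(mask & same)
  if (identical(scope, "between")) return(mask & !same)
  if (length(scope) == 2L) {
    pairk <- outer(net, net, function(a, b) {
      (a == scope[1] & b == scope[2]) | (a == scope[2] & b == scope[1])
    })
    if (identical(scope[1], scope[2])) pairk <- same & net == scope[1]
    return(mask & pairk)
  }
  stop("`scope` must be \"all\", \"within\", \"between\" or a network pair")
}

#' Rank-correlation similarity between two connectivity matrices
#'
#' Spearman rank correlation over the upper-triangle FC values shared by
#' two matrices on the same regions -- the similarity metric used to
#' compare measures. Being rank-based, it is invariant to any common
#' monotone rescaling of the values. The scope can restrict the comparison
#' to within-network, between-network, or one network-pair block.
#'
#' @param fc_a,fc_b [fc_matrix()] objects over the same regions.
#' @param scope \code{"all"} (default), \code{"within"}, \code{"between"},
#'   or a length-2 character vector naming a network pair.
#' @param assignment required for non-\code{"all"} scopes.
#' @return Spearman correlation in \code{[-1, 1]}.
#' @export
measure_similarity <- function(fc_a, fc_b, scope = "all", assignment = NULL) {
  a <- fc_values(fc_a)
  b <- fc_values(fc_b)
  if (!all(dim(a) == dim(b))) stop("matrices have different sizes")
  ids <- if (inherits(fc_a, "fc_matrix")) fc_a$region_ids
         else paste0("R", seq_len(nrow(a)))
  mask <- scope_mask(ids, scope, assignment)
  if (sum(mask) < 2L) stop("scope selects fewer than 2 edges")
  cor(a[mask], b[mask], method = "spearman")
}

#' Threshold a connectivity matrix at a fraction of its maximum
#'
#' Entries below \code{fraction * max(fc)} are set to zero; the rest are
#' kept at their value. Used to suppress weak (potentially spurious)
#' connections before graph construction or comparison.
#'
#' @param fc an [fc_matrix()].
#' @param fraction threshold level in \code{[0, 1]} (e.g. 0.1, 0.2, 0.3).
#' @return a thresholded [fc_matrix()].
#' @export
threshold_fc <- function(fc, fraction) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (!is_scalar_number(fraction) || fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]")
  }
  v <- fc$values
  v[v < fraction * max(v)] <- 0
  fc_matrix(v, measure = fc$measure, subject_id = fc$subject_id,
            region_ids = fc$region_ids)
}

#' Spectral edge nonrandomness of a connectivity graph
#'
#' Binarizes the FC matrix by keeping the top \code{density} fraction of
#' edges, restricts to the largest connected component, and computes the
#' spectral edge-nonrandomness: nodes are embedded with the \code{k}
#' leading unit eigenvectors of the adjacency matrix and each present
#' edge receives twice the inner product of its endpoints' embeddings,
#' so that the total over all edges equals the sum of the \code{k} leading
#' adjacency eigenvalues exactly. Community-structured graphs score high;
#' random (Erdos-Renyi-like) graphs score low, and edges joining two
#' different communities tend to receive small values.
#'
#' @param fc an [fc_matrix()], or a binary adjacency matrix (used as-is,
#'   no thresholding).
#' @param density fraction of strongest edges kept when binarizing, in
#'   (0, 1); default 0.10.
#' @param k number of leading eigenvectors (nominally the number of
#'   communities); default 7, capped at the component size with a warning.
#' @return an object of class \code{"nonrandomness"}: list with
#'   \code{total}, \code{per_edge} (data.frame \code{region_a},
#'   \code{region_b}, \code{value}), \code{eigenvalues} (the k leading),
#'   \code{n_nodes}, \code{n_edges}, \code{density}, \code{k}.
#' @export
nonrandomness <- function(fc, density = 0.10, k = 7L) {
  if (!is_scalar_number(k) || k < 1) stop("`k` must be at least 1")
  k <- as.integer(k)
  if (inherits(fc, "fc_matrix")) {
    if (!is_scalar_number(density) || density <= 0 || density >= 1) {
      stop("`density` must lie strictly in (0, 1)")
    }
    v <- fc$values
    nr <- nrow(v)
    w <- v[upper_mask(nr)]
    n_keep <- max(1L, floor(density * length(w)))
    thr <- sort(w, decreasing = TRUE)[n_keep]
    adj <- (v >= thr) * 1
    diag(adj) <- 0
  } else {
    adj <- fc_values(fc)
    adj <- (adj != 0) * 1
    diag(adj) <- 0
    if (is.null(rownames(adj))) {
      dimnames(adj) <- rep(list(paste0("R", seq_len(nrow(adj)))), 2)
    }
  }
  if (sum(adj) == 0) stop("graph is empty after thresholding")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  adj <- adj[keep, keep, drop = FALSE]
  nn <- nrow(adj)
  if (k > nn) {
    warning("`k` = ", k, " exceeds component size ", nn, "; using ", nn)
    k <- nn
  }
  es <- eigen(adj, symmetric = TRUE)
  u <- es$vectors[, seq_len(k), drop = FALSE]
  idx <- which(upper_mask(nn) & adj == 1, arr.ind = TRUE)
  # r_ij = 2 * sum_l u_li u_lj; summed over edges this telescopes to
  # sum_l u_l' A u_l = sum of the k leading eigenvalues
  per_edge <- 2 * rowSums(u[idx[, 1], , drop = FALSE] *
                            u[idx[, 2], , drop = FALSE])
  structure(
    list(total = sum(per_edge),
         per_edge = data.frame(region_a = rownames(adj)[idx[, 1]],
                               region_b = rownames(adj)[idx[, 2]],
                               value = per_edge,
                               stringsAsFactors = FALSE),
         eigenvalues = es$values[seq_len(k)],
         n_nodes = nn, n_edges = nrow(idx),
         density = if (inherits(fc, "fc_matrix")) density else NA_real_,
         k = k),
    class = "nonrandomness"
  )
}

#' @export
print.nonrandomness <- function(x, ...) {
  cat("<nonrandomness> total", format(x$total, digits = 6),
      "over", x$n_edges, "edges /", x$n_nodes, "nodes (k =", x$k,
      if (!is.na(x$density)) paste0(", density ", x$density), ")\n")
  invisible(x)
}

#' Between-subject similarity of connectivity matrices
#'
#' Pearson correlation between each subject's (scoped) upper-triangle FC
#' values and the element-wise average matrix over all subjects -- how
#' consistently a measure recovers the shared network architecture across
#' individuals. The average includes the subject itself by default; set
#' \code{leave_one_out = TRUE} to exclude it.
#'
#' @param fcs list of [fc_matrix()] objects on the same regions (one per
#'   subject).
#' @param scope as in [measure_similarity()].
#' @param assignment required for non-\code{"all"} scopes.
#' @param leave_one_out exclude each subject from its own reference
#'   average (default \code{FALSE}).
#' @return named numeric vector of per-subject correlations.
#' @export
subject_similarity <- function(fcs, scope = "all", assignment = NULL,
                               leave_one_out = FALSE) {
  if (length(fcs) < 2L) stop("need at least 2 subjects")
  mats <- lapply(fcs, fc_values)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("subjects have different region counts")
  ids <- if (inherits(fcs[[1]], "fc_matrix")) fcs[[1]]$region_ids
         else paste0("R", seq_len(dims[1]))
  mask <- scope_mask(ids, scope, assignment)
  tri <- vapply(mats, function(m) m[mask], numeric(sum(mask)))
  avg <- rowMeans(tri)
  ns <- ncol(tri)
  sims <- vapply(seq_len(ns), function(s) {
    ref <- if (leave_one_out) (avg * ns - tri[, s]) / (ns - 1) else avg
    cor(tri[, s], ref)
  }, numeric(1))
  names(sims) <- vapply(seq_along(fcs), function(s) {
    id <- if (inherits(fcs[[s]], "fc_matrix")) fcs[[s]]$subject_id else NULL
    as.character(id %||% paste0("S", s))
  }, character(1))
  sims
}
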