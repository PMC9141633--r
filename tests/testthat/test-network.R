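# Whole-network assembly and graph-level statistics.

make_fc <- function(values, ...) fc_matrix(values, ...)

test_that("assemble_fc builds a symmetric matrix matching pair values", {
  set.seed(35)
  s <- rnorm(60)
  same <- lapply(1:3, function(i) region_activity(rbind(s, s), paste0("R", i)))
  fc <- assemble_fc(same, "pcor")
  off <- fc$values[upper.tri(fc$values)]
  expect_equal(off, rep(1, 3))
  expect_identical(fc$values, t(fc$values))
  expect_equal(diag(fc$values), setNames(rep(0, 3), fc$region_ids))

  regions <- lapply(1:5, function(i) {
    region_activity(matrix(rnorm(4 * 60), 4, 60), paste0("R", i))
  })
  fc <- assemble_fc(regions, "uvmi")
  for (k in 1:5) {
    i <- sample(4, 1)
    j <- sample(setdiff(1:5, i), 1)
    expect_equal(fc$values[i, j], fc_uvmi(regions[[i]], regions[[j]]),
                 tolerance = 1e-12)
  }
})

test_that("edge partition counts within and between edges", {
  assign4 <- data.frame(region = paste0("R", 1:4),
                        network = c("A", "A", "B", "B"))
  part <- partition_edges(paste0("R", 1:4), assign4)
  expect_identical(c(part$n_within, part$n_between), c(2L, 4L))
  expect_identical(part$n_within + part$n_between, 6L)

  one <- data.frame(region = paste0("R", 1:5), network = "A")
  expect_identical(partition_edges(paste0("R", 1:5), one)$n_between, 0L)
  expect_error(partition_edges(paste0("R", 1:3),
                               data.frame(region = "R1", network = "A")),
               "without a network")
})

test_that("measure similarity is a scoped Spearman rank correlation", {
  set.seed(37)
  v <- matrix(rnorm(36), 6)
  v <- v + t(v)
  fa <- make_fc(v, "pcor")
  fb <- make_fc(v * 2 + 1, "mvmi")            # monotone transform
  expect_equal(measure_similarity(fa, fa), 1)
  expect_equal(measure_similarity(fa, fb), 1)

  assign6 <- data.frame(region = fa$region_ids,
                        network = rep(c("A", "B"), each = 3))
  # block scope picks exactly the A-B edges
  ab <- measure_similarity(fa, fb, c("A", "B"), assign6)
  expect_equal(ab, 1)
  part <- partition_edges(fa, assign6)
  expect_identical(part$n_between, 9L)
})

test_that("thresholding keeps values at or above the max fraction", {
  set.seed(39)
  v <- abs(matrix(rnorm(25), 5))
  v <- (v + t(v)) / 2
  fc <- make_fc(v, "pcor")
  expect_identical(threshold_fc(fc, 0)$values, fc$values)
  top <- threshold_fc(fc, 1)
  expect_identical(sum(top$values > 0), 2L)    # the maximal edge, twice
  counts <- vapply(c(0.1, 0.3, 0.5, 0.9),
                   function(f) sum(threshold_fc(fc, f)$values > 0),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("nonrandomness total equals the sum of leading eigenvalues", {
  # complete graph: leading eigenvalue n - 1
  n <- 6
  kn <- matrix(1, n, n) - diag(n)
  dimnames(kn) <- rep(list(paste0("R", 1:n)), 2)
  nr <- nonrandomness(kn, k = 1)
  expect_equal(nr$total, n - 1, tolerance = 1e-8)

  set.seed(43)
  for (i in 1:10) {
    a <- er_graph(20, 40)
    k <- sample(1:5, 1)
    nr <- nonrandomness(a, k = k)
    # independent oracle: eigenvalues of the largest component's adjacency
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      a, mode = "undirected"))
    keep <- comp$membership == which.max(comp$csize)
    ev <- sort(eigen(a[keep, keep], symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    expect_equal(sum(nr$per_edge$value), sum(ev[seq_len(nr$k)]),
                 tolerance = 1e-8)
  }
})

test_that("community structure raises nonrandomness above random graphs", {
  set.seed(45)
  wins <- 0L
  gaps_ok <- 0L
  n_seeds <- 10L
  for (i in seq_len(n_seeds)) {
    a <- planted_graph(40, 0.5, 0.05)
    b <- er_graph(40, sum(a) / 2)
    nr_a <- nonrandomness(a, k = 2)
    nr_b <- nonrandomness(b, k = 2)
    wins <- wins + (nr_a$total > nr_b$total)
    # between-block edges score lower than within-block edges
    blk <- rep(c(1, 2), each = 20)
    names(blk) <- paste0("R", 1:40)
    between <- blk[nr_a$per_edge$region_a] != blk[nr_a$per_edge$region_b]
    if (any(between)) {
      gaps_ok <- gaps_ok +
        (mean(nr_a$per_edge$value[between]) <
           mean(nr_a$per_edge$value[!between]))
    }
  }
  expect_identical(wins, n_seeds)
  expect_gte(gaps_ok, n_seeds - 1L)
})

test_that("nonrandomness validates its inputs", {
  v <- abs(matrix(rnorm(16), 4)); v <- (v + t(v)) / 2
  fc <- make_fc(v, "pcor")
  expect_error(nonrandomness(fc, density = 1.5), "density")
  expect_error(nonrandomness(matrix(0, 3, 3)), "empty")
  expect_warning(nonrandomness(fc, density = 0.5, k = 10), "component size")
})

test_that("subject similarity ranks subjects against the cohort average", {
  set.seed(47)
  base <- matrix(rnorm(49), 7)
  base <- base + t(base)
  fcs <- lapply(1:4, function(s) make_fc(base, "pcor",
                                         subject_id = paste0("S", s)))
  expect_equal(unname(subject_similarity(fcs)), rep(1, 4))

  fcs[[4]] <- make_fc(-base, "pcor", subject_id = "S4")
  sims <- subject_similarity(fcs)
  expect_lt(sims["S4"], min(sims[1:3]))

  # less subject noise -> higher mean similarity
  mean_sim <- vapply(c(0.2, 1, 4), function(s) {
    f <- lapply(1:6, function(i) {
      e <- matrix(rnorm(49, sd = s), 7)
      make_fc(base + e + t(e), "pcor")
    })
    mean(subject_similarity(f))
  }, numeric(1))
  expect_true(all(diff(mean_sim) < 0))

  # leave-one-out lowers (or preserves) each similarity
  f <- lapply(1:5, function(i) {
    e <- matrix(rnorm(49), 7)
    make_fc(base + e + t(e), "pcor")
  })
  expect_true(all(subject_similarity(f, leave_one_out = TRUE) <=
                    subject_similarity(f) + 1e-12))
})
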