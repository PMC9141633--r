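# Independent oracles and small fixture builders used across the suite.

# Pearson correlation written out from its defining sum formula, so tests
# of fc_pcor do not go through stats::cor.
pearson_by_hand <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Kraskov-Stoegbauer-Grassberger (algorithm 1) MI estimate in bits for two
# univariate samples; brute-force O(n^2) distances. Used only as a
# reference estimator that, unlike the Gaussian copula, sees arbitrary
# dependence.
ksg_mi <- function(x, y, k = 4L) {
  n <- length(x)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dj <- pmax(dx, dy)
  diag(dj) <- Inf
  psi_sum <- 0
  for (i in seq_len(n)) {
    eps <- sort(dj[i, ])[k]
    nx <- sum(dx[i, -i] < eps)
    ny <- sum(dy[i, -i] < eps)
    psi_sum <- psi_sum + digamma(nx + 1) + digamma(ny + 1)
  }
  (digamma(k) + digamma(n) - psi_sum / n) / log(2)
}

# bivariate t-copula sample (heavy-tailed dependence), dims 2 x n
rtcopula <- function(n, rho, df = 3) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  w <- sqrt(rchisq(n, df) / df)
  rbind(z1 / w, z2 / w)
}

# two regions with no dependence between them (voxels iid standard normal)
independent_pair <- function(n_x = 10, n_y = 15, n_t = 500) {
  list(x = region_activity(matrix(rnorm(n_x * n_t), n_x, n_t), "x"),
       y = region_activity(matrix(rnorm(n_y * n_t), n_y, n_t), "y"))
}

# planted 2-block adjacency matrix (p_in within blocks, p_out across)
planted_graph <- function(n = 40, p_in = 0.5, p_out = 0.05) {
  half <- n / 2
  block <- rep(c(1, 2), each = half)
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- if (block[i] == block[j]) p_in else p_out
      a[i, j] <- a[j, i] <- rbinom(1, 1, p)
    }
  }
  dimnames(a) <- rep(list(paste0("R", seq_len(n))), 2)
  a
}

# Erdos-Renyi graph with a fixed number of edges
er_graph <- function(n, n_edges) {
  a <- matrix(0, n, n)
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
  a[pick] <- 1
  a <- a + t(a)
  dimnames(a) <- rep(list(paste0("R", seq_len(n))), 2)
  a
}
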