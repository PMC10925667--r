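# Independent oracles, written from first principles and deliberately not
# sharing code with the package.

# Breadth-first search hop distances from one node, on a plain 0/1 matrix.
bfs_distances <- function(A, start) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] > 0 & is.infinite(dist))
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

# Union-find connectivity oracle.
uf_connected <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) if (A[i, j] > 0) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, 1L))) == 1
}

# Brute-force fixed-step Euler integration of the reaction-diffusion system,
# with the reaction formulas written out inline.
euler_oracle <- function(A, theta0, w, r, kind, theta_c, t_max, h) {
  k <- rowSums(A)
  theta <- theta0
  steps <- round(t_max / h)
  for (s in seq_len(steps)) {
    gg <- switch(kind,
                 none = 0 * theta,
                 logistic = theta * (1 - theta),
                 strong_allee = theta * (theta - theta_c) * (1 - theta),
                 neutral_allee = pmax((theta - theta_c) * (1 - theta), 0))
    theta <- theta + h * (w * (as.vector(A %*% theta) - k * theta) + r * gg)
    theta[theta < 0] <- 0
  }
  theta
}

# Random Erdos-Renyi-style symmetric 0/1 matrix (possibly disconnected).
random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up[stats::runif(length(up)) < p]] <- 1
  A + t(A)
}

# The default synthetic connectome, generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (is.null(.fixture_cache$wc)) {
    .fixture_cache$wc <- generate_connectome(generator_spec())
    .fixture_cache$g <- threshold_adjacency(.fixture_cache$wc, 0.034)
    .fixture_cache$summary <- summarize_graph(.fixture_cache$g)
  }
  list(wc = .fixture_cache$wc, g = .fixture_cache$g,
       summary = .fixture_cache$summary)
}
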