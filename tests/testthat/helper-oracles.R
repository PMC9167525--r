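# Independent oracles and small fixture builders shared across tests.

# Brute-force TOM by triple loop, straight from the definition.
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  k <- rowSums(a) - 1
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# Step-up BH from the definition: q_(i) = min_{j >= i} m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws.
hyper_oracle <- function(k, K, n, N) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Expression matrix of `blocks` planted modules sharing a latent factor,
# plus optional background genes; rows are genes.
block_expression <- function(blocks, n_samples, noise_sd = 0.3,
                             n_background = 0, seed = 1) {
  withr::with_seed(seed, {
    f <- matrix(rnorm(length(blocks) * n_samples), length(blocks))
    x <- do.call(rbind, lapply(seq_along(blocks), function(m) {
      matrix(rep(f[m, ], each = blocks[m]), blocks[m], n_samples) +
        matrix(rnorm(blocks[m] * n_samples, 0, noise_sd), blocks[m])
    }))
    if (n_background > 0) {
      x <- rbind(x, matrix(rnorm(n_background * n_samples), n_background))
    }
    dimnames(x) <- list(sprintf("g%04d", seq_len(nrow(x))),
                        sprintf("s%03d", seq_len(n_samples)))
    x
  })
}

# Balanced 3-population x 2-temperature design.
balanced_design <- function(n_per_cell) {
  data.frame(population = rep(c("N.Ref", "TE", "S.Ref"), 2),
             acclimation = rep(c(12, 28), each = 3),
             n_samples = rep(n_per_cell, 6))
}

# Random symmetric adjacency with unit diagonal and values in [0, 1].
random_adjacency <- function(n, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
}
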