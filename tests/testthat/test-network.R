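test_that("adjacency applies the soft-threshold transform", {
  x <- block_expression(c(5), 30, noise_sd = 0.2, n_background = 5, seed = 2)
  r <- cor(t(x))
  for (type in c("unsigned", "signed")) {
    for (beta in c(1, 2, 5)) {
      a <- adjacency_matrix(x, beta, type)
      expected <- if (type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
      diag(expected) <- 1
      expect_equal(a, expected, tolerance = 1e-12)
    }
  }
  # perfectly correlated pair -> 1 for any power; signed anti-correlated -> 0
  y <- rbind(a = 1:10, b = 2 * (1:10) + 3, c = -(1:10))
  colnames(y) <- sprintf("s%02d", 1:10)
  a2 <- adjacency_matrix(y, 6, "unsigned")
  expect_equal(a2["a", "b"], 1)
  s2 <- adjacency_matrix(y, 6, "signed")
  expect_equal(s2["a", "c"], 0, tolerance = 1e-12)
  expect_error(adjacency_matrix(y, 0.5), ">= 1")
})

test_that("TOM matches its closed forms and the brute-force oracle", {
  ones <- matrix(1, 3, 3)
  t1 <- tom_similarity(ones)
  expect_equal(unname(t1), matrix(1, 3, 3))  # (1+1)/(2+1-1) = 1

  # unconnected pair with no common neighbour
  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 0.8
  expect_equal(tom_similarity(a)[1, 3], 0)

  for (seed in 1:3) {
    a6 <- random_adjacency(6, seed)
    expect_equal(tom_similarity(a6), tom_oracle(a6), tolerance = 1e-12)
  }
  a50 <- random_adjacency(50, 9)
  tom50 <- tom_similarity(a50)
  expect_equal(tom50, tom_oracle(a50), tolerance = 1e-12)
  expect_true(isSymmetric(tom50))
  expect_true(all(tom50 >= 0 & tom50 <= 1 + 1e-12))

  bad <- random_adjacency(4, 1)
  bad[1, 2] <- 0.9
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("soft-threshold scan reports decreasing connectivity and fits", {
  x <- block_expression(c(30, 30), 40, noise_sd = 0.5, n_background = 40,
                        seed = 3)
  scan <- soft_threshold_scan(x, powers = 1:6)
  expect_true(all(diff(scan$mean_connectivity) < 0))
  expect_error(soft_threshold_scan(x[1:10, ], 1:3), "20 genes")

  # connectivity drawn from a discrete power law: near-perfect fit
  k <- withr::with_seed(4, {
    vals <- 1:50
    sample(vals, 2000, replace = TRUE, prob = vals^-2)
  })
  fit <- coexphys:::scale_free_fit(k)
  expect_gt(fit$r_squared, 0.9)
  expect_lt(fit$slope, 0)

  degen <- coexphys:::scale_free_fit(rep(3, 100))
  expect_true(degen$degenerate && is.na(degen$r_squared))
})

test_that("dynamic tree cut recovers planted blocks and enforces min size", {
  x <- block_expression(c(50, 40, 30), 50, noise_sd = 0.23, seed = 4)
  tom <- tom_similarity(adjacency_matrix(x, 2))
  labels <- cluster_and_cut(1 - tom, min_module_size = 30)
  truth <- rep(1:3, c(50, 40, 30))
  expect_equal(length(setdiff(unique(labels), 0)), 3)
  expect_gt(ari(labels, truth), 0.95)

  # one homogeneous block stays one module
  xh <- block_expression(c(60), 40, noise_sd = 0.3, seed = 5)
  lh <- cluster_and_cut(1 - tom_similarity(adjacency_matrix(xh, 2)), 30)
  expect_equal(unname(lh), rep(1L, 60))

  # a block below the minimum size is unassigned
  xt <- block_expression(c(50, 40, 30, 10), 50, noise_sd = 0.23, seed = 4)
  lt <- cluster_and_cut(1 - tom_similarity(adjacency_matrix(xt, 2)), 30)
  expect_true(all(lt[121:130] == 0))
  expect_equal(length(setdiff(unique(lt), 0)), 3)
})

test_that("module labels are invariant to sample and gene permutations", {
  x <- block_expression(c(40, 30), 36, noise_sd = 0.3, n_background = 20,
                        seed = 6)
  tom <- tom_similarity(adjacency_matrix(x, 2))
  base <- cluster_and_cut(1 - tom, 30)

  perm_s <- withr::with_seed(7, sample(ncol(x)))
  tom_s <- tom_similarity(adjacency_matrix(x[, perm_s], 2))
  expect_equal(cluster_and_cut(1 - tom_s, 30), base)

  perm_g <- withr::with_seed(8, sample(nrow(x)))
  tom_g <- tom_similarity(adjacency_matrix(x[perm_g, ], 2))
  permuted <- cluster_and_cut(1 - tom_g, 30)
  expect_equal(permuted[names(base)], base)
})

test_that("eigengene matches the SVD oracle and orientation rules", {
  # identical profiles: ME is the standardized common profile, VE = 1
  prof <- sin(seq_len(20))
  x <- matrix(rep(prof, each = 5), 5, 20,
              dimnames = list(letters[1:5], sprintf("s%02d", 1:20)))
  eg <- eigengene(x, letters[1:5])
  expect_equal(eg$variance_explained, 1)
  expect_equal(unname(eg$me), as.numeric(scale(prof)), tolerance = 1e-12)

  # dense SVD oracle on random modules
  for (seed in 1:3) {
    xr <- withr::with_seed(seed, matrix(rnorm(300), 10, 30,
                                        dimnames = list(letters[1:10],
                                                        sprintf("s%02d", 1:30))))
    eg2 <- eigengene(xr, letters[1:10])
    pc1 <- prcomp(scale(t(xr)), center = FALSE)$x[, 1]
    expect_equal(abs(cor(eg2$me, pc1)), 1, tolerance = 1e-10)
    # orientation: mean member correlation positive
    expect_gt(mean(cor(t(xr), eg2$me)), 0)
    # invariant to gene relabeling
    eg3 <- eigengene(xr[10:1, ], letters[10:1])
    expect_equal(eg3$me, eg2$me, tolerance = 1e-10)
  }
  expect_error(eigengene(x, letters[1:2]), "at least 3")
})

test_that("eigengene-based merging is deterministic and idempotent", {
  x <- block_expression(c(40, 40), 30, noise_sd = 0.25, seed = 9)
  # duplicate module: split one block into two labels
  labels <- c(rep(1L, 20), rep(2L, 20), rep(3L, 40))
  names(labels) <- rownames(x)
  merged <- merge_close_modules(x, labels, 0.75)
  expect_equal(length(unique(merged$labels)), 2)
  expect_equal(merged$merged, 1L)
  # the two halves of block one now share a label
  expect_equal(length(unique(merged$labels[1:40])), 1)

  # far-apart modules unchanged
  labels2 <- c(rep(1L, 40), rep(2L, 40))
  names(labels2) <- rownames(x)
  unchanged <- merge_close_modules(x, labels2, 0.75)
  expect_equal(unchanged$merged, 0L)

  # idempotence: second pass changes nothing
  again <- merge_close_modules(x, merged$labels, 0.75)
  expect_equal(again$labels, merged$labels)
  expect_equal(again$merged, 0L)

  expect_error(merge_close_modules(x, labels, 1.5), "merge_threshold")
})

test_that("module membership finds hubs and positive fractions", {
  # identical profiles: all MM = 1, alphabetical tie-break for the hub
  prof <- cos(seq_len(25))
  x <- matrix(rep(prof, each = 4), 4, 25,
              dimnames = list(c("gB", "gA", "gD", "gC"),
                              sprintf("s%02d", 1:25)))
  labels <- setNames(rep(1L, 4), rownames(x))
  mes <- matrix(eigengene(x, rownames(x))$me, 25, 1,
                dimnames = list(colnames(x), "ME1"))
  memb <- module_membership(x, mes, labels)
  expect_equal(unname(memb$mm[, 1]), rep(1, 4), tolerance = 1e-12)
  expect_equal(memb$hubs$hub, "gA")
  expect_equal(unname(memb$positive_fraction), 1)

  # planted hub with double loading is recovered in most seeds
  hits <- vapply(1:20, function(seed) {
    xs <- withr::with_seed(seed, {
      f <- rnorm(40)
      lam <- c(2, rep(1, 29))
      xs <- lam %o% f + matrix(rnorm(30 * 40, 0, 1), 30, 40)
      dimnames(xs) <- list(c("hub", sprintf("g%02d", 1:29)),
                           sprintf("s%02d", 1:40))
      xs
    })
    lab <- setNames(rep(1L, 30), rownames(xs))
    me <- matrix(eigengene(xs, rownames(xs))$me, 40, 1,
                 dimnames = list(colnames(xs), "ME1"))
    module_membership(xs, me, lab)$hubs$hub == "hub"
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # orientation forces mean member MM > 0
  x2 <- block_expression(c(30), 40, noise_sd = 1, seed = 10)
  lab2 <- setNames(rep(1L, 30), rownames(x2))
  me2 <- matrix(eigengene(x2, rownames(x2))$me, 40, 1,
                dimnames = list(colnames(x2), "ME1"))
  memb2 <- module_membership(x2, me2, lab2)
  expect_gt(mean(memb2$mm[, 1]), 0)
})

test_that("planted modules are recovered end to end with high ARI", {
  cfg <- sim_config(n_genes = 600, module_sizes = c(50, 50, 50),
                    design = balanced_design(10),
                    loading_range = c(0.8, 1.2), dispersion = 0.2,
                    seed = 11)
  ds <- simulate_dataset(cfg)
  x <- normalize_counts(ds$counts)$log_values
  mods <- detect_modules(x, beta = 5)
  expect_gt(ari(mods$labels, ds$truth$module), 0.8)
  # eigengenes track the planted factors
  for (m in 1:3) {
    best <- max(abs(cor(ds$truth$factors[m, ], mods$mes)))
    expect_gt(best, 0.9)
  }
})
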