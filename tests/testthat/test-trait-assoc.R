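test_that("mass residuals follow ordinary least squares", {
  mass <- c(1, 2, 3)
  expect_equal(mass_residuals(2 * mass, mass), c(0, 0, 0))

  # mass-independent trait: residuals are the centered trait
  trait <- c(4, 4, 4)
  expect_equal(mass_residuals(trait, mass), c(0, 0, 0))
  trait2 <- c(5, 1, 3) - mean(c(5, 1, 3))
  # slope of trait2 on mass: cov/var
  b <- cov(trait2, mass) / var(mass)
  expect_equal(mass_residuals(trait2, mass),
               trait2 - b * (mass - mean(mass)), tolerance = 1e-12)

  # closed-form OLS toy: residuals (1/6, -1/3, 1/6)
  expect_equal(mass_residuals(c(2, 4, 7), mass), c(1 / 6, -1 / 3, 1 / 6),
               tolerance = 1e-12)

  # missing values preserved in place
  out <- mass_residuals(c(2, NA, 4, 7, 5), c(1, 2, 3, 4, 5))
  expect_true(is.na(out[2]) && sum(is.na(out)) == 1)

  expect_error(mass_residuals(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(mass_residuals(c(1, NA, NA), c(1, 2, 3)), "3 non-missing")
})

test_that("ME-trait correlation matches hand computation with per-trait BH", {
  me1 <- c(1, 2, 3, 4, 5)
  mes <- cbind(ME1 = me1, ME2 = c(2, 1, 4, 3, 5))
  rownames(mes) <- sprintf("s%d", 1:5)
  traits <- cbind(self = me1, rev = 5:1, toy = c(1.2, 1.9, 3.4, 3.6, 5.1))
  rownames(traits) <- rownames(mes)
  res <- correlate_me_traits(mes, traits)

  expect_equal(res$r[res$trait == "self" & res$module == "ME1"], 1)
  expect_equal(res$r[res$trait == "rev" & res$module == "ME1"], -1)

  # independent computation of r and its t(3)-based p for the toy trait
  r_hand <- sum(scale(me1) * scale(traits[, "toy"])) / 4
  t_hand <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  row <- res[res$trait == "toy" & res$module == "ME1", ]
  expect_equal(row$r, r_hand, tolerance = 1e-10)
  expect_equal(row$p, p_hand, tolerance = 1e-10)

  # BH within each trait family (2 modules per trait)
  for (k in colnames(traits)) {
    sub <- res[res$trait == k, ]
    expect_equal(sub$q, bh_oracle(sub$p), tolerance = 1e-12)
  }
  expect_error(correlate_me_traits(mes[1:3, ], traits[1:3, ]),
               "4 complete pairs")
})

test_that("jack-knife support is exact for deterministic relations", {
  me <- seq_len(40)
  jk <- jackknife_support(me, 2 * me + 1, seed = 1)
  expect_equal(jk$support, 100)
  expect_true(jk$pass)
  expect_error(jackknife_support(1:9, 1:9, seed = 1), "n >= 10")
  # reproducible under the same seed
  x <- withr::with_seed(2, rnorm(40))
  y <- withr::with_seed(3, rnorm(40))
  expect_identical(jackknife_support(x, y, seed = 7),
                   jackknife_support(x, y, seed = 7))
})

test_that("jack-knife rarely passes independent ME-trait pairs", {
  false_pass <- withr::with_seed(12, {
    vapply(1:200, function(i) {
      me <- rnorm(40)
      trait <- rnorm(40)
      jackknife_support(me, trait, seed = i)$pass
    }, logical(1))
  })
  expect_lt(mean(false_pass), 0.05)
})

test_that("jack-knife keeps strong correlations at moderate sample size", {
  # true |r| ~ 0.7 at n = 20: the screen retains most such signals
  pass <- withr::with_seed(13, {
    vapply(1:100, function(i) {
      f <- rnorm(20)
      me <- f + rnorm(20, 0, 0.7)
      trait <- f + rnorm(20, 0, 0.7)
      jackknife_support(me, trait, seed = 1000 + i)$pass
    }, logical(1))
  })
  expect_gt(mean(pass), 0.8)
})

test_that("an injected trait outlier can fake significance that the screen catches", {
  # zero-coupling datasets with one +5 SD trait value: occasionally a module
  # eigengene attains spurious full-sample significance with the shifted
  # trait; the screen fails at least one such case
  w0 <- matrix(0, 6, 2)
  spurious <- 0L
  rejected <- 0L
  for (i in 1:20) {
    cfg <- sim_config(n_genes = 70, module_sizes = c(30, 30),
                      design = balanced_design(7), trait_weights = w0,
                      dispersion = 0.2, seed = 4000 + i)
    ds <- simulate_dataset(cfg)
    ds <- inject_outlier(ds, sample_index = 1 + (i %% 42),
                         trait_shift = c(WAM = 5))
    x <- normalize_counts(ds$counts)$log_values
    for (m in 1:2) {
      me <- eigengene(x, names(ds$truth$module)[ds$truth$module == m])$me
      if (cor.test(me, ds$traits[, "WAM"])$p.value < 0.05) {
        spurious <- spurious + 1L
        jk <- jackknife_support(me, ds$traits[, "WAM"], seed = 5000 + i)
        if (!jk$pass) rejected <- rejected + 1L
      }
    }
  }
  expect_gte(spurious, 1)
  expect_gte(rejected, 1)
})

test_that("multiple correlation equals the square root of OLS R-squared", {
  withr::with_seed(15, {
    mes <- matrix(rnorm(120), 40, 3,
                  dimnames = list(NULL, c("ME1", "ME2", "ME3")))
    trait <- 0.8 * mes[, 1] - 0.5 * mes[, 2] + rnorm(40)
  })
  mc <- multiple_correlation(trait, mes)
  oracle <- summary(lm(trait ~ mes[, 1] + mes[, 2] + mes[, 3]))$r.squared
  expect_equal(mc$r_squared, oracle, tolerance = 1e-12)
  expect_equal(mc$R, sqrt(oracle), tolerance = 1e-12)

  # single ME: R = |r|
  single <- multiple_correlation(trait, mes[, 1, drop = FALSE])
  expect_equal(single$R, abs(cor(trait, mes[, 1])), tolerance = 1e-12)

  # exact linear combination: R = 1
  exact <- 2 * mes[, 1] - mes[, 2]
  expect_equal(multiple_correlation(exact, mes[, 1:2])$R, 1,
               tolerance = 1e-10)

  # monotone non-decreasing as MEs are added
  r1 <- multiple_correlation(trait, mes[, 1, drop = FALSE])$R
  r2 <- multiple_correlation(trait, mes[, 1:2])$R
  r3 <- multiple_correlation(trait, mes)$R
  expect_true(r1 <= r2 + 1e-12 && r2 <= r3 + 1e-12)

  expect_error(multiple_correlation(rnorm(4), matrix(rnorm(12), 4, 3)),
               "fewer eigengenes")
})

test_that("gene significance mirrors trait correlation with hub selection", {
  x <- block_expression(c(10), 30, noise_sd = 0.5, seed = 16)
  trait <- x[4, ]
  gs <- gene_significance(x, trait)
  expect_equal(unname(gs$gs[4]), 1)

  flipped <- gene_significance(x, -trait)
  expect_equal(flipped$gs, -gs$gs, tolerance = 1e-12)

  # direct-computation oracle
  expect_equal(unname(gs$gs), unname(drop(cor(t(x), trait))),
               tolerance = 1e-12)

  labels <- setNames(rep(1L, 10), rownames(x))
  with_hubs <- gene_significance(x, trait, labels)
  expect_equal(with_hubs$hubs$hub, rownames(x)[4])
  expect_true(with_hubs$positive_fraction > 0)
})

test_that("association summary reproduces the published AVERAGE rows", {
  heart <- data.frame(
    trait = c("CTMax12", "CTMax28", "FA12", "FA12", "FA12", "hm12",
              "LKA12", "LKA12", "WAM12", "WAM12", "WAM12", "WAM12"),
    module = paste0("ME", c(1, 2, 3, 4, 5, 6, 6, 7, 8, 9, 4, 5)),
    r = c(0.49, -0.53, 0.50, 0.53, 0.55, -0.57, -0.65, -0.56, -0.56,
          -0.55, -0.54, -0.56)
  )
  hs <- association_summary(heart)
  expect_equal(hs$r[hs$trait == "AVERAGE"], 0.55)

  brain <- data.frame(
    trait = c("bm12", "bm28", "CTmax28", "CTmax28", "CTmax28", "WAM28"),
    module = paste0("ME", c(1, 3, 2, 3, 4, 4)),
    r = c(-0.60, 0.58, -0.60, -0.57, -0.67, -0.70)
  )
  bs <- association_summary(brain)
  expect_equal(bs$r[bs$trait == "AVERAGE"], 0.62)

  single <- association_summary(data.frame(trait = "t", module = "ME1",
                                           r = -0.4))
  expect_equal(single$r[single$trait == "AVERAGE"], 0.40)
  expect_null(association_summary(data.frame(trait = character(),
                                             module = character(),
                                             r = numeric())))
})

test_that("range spread is (max - min) / min on positive values", {
  expect_equal(range_spread(c(3, 3, 3)), 0)
  expect_equal(range_spread(c(1, 15)), 14)
  expect_error(range_spread(c(0, 5)), "positive minimum")
  expect_error(range_spread(c(-1, 5)), "positive minimum")
})

test_that("planted trait weights give sign-correct recovered associations", {
  w <- matrix(0, 6, 2)
  w[1, 1] <- 1      # WAM coupled positively to module 1
  w[4, 2] <- -1     # CaM_FA coupled negatively to module 2
  ok <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_genes = 200, module_sizes = c(40, 40),
                      design = data.frame(population = "TE",
                                          acclimation = 12, n_samples = 60),
                      trait_weights = w, trait_noise_sd = 1,
                      dispersion = 0.2, seed = 3000 + seed)
    ds <- simulate_dataset(cfg)
    x <- normalize_counts(ds$counts)$log_values
    mods <- detect_modules(x, beta = 5)
    if (is.null(mods$mes) || ncol(mods$mes) < 2) return(FALSE)
    # match detected modules to planted ones through the latent factors
    match1 <- which.max(abs(cor(ds$truth$factors[1, ], mods$mes)))
    match2 <- which.max(abs(cor(ds$truth$factors[2, ], mods$mes)))
    res <- correlate_me_traits(mods$mes, ds$traits[, c("WAM", "CaM_FA")])
    r_wam <- res$r[res$trait == "WAM" &
                     res$module == colnames(mods$mes)[match1]]
    q_wam <- res$q[res$trait == "WAM" &
                     res$module == colnames(mods$mes)[match1]]
    r_fa <- res$r[res$trait == "CaM_FA" &
                    res$module == colnames(mods$mes)[match2]]
    q_fa <- res$q[res$trait == "CaM_FA" &
                    res$module == colnames(mods$mes)[match2]]
    sgn1 <- sign(cor(ds$truth$factors[1, ], mods$mes[, match1]))
    sgn2 <- sign(cor(ds$truth$factors[2, ], mods$mes[, match2]))
    q_wam < 0.05 && q_fa < 0.05 &&
      sign(r_wam) == sgn1 && sign(r_fa) == -sgn2
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
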