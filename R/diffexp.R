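# Simplified negative-binomial GLM differential expression.
#
# This engine deliberately omits the dispersion shrinkage, Cook's-distance
# outlier handling and independent filtering of full-featured DE packages:
# per-gene dispersion is a method-of-moments estimate from a Poisson fit and
# the NB GLM is fitted at that fixed dispersion. Users should not expect
# count-for-count agreement with analyses run through those packages.

#' Method-of-moments NB dispersion estimate
#'
#' Fits a Poisson GLM (log link, offset `log(size_factors)`) and estimates the
#' negative-binomial dispersion phi (variance = mu + phi * mu^2) as
#' `max(phi_min, sum(((y - mu)^2 - mu) / mu^2) / (n - rank))`.
#'
#' @param y counts for one gene.
#' @param design model matrix.
#' @param sf size factors.
#' @param phi_min dispersion floor (default 1e-8).
#' @return Estimated dispersion (scalar).
#' @export
estimate_dispersion <- function(y, design, sf, phi_min = 1e-8) {
  if (length(y) < qr(design)$rank + 1) {
    stop("need more samples than design rank", call. = FALSE)
  }
  if (all(y == 0)) stop("all-zero gene: dispersion undefined", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::poisson(), offset = log(sf))
  )
  mu <- fit$fitted.values
  r <- qr(design)$rank
  phi <- sum(((y - mu)^2 - mu) / mu^2) / (length(y) - r)
  max(phi_min, phi)
}

#' Fit a negative-binomial GLM at fixed dispersion
#'
#' Log link with offset `log(size_factors)` and NB variance mu + phi * mu^2,
#' fitted by iteratively reweighted least squares. Non-convergence is flagged
#' rather than raising an error so callers can exclude the gene with a log
#' entry.
#'
#' @param y counts for one gene.
#' @param design full-rank model matrix.
#' @param sf size factors.
#' @param phi fixed NB dispersion.
#' @return list with `coefficients`, `vcov` (at dispersion 1), `fitted`,
#'   `converged`, `phi`, and the log-likelihood `logLik`.
#' @export
fit_nb_glm <- function(y, design, sf, phi) {
  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  fam <- if (phi <= 1e-8) {
    stats::poisson()
  } else {
    MASS::negative.binomial(theta = 1 / phi)
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      design, y, family = fam, offset = log(sf),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    )),
    error = function(e) NULL
  )
  boundary <- !is.null(fit) &&
    (any(fit$fitted.values < 1e-8) || any(abs(fit$coefficients) > 30))
  if (is.null(fit) || !fit$converged || boundary ||
      any(!is.finite(fit$coefficients))) {
    return(list(coefficients = rep(NA_real_, ncol(design)),
                vcov = matrix(NA_real_, ncol(design), ncol(design)),
                fitted = rep(NA_real_, length(y)),
                converged = FALSE, phi = phi, logLik = NA_real_))
  }
  # Wald covariance at dispersion 1: (X' W X)^{-1} from the final IRLS weights
  w <- fit$weights
  xw <- design * sqrt(w)
  vcov <- chol2inv(chol(crossprod(xw)))
  dimnames(vcov) <- list(colnames(design), colnames(design))
  mu <- fit$fitted.values
  ll <- if (phi <= 1e-8) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  list(coefficients = fit$coefficients, vcov = vcov, fitted = mu,
       converged = TRUE, phi = phi, logLik = ll)
}

#' Wald test of a linear contrast
#'
#' z = c'beta / sqrt(c' Sigma c), two-sided p from the standard normal.
#'
#' @param fit a [fit_nb_glm()] result.
#' @param contrast numeric contrast vector, one entry per coefficient.
#' @return list with `estimate` (c'beta), `se`, `statistic`, `p`.
#' @export
wald_contrast <- function(fit, contrast) {
  if (length(contrast) != length(fit$coefficients)) {
    stop("contrast length must match the number of coefficients",
         call. = FALSE)
  }
  if (all(contrast == 0)) stop("zero contrast vector", call. = FALSE)
  if (!fit$converged) {
    return(list(estimate = NA_real_, se = NA_real_, statistic = NA_real_,
                p = NA_real_))
  }
  est <- sum(contrast * fit$coefficients)
  se <- sqrt(drop(t(contrast) %*% fit$vcov %*% contrast))
  z <- est / se
  list(estimate = est, se = se, statistic = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment:
#' q_(i) = min over j >= i of m * p_(j) / j, with stable handling of ties.
#'
#' @param p vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Shared internals ------------------------------------------------------

de_design_matrix <- function(samples, model = c("interaction",
                                                "population_only")) {
  model <- match.arg(model)
  pop <- factor(samples$population, levels = c("N.Ref", "TE", "S.Ref"))
  if (anyNA(pop)) stop("unknown population labels", call. = FALSE)
  if (model == "population_only") {
    return(stats::model.matrix(~pop))
  }
  acc <- factor(samples$acclimation, levels = c(12, 28))
  stats::model.matrix(~ pop * acc)
}

fit_gene_table <- function(counts, design, sf) {
  lapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]
    if (all(y == 0)) return(NULL)
    phi <- estimate_dispersion(y, design, sf)
    fit_nb_glm(y, design, sf, phi)
  })
}

# natural-log contrast results converted to log2 for reporting
contrast_row <- function(fit, contrast, gene, name) {
  w <- wald_contrast(fit, contrast)
  data.frame(gene_id = gene, contrast = name,
             log2fc = w$estimate / log(2), se = w$se / log(2),
             stat = w$statistic, p = w$p, stringsAsFactors = FALSE)
}

finalize_de_table <- function(rows, fdr) {
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$direction <- ifelse(res$log2fc > 0, "up",
                          ifelse(res$log2fc < 0, "down", "none"))
  res$significant <- !is.na(res$q) & res$q < fdr
  res
}

#' Acclimation differential expression within each population
#'
#' Fits the interaction model `~ population * acclimation` per gene and tests
#' the 12 vs 28 degree contrast within each population. BH correction is
#' applied jointly across all comparisons made within the model; significance
#' is q below `fdr`. An interaction likelihood-ratio test (full vs additive
#' model) is reported per gene to quantify population-specific acclimation
#' responses.
#'
#' @param counts gene x sample count matrix.
#' @param samples data.frame with `population` and `acclimation` per sample
#'   (column order matching `counts`).
#' @param sf size factors (computed from `counts` when NULL).
#' @param fdr significance threshold on q (default 0.05).
#' @return list with `table` (gene, contrast, log2fc, se, stat, p, q,
#'   direction, significant), `deg_sets` (list of significant gene ids per
#'   population), and `interaction` (per-gene LRT p/q and the fraction of
#'   genes with interaction q < fdr).
#' @export
acclimation_de_per_population <- function(counts, samples, sf = NULL,
                                          fdr = 0.05) {
  stop_if_not_count_matrix(counts)
  sf <- sf %||% size_factors(counts)
  design <- de_design_matrix(samples, "interaction")
  design_add <- stats::model.matrix(
    ~ factor(samples$population, levels = c("N.Ref", "TE", "S.Ref")) +
      factor(samples$acclimation, levels = c(12, 28))
  )
  # coefficients: (Intercept), popTE, popS.Ref, acc28, popTE:acc28,
  # popS.Ref:acc28; acclimation effect is acc28 (+ interaction term per pop)
  contrasts <- list(
    N.Ref = c(0, 0, 0, 1, 0, 0),
    TE = c(0, 0, 0, 1, 1, 0),
    S.Ref = c(0, 0, 0, 1, 0, 1)
  )
  rows <- list()
  lrt_p <- rep(NA_real_, nrow(counts))
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    if (all(y == 0)) next
    phi <- estimate_dispersion(y, design, sf)
    fit <- fit_nb_glm(y, design, sf, phi)
    if (!fit$converged) next
    for (pp in names(contrasts)) {
      rows[[length(rows) + 1]] <-
        contrast_row(fit, contrasts[[pp]], rownames(counts)[g],
                     paste0("acc28_vs_12_", pp))
    }
    fit0 <- fit_nb_glm(y, design_add, sf, phi)
    if (fit0$converged) {
      lr <- 2 * (fit$logLik - fit0$logLik)
      lrt_p[g] <- stats::pchisq(max(lr, 0), df = 2, lower.tail = FALSE)
    }
  }
  res <- finalize_de_table(rows, fdr)
  deg_sets <- lapply(names(contrasts), function(pp) {
    res$gene_id[res$significant & res$contrast == paste0("acc28_vs_12_", pp)]
  })
  names(deg_sets) <- names(contrasts)
  lrt_q <- bh_adjust(lrt_p)
  list(table = res, deg_sets = deg_sets,
       interaction = list(
         p = stats::setNames(lrt_p, rownames(counts)),
         q = stats::setNames(lrt_q, rownames(counts)),
         significant_fraction = mean(lrt_q < fdr, na.rm = TRUE)
       ))
}

#' Pairwise population differential expression within one temperature
#'
#' Fits the population-only model `~ population` per gene on samples from a
#' single acclimation temperature and tests the three pairwise Wald contrasts
#' (TE vs N.Ref, TE vs S.Ref, N.Ref vs S.Ref). BH correction is applied
#' jointly across all three comparisons.
#'
#' @inheritParams acclimation_de_per_population
#' @return list with `table` and `flags`, a gene x contrast logical matrix of
#'   significance used by [classify_adaptive()].
#' @export
population_de_within_temperature <- function(counts, samples, sf = NULL,
                                             fdr = 0.05) {
  stop_if_not_count_matrix(counts)
  if (length(unique(samples$acclimation)) != 1) {
    stop("samples must come from a single acclimation temperature",
         call. = FALSE)
  }
  sf <- sf %||% size_factors(counts)
  design <- de_design_matrix(samples, "population_only")
  # coefficients: (Intercept), popTE, popS.Ref
  contrasts <- list(
    TE_vs_N.Ref = c(0, 1, 0),
    TE_vs_S.Ref = c(0, 1, -1),
    N.Ref_vs_S.Ref = c(0, 0, -1)
  )
  rows <- list()
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    if (all(y == 0)) next
    phi <- estimate_dispersion(y, design, sf)
    fit <- fit_nb_glm(y, design, sf, phi)
    if (!fit$converged) next
    for (cc in names(contrasts)) {
      rows[[length(rows) + 1]] <-
        contrast_row(fit, contrasts[[cc]], rownames(counts)[g], cc)
    }
  }
  res <- finalize_de_table(rows, fdr)
  genes <- unique(res$gene_id)
  flags <- matrix(FALSE, length(genes), length(contrasts),
                  dimnames = list(genes, names(contrasts)))
  for (cc in names(contrasts)) {
    sub <- res[res$contrast == cc, ]
    flags[sub$gene_id, cc] <- sub$significant
  }
  list(table = res, flags = flags)
}

#' Classify the adaptive expression pattern
#'
#' A gene shows the adaptive pattern when the thermally altered population
#' (TE) differs significantly from both reference populations while the two
#' references do not differ from each other.
#'
#' @param flags logical matrix (or data.frame) with columns `TE_vs_N.Ref`,
#'   `TE_vs_S.Ref`, `N.Ref_vs_S.Ref`.
#' @return Named logical vector, one entry per gene.
#' @export
classify_adaptive <- function(flags) {
  flags <- as.matrix(flags)
  need <- c("TE_vs_N.Ref", "TE_vs_S.Ref", "N.Ref_vs_S.Ref")
  if (!all(need %in% colnames(flags))) {
    stop("flags must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- flags[, "TE_vs_N.Ref"] & flags[, "TE_vs_S.Ref"] &
    !flags[, "N.Ref_vs_S.Ref"]
  stats::setNames(as.logical(out), rownames(flags))
}

#' Venn partition of three DEG sets
#'
#' Partitions the union of three gene sets into the seven exclusive Venn
#' regions and reports the shared fraction: the proportion of the union
#' present in at least two sets.
#'
#' @param sets named list of three character vectors.
#' @return list with `regions` (named counts: `A_only`, ..., `ABC`),
#'   `union_size`, `shared` (genes in >= 2 sets) and `shared_fraction`.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) != 3) stop("need exactly three sets", call. = FALSE)
  nm <- names(sets) %||% c("A", "B", "C")
  a <- unique(sets[[1]]); b <- unique(sets[[2]]); c <- unique(sets[[3]])
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  regions <- c(
    sum(in_a & !in_b & !in_c), sum(!in_a & in_b & !in_c),
    sum(!in_a & !in_b & in_c), sum(in_a & in_b & !in_c),
    sum(in_a & !in_b & in_c), sum(!in_a & in_b & in_c),
    sum(in_a & in_b & in_c)
  )
  names(regions) <- c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
                      paste0(nm[3], "_only"),
                      paste0(nm[1], "_", nm[2]), paste0(nm[1], "_", nm[3]),
                      paste0(nm[2], "_", nm[3]),
                      paste(nm, collapse = "_"))
  shared <- u[(in_a + in_b + in_c) >= 2]
  list(regions = regions, union_size = length(u), shared = shared,
       shared_fraction = if (length(u) == 0) 0 else length(shared) / length(u))
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction; degrees of freedom (r - 1)(c - 1). Errors when
#' any expected cell count is zero.
#'
#' @param tab contingency table (matrix).
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative cell counts", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("zero expected cell count; chi-squared test undefined",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}
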