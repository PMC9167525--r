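# Module eigengene - physiological trait association with jack-knife
# robustness screening.

#' Mass-corrected trait residuals
#'
#' Ordinary least squares of the trait on a mass covariate; the residuals
#' carry the trait variation not explained by body (or heart) size. Samples
#' with missing trait or mass are returned as NA residuals.
#'
#' @param trait numeric trait values.
#' @param mass positive mass covariate, same length.
#' @return Residuals, same length and order as `trait` (NA where input was
#'   missing).
#' @export
mass_residuals <- function(trait, mass) {
  ok <- !is.na(trait) & !is.na(mass)
  if (sum(ok) < 3) stop("need at least 3 non-missing pairs", call. = FALSE)
  if (stats::var(mass[ok]) == 0) {
    stop("mass covariate has zero variance", call. = FALSE)
  }
  fit <- stats::lm(trait[ok] ~ mass[ok])
  out <- rep(NA_real_, length(trait))
  out[ok] <- stats::residuals(fit)
  out
}

#' Signed Pearson correlation of module eigengenes with traits
#'
#' Pairwise-complete Pearson correlation of each eigengene with each
#' (mass-residual) trait, two-sided t-test p-values, and BH correction across
#' modules within each trait (the correction family the analysis uses for a
#' single trait).
#'
#' @param mes sample x module eigengene matrix.
#' @param traits sample x trait matrix of residual trait values (NA allowed).
#' @return data.frame: `trait`, `module`, `r`, `n`, `p`, `q`.
#' @export
correlate_me_traits <- function(mes, traits) {
  traits <- as.matrix(traits)
  rows <- list()
  for (k in colnames(traits)) {
    for (m in colnames(mes)) {
      ok <- !is.na(traits[, k]) & !is.na(mes[, m])
      n <- sum(ok)
      if (n < 4) {
        stop("fewer than 4 complete pairs for ", k, " vs ", m, call. = FALSE)
      }
      ct <- stats::cor.test(mes[ok, m], traits[ok, k])
      rows[[length(rows) + 1]] <- data.frame(
        trait = k, module = m, r = unname(ct$estimate), n = n,
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- stats::ave(res$p, res$trait, FUN = bh_adjust)
  res
}

#' Jack-knife robustness screen for one module-trait correlation
#'
#' Repeatedly subsamples `floor(frac * n)` samples without replacement and
#' recomputes the Pearson correlation. The support count is the number of
#' repetitions whose raw p is below `alpha` AND whose correlation has the same
#' sign as the full-sample correlation; the pair passes when support reaches
#' `min_support`. This removes significant correlations driven by one or a
#' few outlying individuals, which dominate the full-sample correlation but
#' drop out of many subsamples.
#'
#' @param me eigengene scores per sample.
#' @param trait residual trait values per sample (NA allowed; complete pairs
#'   used).
#' @param frac subsample fraction (default 0.9).
#' @param reps repetitions (default 100).
#' @param alpha within-repetition raw significance level (default 0.05).
#' @param min_support support needed to pass (default 70, inclusive).
#' @param seed RNG seed for reproducible subsampling.
#' @return list with `support` (0..reps), `pass`, `r_full`, `reps`.
#' @export
jackknife_support <- function(me, trait, frac = 0.9, reps = 100,
                              alpha = 0.05, min_support = 70, seed = NULL) {
  ok <- !is.na(me) & !is.na(trait)
  me <- me[ok]; trait <- trait[ok]
  n <- length(me)
  if (n < 10) {
    stop("jack-knife screen needs n >= 10 so the 90% subsample drops ",
         "at least one sample", call. = FALSE)
  }
  m <- floor(frac * n)
  r_full <- stats::cor(me, trait)
  support <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(reps)) {
      idx <- sample.int(n, m)
      ct <- stats::cor.test(me[idx], trait[idx])
      if (!is.na(ct$p.value) && ct$p.value < alpha &&
          sign(unname(ct$estimate)) == sign(r_full)) {
        hits <- hits + 1L
      }
    }
    hits
  })
  list(support = support, pass = support >= min_support, r_full = r_full,
       reps = reps)
}

#' Multiple correlation of a trait with several eigengenes
#'
#' Fits `trait ~ ME1 + ME2 + ...` by OLS and returns the Pearson correlation
#' between fitted and observed values — the square root of the regression
#' R-squared, i.e. how well the passing modules jointly predict the trait.
#'
#' @param trait residual trait values.
#' @param mes sample x module matrix of the eigengenes to combine.
#' @return list with `R` (multiple correlation), `r_squared`, `n`,
#'   `coefficients`.
#' @export
multiple_correlation <- function(trait, mes) {
  mes <- as.matrix(mes)
  ok <- !is.na(trait) & stats::complete.cases(mes)
  trait <- trait[ok]; mes <- mes[ok, , drop = FALSE]
  if (ncol(mes) >= length(trait) - 2) {
    stop("need fewer eigengenes than n - 2 samples", call. = FALSE)
  }
  fit <- stats::lm(trait ~ mes)
  # suppress summary.lm's note on exact fits; R = 1 is a legitimate result
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(R = stats::cor(stats::fitted(fit), trait), r_squared = r2,
       n = length(trait), coefficients = stats::coef(fit))
}

#' Gene significance for a trait
#'
#' GS of a gene is the Pearson correlation between its expression and the
#' (residual) trait. Per module, the hub-GS gene maximizes |GS| among members
#' (signed GS reported, ties to the smallest gene id) and the positive-GS
#' fraction is the share of members with GS > 0.
#'
#' @param expr gene x sample log-expression matrix.
#' @param trait residual trait values per sample.
#' @param labels optional named module labels; when given, per-module hub-GS
#'   and positive fractions are returned.
#' @return list with `gs` (named per gene) and, when labels are supplied,
#'   `hubs` (module, hub gene, gs) and `positive_fraction` per module.
#' @export
gene_significance <- function(expr, trait, labels = NULL) {
  ok <- !is.na(trait)
  gs <- drop(stats::cor(t(expr[, ok, drop = FALSE]), trait[ok]))
  names(gs) <- rownames(expr)
  out <- list(gs = gs)
  if (!is.null(labels)) {
    mods <- sort(setdiff(unique(labels), 0))
    out$hubs <- do.call(rbind, lapply(mods, function(m) {
      members <- sort(names(labels)[labels == m])
      v <- gs[members]
      hub <- members[which.max(abs(v))]
      data.frame(module = m, hub = hub, gs = unname(v[hub]),
                 stringsAsFactors = FALSE)
    }))
    out$positive_fraction <- stats::setNames(
      vapply(mods, function(m) mean(gs[names(labels)[labels == m]] > 0),
             numeric(1)),
      paste0("ME", mods))
  }
  out
}

#' Module-trait association with jack-knife screening
#'
#' End-to-end association stage: correlates every eigengene with every
#' residual trait (BH within trait), applies the jack-knife screen to the
#' FDR-significant pairs, and computes the multiple correlation for each
#' trait with two or more passing modules.
#'
#' @param mes sample x module eigengene matrix.
#' @param traits sample x trait residual matrix.
#' @param fdr q-value threshold (default 0.05).
#' @param frac,reps,alpha,min_support jack-knife parameters, see
#'   [jackknife_support()].
#' @param seed RNG seed for the jack-knife subsampling.
#' @return list with `table` (trait, module, r, n, p, q, support, pass) and
#'   `multiple` (per trait with >= 2 passing modules: R, modules).
#' @export
associate_modules <- function(mes, traits, fdr = 0.05, frac = 0.9,
                              reps = 100, alpha = 0.05, min_support = 70,
                              seed = NULL) {
  res <- correlate_me_traits(mes, traits)
  res$support <- NA_integer_
  res$pass <- FALSE
  sig <- which(res$q < fdr)
  for (i in sig) {
    jk <- jackknife_support(
      mes[, res$module[i]], as.matrix(traits)[, res$trait[i]],
      frac = frac, reps = reps, alpha = alpha, min_support = min_support,
      seed = if (is.null(seed)) NULL else substream_seed(seed, paste0(
        res$module[i], res$trait[i]))
    )
    res$support[i] <- jk$support
    res$pass[i] <- jk$pass
  }
  multiple <- list()
  for (k in unique(res$trait[res$pass])) {
    mods <- res$module[res$pass & res$trait == k]
    if (length(mods) >= 2) {
      mc <- multiple_correlation(as.matrix(traits)[, k],
                                 mes[, mods, drop = FALSE])
      multiple[[k]] <- list(R = mc$R, modules = mods, n = mc$n)
    }
  }
  list(table = res, multiple = multiple)
}

#' Association summary table with AVERAGE row
#'
#' One row per passing (trait, module) association, sorted by trait then
#' module, plus an AVERAGE row holding the mean of |r| rounded to 2 decimals
#' — the headline "average module-trait correlation" statistic.
#'
#' @param results an [associate_modules()] result, or a data.frame with at
#'   least `trait`, `module`, `r` (all rows are then treated as passing).
#' @return data.frame with columns `trait`, `module`, `r` and a final row
#'   `trait = "AVERAGE"` carrying the rounded mean absolute correlation; NULL
#'   when there are no passing associations.
#' @export
association_summary <- function(results) {
  tab <- if (is.data.frame(results)) {
    results
  } else {
    results$table[results$table$pass, , drop = FALSE]
  }
  if (nrow(tab) == 0) return(NULL)
  tab <- tab[order(tab$trait, tab$module), , drop = FALSE]
  out <- data.frame(trait = tab$trait, module = tab$module, r = tab$r,
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(trait = "AVERAGE", module = "",
                        r = round(mean(abs(out$r)), 2)))
}

#' Range spread
#'
#' Fold-difference statistic `(max - min) / min` used to express how variable
#' a trait is across individuals or environments.
#'
#' @param values positive numeric vector (minimum must be > 0).
#' @return Scalar fold difference.
#' @export
range_spread <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values", call. = FALSE)
  if (min(values) <= 0) {
    stop("range spread requires a strictly positive minimum", call. = FALSE)
  }
  (max(values) - min(values)) / min(values)
}
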