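#' Simulation configuration for synthetic expression and trait data
#'
#' Defines the generative model used by [simulate_dataset()]: negative-binomial
#' counts with library-size variation, planted co-expression modules driven by
#' latent per-sample factors, continuous physiological traits coupled to those
#' factors, and optional differential-expression effects between acclimation
#' temperatures and among populations.
#'
#' The default design mirrors a field study of three killifish populations
#' (a northern reference \code{N.Ref}, a thermally altered \code{TE}, and a
#' southern reference \code{S.Ref}) acclimated to 12 or 28 degrees C, with
#' heart-tissue sample sizes of 4/6/9 at 12 C and 4/8/10 at 28 C.
#'
#' Counts for gene \eqn{g} in sample \eqn{j} are drawn from a negative
#' binomial with mean \eqn{\mu_{gj}} and variance \eqn{\mu + \phi\mu^2}
#' (dispersion parameterization standard in RNA-seq), where
#' \deqn{\log \mu_{gj} = \log s_j + b_g + \lambda_g e_{m(g),j}
#'   + \delta^{acc}_g 1[acc_j = 28] + \delta^{pop}_g(pop_j),}
#' with \eqn{e_{m,j}} iid standard-normal module factors; background genes
#' omit the \eqn{\lambda} term. Traits are
#' \eqn{t_{kj} = \alpha_k + \gamma_k \cdot mass_j + \sum_m w_{km} e_{mj} +
#' \epsilon_{kj}}.
#'
#' @param n_genes total number of genes.
#' @param design data.frame with columns `population`
#'   (`"N.Ref"`, `"TE"`, `"S.Ref"`), `acclimation` (12 or 28) and
#'   `n_samples`.
#' @param module_sizes integer vector of planted module sizes; their sum must
#'   not exceed `n_genes` (the remainder are background genes).
#' @param loading_range interval for per-gene factor loadings \eqn{\lambda_g}.
#' @param baseline_logmean_range interval for baseline log-means \eqn{b_g}
#'   (natural log of expected counts at size factor 1).
#' @param dispersion single NB dispersion \eqn{\phi} or a range to sample
#'   per-gene dispersions from.
#' @param libsize_lognormal `c(meanlog, sdlog)` for per-sample size factors.
#' @param trait_names trait labels; defaults to the six physiological traits
#'   (whole-animal metabolic rate, critical thermal maximum, and four
#'   substrate-specific cardiac metabolic rates).
#' @param trait_weights traits x modules coupling matrix `w`; default couples
#'   trait k to module k at weight 0.75.
#' @param trait_noise_sd residual trait noise, recycled per trait.
#' @param mass_model list with `meanlog`/`sdlog` of the body-mass lognormal,
#'   per-trait `intercept` and `slope` on body mass, and
#'   `heart_mass_fraction`/`heart_mass_sd` for the heart-mass covariate.
#' @param de_effects list controlling planted differential expression:
#'   `acc_fraction` of genes get an acclimation effect with |log2FC| drawn
#'   from `acc_log2fc_range`, restricted to populations in `acc_populations`
#'   (default all three); `pop_fraction` of genes get population offsets
#'   (N.Ref baseline) with |log2FC| from `pop_log2fc_range`;
#'   `adaptive_fraction` of those are planted as the adaptive pattern
#'   (TE differs from both references, which are equal).
#' @param outliers list of `list(sample, trait_shift, expression_logshift)`
#'   applied after generation via [inject_outlier()].
#' @param seed integer seed; one pseudo-random stream per dataset split into
#'   named substreams (counts, traits, outliers).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       design = data.frame(
                         population = rep(c("N.Ref", "TE", "S.Ref"), 2),
                         acclimation = rep(c(12, 28), each = 3),
                         n_samples = c(4, 6, 9, 4, 8, 10)
                       ),
                       module_sizes = c(194, 147, 281, 168, 336),
                       loading_range = c(0.8, 1.2),
                       baseline_logmean_range = c(3, 7),
                       dispersion = c(0.1, 0.5),
                       libsize_lognormal = c(0, 0.25),
                       trait_names = c("WAM", "CT_max", "CaM_GLU", "CaM_FA",
                                       "CaM_LKA", "CaM_END"),
                       trait_weights = NULL,
                       trait_noise_sd = 1,
                       mass_model = list(meanlog = log(10), sdlog = 0.3,
                                         intercept = 0, slope = 0.1,
                                         heart_mass_fraction = 0.005,
                                         heart_mass_sd = 0.1),
                       de_effects = list(acc_fraction = 0,
                                         acc_log2fc_range = c(1, 2),
                                         acc_populations = NULL,
                                         pop_fraction = 0,
                                         pop_log2fc_range = c(1, 2),
                                         adaptive_fraction = 0),
                       outliers = list(),
                       seed = 1) {
  n_modules <- length(module_sizes)
  if (is.null(trait_weights)) {
    trait_weights <- matrix(0, length(trait_names), n_modules,
                            dimnames = list(trait_names, NULL))
    for (k in seq_len(min(length(trait_names), n_modules))) {
      trait_weights[k, k] <- 0.75
    }
  }
  trait_weights <- as.matrix(trait_weights)
  rownames(trait_weights) <- trait_names
  de_defaults <- list(acc_fraction = 0, acc_log2fc_range = c(1, 2),
                      acc_populations = NULL, pop_fraction = 0,
                      pop_log2fc_range = c(1, 2), adaptive_fraction = 0)
  de_effects <- utils::modifyList(de_defaults, de_effects)
  cfg <- structure(list(
    n_genes = n_genes, design = design, module_sizes = module_sizes,
    loading_range = loading_range,
    baseline_logmean_range = baseline_logmean_range,
    dispersion = dispersion, libsize_lognormal = libsize_lognormal,
    trait_names = trait_names, trait_weights = trait_weights,
    trait_noise_sd = rep_len(trait_noise_sd, length(trait_names)),
    mass_model = mass_model, de_effects = de_effects,
    outliers = outliers, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1 || cfg$n_genes != round(cfg$n_genes)) {
    stop("n_genes must be a positive integer", call. = FALSE)
  }
  if (any(cfg$module_sizes < 1) ||
      any(cfg$module_sizes != round(cfg$module_sizes))) {
    stop("module sizes must be positive integers", call. = FALSE)
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop("module sizes sum exceeds n_genes", call. = FALSE)
  }
  req <- c("population", "acclimation", "n_samples")
  if (!all(req %in% names(cfg$design))) {
    stop("design needs columns population, acclimation, n_samples",
         call. = FALSE)
  }
  if (any(cfg$design$n_samples <= 0) ||
      any(cfg$design$n_samples != round(cfg$design$n_samples))) {
    stop("all design sample counts must be positive integers", call. = FALSE)
  }
  if (any(cfg$dispersion <= 0)) {
    stop("NB dispersion must be positive", call. = FALSE)
  }
  if (nrow(cfg$trait_weights) != length(cfg$trait_names) ||
      ncol(cfg$trait_weights) != length(cfg$module_sizes)) {
    stop("trait_weights must be traits x modules", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a synthetic expression/trait dataset with recorded ground truth
#'
#' Draws module factors, gene parameters, negative-binomial counts,
#' body/heart mass and traits under the generative model described in
#' [sim_config()], then applies any configured outlier injections. The same
#' configuration always regenerates an identical dataset.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `synthetic_dataset`: a list with `counts`
#'   (integer gene x sample matrix), `samples` (population, acclimation,
#'   body/heart mass), `traits` (samples x traits), and `truth` (planted
#'   module labels, latent factor matrix, trait weights, DE effect sizes on
#'   the log2 scale, outlier flags).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  n_samples <- sum(config$design$n_samples)
  n_genes <- config$n_genes
  n_modules <- length(config$module_sizes)

  population <- rep(config$design$population, config$design$n_samples)
  acclimation <- rep(config$design$acclimation, config$design$n_samples)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  module <- integer(n_genes)
  if (n_modules > 0) {
    module[seq_len(sum(config$module_sizes))] <-
      rep(seq_len(n_modules), config$module_sizes)
  }

  de <- config$de_effects
  counts <- with_seed(substream_seed(config$seed, "counts"), {
    b <- stats::runif(n_genes, config$baseline_logmean_range[1],
                      config$baseline_logmean_range[2])
    lambda <- stats::runif(n_genes, config$loading_range[1],
                           config$loading_range[2])
    phi <- if (length(config$dispersion) == 1) {
      rep(config$dispersion, n_genes)
    } else {
      stats::runif(n_genes, min(config$dispersion), max(config$dispersion))
    }
    s <- stats::rlnorm(n_samples, config$libsize_lognormal[1],
                       config$libsize_lognormal[2])
    e <- matrix(stats::rnorm(max(n_modules, 1) * n_samples),
                nrow = max(n_modules, 1),
                dimnames = list(NULL, sample_ids))
    if (n_modules == 0) e <- e[0, , drop = FALSE]

    # planted acclimation effects (log2 scale), optionally restricted to a
    # subset of populations so per-population DE recovery can be exercised
    de_acc <- numeric(n_genes)
    n_acc <- round(de$acc_fraction * n_genes)
    if (n_acc > 0) {
      idx <- sample.int(n_genes, n_acc)
      de_acc[idx] <- sample(c(-1, 1), n_acc, replace = TRUE) *
        stats::runif(n_acc, de$acc_log2fc_range[1], de$acc_log2fc_range[2])
    }
    acc_pops <- de$acc_populations %||% c("N.Ref", "TE", "S.Ref")

    # planted population offsets, N.Ref baseline (columns TE, S.Ref)
    de_pop <- matrix(0, n_genes, 2, dimnames = list(gene_ids,
                                                    c("TE", "S.Ref")))
    n_pop <- round(de$pop_fraction * n_genes)
    if (n_pop > 0) {
      idx <- sample.int(n_genes, n_pop)
      mag <- function(n) sample(c(-1, 1), n, replace = TRUE) *
        stats::runif(n, de$pop_log2fc_range[1], de$pop_log2fc_range[2])
      de_pop[idx, "TE"] <- mag(n_pop)
      de_pop[idx, "S.Ref"] <- mag(n_pop)
      n_adapt <- round(de$adaptive_fraction * n_pop)
      if (n_adapt > 0) {
        # adaptive pattern: TE differs from both references, refs equal
        de_pop[idx[seq_len(n_adapt)], "S.Ref"] <- 0
      }
    }

    acc_on <- (acclimation == 28) & (population %in% acc_pops)
    log_mu <- matrix(b, n_genes, n_samples) +
      matrix(log(s), n_genes, n_samples, byrow = TRUE)
    in_mod <- module > 0
    if (any(in_mod)) {
      log_mu[in_mod, ] <- log_mu[in_mod, ] +
        lambda[in_mod] * e[module[in_mod], , drop = FALSE]
    }
    log_mu <- log_mu + log(2) * (de_acc %o% as.numeric(acc_on))
    pop_idx <- match(population, c("TE", "S.Ref"))
    for (j in which(!is.na(pop_idx))) {
      log_mu[, j] <- log_mu[, j] + log(2) * de_pop[, pop_idx[j]]
    }

    mu <- exp(log_mu)
    y <- stats::rnbinom(length(mu), mu = mu, size = 1 / rep(phi, n_samples))
    cm <- matrix(as.integer(y), n_genes, n_samples,
                 dimnames = list(gene_ids, sample_ids))
    list(counts = cm, b = b, lambda = lambda, phi = phi, s = s, e = e,
         de_acc = de_acc, de_pop = de_pop, acc_populations = acc_pops)
  })

  traits <- with_seed(substream_seed(config$seed, "traits"), {
    mm <- config$mass_model
    mass <- stats::rlnorm(n_samples, mm$meanlog, mm$sdlog)
    heart_mass <- mm$heart_mass_fraction * mass *
      exp(stats::rnorm(n_samples, 0, mm$heart_mass_sd))
    k <- length(config$trait_names)
    eps <- matrix(stats::rnorm(n_samples * k, 0,
                               rep(config$trait_noise_sd, each = n_samples)),
                  n_samples, k)
    tt <- matrix(mm$intercept, n_samples, k) + mm$slope * mass +
      t(config$trait_weights %*% counts$e) + eps
    dimnames(tt) <- list(sample_ids, config$trait_names)
    list(traits = tt, mass = mass, heart_mass = heart_mass)
  })

  samples <- data.frame(
    sample_id = sample_ids, population = population,
    acclimation = acclimation, body_mass = traits$mass,
    heart_mass = traits$heart_mass, stringsAsFactors = FALSE
  )

  ds <- structure(list(
    counts = counts$counts,
    samples = samples,
    traits = traits$traits,
    truth = list(
      module = stats::setNames(module, gene_ids),
      factors = counts$e,
      trait_weights = config$trait_weights,
      baseline_logmean = counts$b,
      loading = counts$lambda,
      dispersion = counts$phi,
      size_factor = counts$s,
      de_acc_log2fc = stats::setNames(counts$de_acc, gene_ids),
      de_acc_populations = counts$acc_populations,
      de_pop_log2fc = counts$de_pop,
      outliers = integer(0)
    ),
    config = config
  ), class = "synthetic_dataset")

  for (o in config$outliers) {
    ds <- inject_outlier(ds, o$sample,
                         o$trait_shift %||% 0,
                         o$expression_logshift %||% 0)
  }
  ds
}

#' Inject an outlier sample into a synthetic dataset
#'
#' Additively shifts one sample's trait values and rescales its counts by
#' `exp(expression_logshift)` (rounded back to integers), marking the sample
#' in the ground truth. Used to exercise the jack-knife robustness screen:
#' a single extreme sample can create a spurious full-sample module-trait
#' correlation that subsampling should reject.
#'
#' @param dataset a `synthetic_dataset`.
#' @param sample_index integer index of the sample to perturb.
#' @param trait_shift scalar added to every trait, or a vector (recycled
#'   across traits, or named by trait).
#' @param expression_logshift natural-log fold change applied to the sample's
#'   counts.
#' @return The modified dataset (a copy).
#' @export
inject_outlier <- function(dataset, sample_index, trait_shift = 0,
                           expression_logshift = 0) {
  n <- ncol(dataset$counts)
  if (length(sample_index) != 1 || sample_index < 1 || sample_index > n ||
      sample_index != round(sample_index)) {
    stop("sample_index out of range 1..", n, call. = FALSE)
  }
  if (!is.null(names(trait_shift))) {
    shift <- numeric(ncol(dataset$traits))
    names(shift) <- colnames(dataset$traits)
    shift[names(trait_shift)] <- trait_shift
  } else {
    shift <- rep_len(trait_shift, ncol(dataset$traits))
  }
  dataset$traits[sample_index, ] <- dataset$traits[sample_index, ] + shift
  dataset$counts[, sample_index] <- as.integer(round(
    dataset$counts[, sample_index] * exp(expression_logshift)
  ))
  dataset$truth$outliers <- sort(unique(c(dataset$truth$outliers,
                                          as.integer(sample_index))))
  dataset
}

#' Write a synthetic dataset to plain-text files
#'
#' Counts as gene x sample TSV (first column the gene id; optionally also
#' matrix-market MTX with row/column name sidecars), samples and traits as
#' TSV, and the ground truth as JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @param mtx also write counts as sparse matrix-market (needs the Matrix
#'   package).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, mtx = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    traits = file.path(dir, "traits.tsv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.table(
    data.frame(gene_id = rownames(dataset$counts), dataset$counts,
               check.names = FALSE),
    paths["counts"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(dataset$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(dataset$traits), dataset$traits,
               check.names = FALSE),
    paths["traits"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- dataset$truth
  truth$factors <- unname(as.data.frame(t(truth$factors)))
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  if (mtx) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("Matrix package required for MTX output", call. = FALSE)
    }
    mtx_path <- file.path(dir, "counts.mtx")
    Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE), mtx_path)
    writeLines(rownames(dataset$counts), file.path(dir, "counts.mtx.rownames"))
    writeLines(colnames(dataset$counts), file.path(dir, "counts.mtx.colnames"))
    paths <- c(paths, mtx = mtx_path)
  }
  invisible(paths)
}
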