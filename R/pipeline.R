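# End-to-end orchestration: simulate/load -> preprocess -> differential
# expression -> network -> trait association -> enrichment, with a manifest
# recording seeds, thresholds and per-stage accounting.

#' Pipeline configuration
#'
#' Collects every stage's parameters with the analysis defaults: the
#' 30-count/10%-of-samples gene filter, read-depth sample filter, unsigned
#' network at the supplied soft-threshold power, minimum module size 30,
#' eigengene merge threshold 0.75, 90%/100-rep/support-70 jack-knife, and FDR
#' 0.05 throughout.
#'
#' @param simulate NULL, or a [sim_config()] used to generate the input
#'   dataset in place of files.
#' @param counts,samples,traits input TSV paths (ignored when `simulate` is
#'   given). Counts: first column gene id; samples: `sample_id`,
#'   `population`, `acclimation`, `body_mass`, `heart_mass`; traits: first
#'   column sample id.
#' @param annotation,pathways optional annotation file paths for
#'   [load_gene_sets()].
#' @param out_dir output directory for stage artifacts.
#' @param min_count,min_fraction gene filter, see [filter_genes()].
#' @param min_total_reads sample filter threshold (default 0 = keep all).
#' @param beta soft-threshold power (default 5).
#' @param network_type `"unsigned"` or `"signed"`.
#' @param min_module_size,merge_threshold module detection parameters.
#' @param fdr significance threshold used by every testing stage.
#' @param jackknife list(frac, reps, alpha, min_support).
#' @param covariates named list mapping trait name to the mass column used
#'   for residuals; traits not listed use `default_covariate`. The preset
#'   `covariates = "body_mass"` corrects every trait by body mass.
#' @param default_covariate fallback mass column (default `"body_mass"`;
#'   traits whose name starts with `CaM` default to `"heart_mass"`).
#' @param run_de run the differential-expression stage (slowest stage;
#'   default TRUE).
#' @param seed global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, counts = NULL, samples = NULL,
                            traits = NULL, annotation = NULL,
                            pathways = NULL, out_dir = tempfile("coexphys_"),
                            min_count = 30, min_fraction = 0.10,
                            min_total_reads = 0, beta = 5,
                            network_type = "unsigned", min_module_size = 30,
                            merge_threshold = 0.75, fdr = 0.05,
                            jackknife = list(frac = 0.9, reps = 100,
                                             alpha = 0.05, min_support = 70),
                            covariates = list(),
                            default_covariate = "body_mass",
                            run_de = TRUE, seed = 1) {
  jk <- utils::modifyList(list(frac = 0.9, reps = 100, alpha = 0.05,
                               min_support = 70), jackknife)
  structure(list(simulate = simulate, counts = counts, samples = samples,
                 traits = traits, annotation = annotation,
                 pathways = pathways, out_dir = out_dir,
                 min_count = min_count, min_fraction = min_fraction,
                 min_total_reads = min_total_reads, beta = beta,
                 network_type = network_type,
                 min_module_size = min_module_size,
                 merge_threshold = merge_threshold, fdr = fdr,
                 jackknife = jk, covariates = covariates,
                 default_covariate = default_covariate, run_de = run_de,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Thin wrapper turning a YAML document of [pipeline_config()] keys into a
#' config object (requires the yaml package).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (!is.null(sim$design)) sim$design <- as.data.frame(sim$design)
    if (!is.null(sim$trait_weights)) {
      sim$trait_weights <- do.call(rbind, sim$trait_weights)
    }
    cfg$simulate <- do.call(sim_config, sim)
  }
  do.call(pipeline_config, cfg)
}

read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

trait_covariate <- function(trait, config) {
  if (identical(config$covariates, "body_mass")) return("body_mass")
  config$covariates[[trait]] %||%
    if (startsWith(trait, "CaM")) "heart_mass" else config$default_covariate
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess -> differential expression ->
#' network -> trait association -> enrichment, writing TSV/JSON artifacts and
#' a run manifest to `config$out_dir`. Any stage failure stops with the stage
#' name. Two runs with the same configuration produce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all stage results (`dataset`,
#'   `preprocess`, `diffexp`, `network`, `association`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- input ---------------------------------------------------------------
  ds <- stage("input", {
    if (!is.null(config$simulate)) {
      simulate_dataset(config$simulate)
    } else {
      for (p in c(config$counts, config$samples, config$traits)) {
        if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
      }
      counts <- read_counts_tsv(config$counts)
      samples <- utils::read.delim(config$samples,
                                   stringsAsFactors = FALSE)
      tdf <- utils::read.delim(config$traits, check.names = FALSE,
                               stringsAsFactors = FALSE)
      traits <- as.matrix(tdf[, -1, drop = FALSE])
      rownames(traits) <- tdf[[1]]
      list(counts = counts, samples = samples, traits = traits)
    }
  })

  # -- preprocess ----------------------------------------------------------
  pre <- stage("preprocess", {
    keep_samples <- filter_samples(ds$counts, config$min_total_reads)
    counts <- ds$counts[, keep_samples, drop = FALSE]
    keep_genes <- filter_genes(counts, config$min_count, config$min_fraction)
    counts <- counts[keep_genes, , drop = FALSE]
    norm <- normalize_counts(counts)
    samples <- ds$samples[match(keep_samples, ds$samples$sample_id), ]
    traits <- ds$traits[keep_samples, , drop = FALSE]
    cvs <- lapply(split(seq_len(ncol(counts)), samples$acclimation),
                  function(idx) cv_profile(norm, idx,
                                           label = samples$acclimation[idx[1]]))
    list(counts = counts, norm = norm, samples = samples, traits = traits,
         cv = cvs,
         n_genes = c(before = nrow(ds$counts), after = nrow(counts)),
         n_samples = c(before = ncol(ds$counts), after = ncol(counts)))
  })

  # -- differential expression ----------------------------------------------
  de <- if (config$run_de) stage("diffexp", {
    acc <- acclimation_de_per_population(pre$counts, pre$samples,
                                         pre$norm$size_factors, config$fdr)
    pop <- lapply(split(seq_len(ncol(pre$counts)), pre$samples$acclimation),
                  function(idx) {
                    population_de_within_temperature(
                      pre$counts[, idx, drop = FALSE],
                      pre$samples[idx, , drop = FALSE], fdr = config$fdr)
                  })
    adaptive <- lapply(pop, function(x) classify_adaptive(x$flags))
    venn <- overlap_counts(acc$deg_sets)
    list(acclimation = acc, population = pop, adaptive = adaptive,
         venn = venn)
  }) else NULL

  # -- network --------------------------------------------------------------
  net <- stage("network", {
    detect_modules(pre$norm$log_values, config$beta, config$network_type,
                   config$min_module_size, config$merge_threshold)
  })

  # -- trait association ----------------------------------------------------
  assoc <- stage("trait_assoc", {
    strata <- if (is.null(net$mes)) {
      list()
    } else {
      split(seq_len(nrow(pre$samples)), pre$samples$acclimation)
    }
    out <- list()
    for (temp in names(strata)) {
      idx <- strata[[temp]]
      if (length(idx) < 10) next
      resid <- sapply(colnames(pre$traits), function(k) {
        mass <- pre$samples[[trait_covariate(k, config)]][idx]
        mass_residuals(pre$traits[idx, k], mass)
      })
      rownames(resid) <- rownames(pre$traits)[idx]
      jk <- config$jackknife
      res <- associate_modules(
        net$mes[idx, , drop = FALSE], resid, fdr = config$fdr,
        frac = jk$frac, reps = jk$reps, alpha = jk$alpha,
        min_support = jk$min_support,
        seed = substream_seed(config$seed, paste0("jackknife", temp))
      )
      res$table$temperature <- temp
      out[[temp]] <- res
    }
    if (length(out) == 0) NULL else out
  })

  # -- enrichment -----------------------------------------------------------
  enr <- stage("enrichment", {
    if (is.null(config$annotation) || is.null(net$mes)) {
      NULL
    } else {
      ann <- load_gene_sets(config$annotation, config$pathways)
      universe <- rownames(pre$counts)
      mods <- sort(setdiff(unique(net$labels), 0))
      out <- lapply(mods, function(m) {
        genes <- names(net$labels)[net$labels == m]
        tab <- enrich_module(genes, ann, universe, config$fdr)
        tp <- top_pathway(tab$term[tab$significant], ann$pathways)
        list(module = m, table = tab, top_pathway = tp)
      })
      names(out) <- paste0("ME", mods)
      out
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("coexphys")),
    seed = config$seed,
    thresholds = config[c("min_count", "min_fraction", "min_total_reads",
                          "beta", "network_type", "min_module_size",
                          "merge_threshold", "fdr")],
    jackknife = config$jackknife,
    genes = pre$n_genes, samples = pre$n_samples,
    n_modules = length(setdiff(unique(net$labels), 0)),
    input_checksum = if (is.null(config$simulate)) {
      vapply(c(config$counts, config$samples, config$traits),
             function(p) unname(tools::md5sum(p)), character(1))
    } else {
      "simulated"
    }
  )

  result <- list(dataset = ds, preprocess = pre, diffexp = de, network = net,
                 association = assoc, enrichment = enr, manifest = manifest)
  stage("write", write_artifacts(result, config))
  invisible(result)
}

write_artifacts <- function(result, config) {
  dir <- config$out_dir
  wt <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  net <- result$network
  if (!is.null(net$labels)) {
    wt(data.frame(gene_id = names(net$labels), module = net$labels),
       "module_labels.tsv")
  }
  if (!is.null(net$mes)) {
    wt(data.frame(sample_id = rownames(net$mes), net$mes,
                  check.names = FALSE), "module_eigengenes.tsv")
    wt(net$hubs, "module_hubs.tsv")
  }
  if (!is.null(result$association)) {
    assoc <- do.call(rbind, lapply(result$association, `[[`, "table"))
    wt(assoc, "associations.tsv")
    summaries <- lapply(result$association, association_summary)
    summaries <- summaries[!vapply(summaries, is.null, logical(1))]
    if (length(summaries) > 0) {
      wt(do.call(rbind, Map(function(s, temp) cbind(temperature = temp, s),
                            summaries, names(summaries))),
         "association_summary.tsv")
    }
    jsonlite::write_json(lapply(result$association, `[[`, "multiple"),
                         file.path(dir, "multiple_correlations.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(result$diffexp)) {
    wt(result$diffexp$acclimation$table, "de_acclimation.tsv")
    jsonlite::write_json(
      list(regions = as.list(result$diffexp$venn$regions),
           union_size = result$diffexp$venn$union_size,
           shared_fraction = result$diffexp$venn$shared_fraction),
      file.path(dir, "venn_acclimation.json"), digits = NA,
      auto_unbox = TRUE)
  }
  if (!is.null(result$enrichment)) {
    enr <- do.call(rbind, lapply(result$enrichment, function(e) {
      if (nrow(e$table) == 0) return(NULL)
      cbind(module = e$module, e$table)
    }))
    if (!is.null(enr)) wt(enr, "enrichment.tsv")
    wt(do.call(rbind, lapply(result$enrichment, function(e) {
      data.frame(module = e$module, pathway = e$top_pathway$pathway,
                 n_terms = e$top_pathway$count, tie = e$top_pathway$tie)
    })), "top_pathways.tsv")
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Render a plain-text report from pipeline artifacts
#'
#' Summarizes a completed [run_pipeline()] output directory: module table
#' (size, hub, hub MM, positive-MM fraction), association table with its
#' AVERAGE row, multiple correlations, top enriched pathways and
#' differential-expression Venn counts. Missing artifacts are reported as
#' gaps rather than errors.
#'
#' @param out_dir pipeline output directory.
#' @return Character vector of report lines (also printed), invisibly.
#' @export
render_report <- function(out_dir) {
  lines <- c("coexphys pipeline report", strrep("=", 24))
  rd <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) {
      utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      NULL
    }
  }
  hubs <- rd("module_hubs.tsv")
  if (!is.null(hubs)) {
    lines <- c(lines, "", "Modules:",
               utils::capture.output(print(hubs, row.names = FALSE)))
  } else {
    lines <- c(lines, "", "Modules: artifact missing")
  }
  summ <- rd("association_summary.tsv")
  if (!is.null(summ)) {
    lines <- c(lines, "", "Module-trait associations (passing):",
               utils::capture.output(print(summ, row.names = FALSE)))
  } else {
    lines <- c(lines, "",
               "Module-trait associations: none passing (AVERAGE omitted)")
  }
  mc <- file.path(out_dir, "multiple_correlations.json")
  if (file.exists(mc)) {
    m <- jsonlite::read_json(mc)
    for (temp in names(m)) {
      for (k in names(m[[temp]])) {
        lines <- c(lines, sprintf(
          "Multiple correlation at %s C, %s: R = %.3f (%s)", temp, k,
          m[[temp]][[k]]$R,
          paste(unlist(m[[temp]][[k]]$modules), collapse = " + ")))
      }
    }
  }
  venn <- file.path(out_dir, "venn_acclimation.json")
  if (file.exists(venn)) {
    v <- jsonlite::read_json(venn)
    lines <- c(lines, "", sprintf(
      "Acclimation DEG overlap: union %d, shared fraction %.3f",
      v$union_size, v$shared_fraction))
  }
  tp <- rd("top_pathways.tsv")
  if (!is.null(tp)) {
    lines <- c(lines, "", "Top pathways per module:",
               utils::capture.output(print(tp, row.names = FALSE)))
  }
  writeLines(lines)
  invisible(lines)
}
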