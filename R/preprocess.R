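#' Median-of-ratios size factors
#'
#' For every gene with strictly positive counts in all samples, each sample's
#' count is divided by the gene's geometric mean across samples; the sample's
#' size factor is the median of those ratios. This is the median-ratio
#' library-size normalization standard for RNA-seq count matrices.
#'
#' @param counts gene x sample integer matrix with dimnames.
#' @return Named positive numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  stop_if_not_count_matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has positive counts in every sample; ",
         "pre-filter low-count genes or samples first", call. = FALSE)
  }
  log_ratios <- log(counts[all_pos, , drop = FALSE]) -
    rowMeans(log(counts[all_pos, , drop = FALSE]))
  s <- exp(apply(log_ratios, 2, stats::median))
  stats::setNames(s, colnames(counts))
}

#' Normalize a count matrix by size factors
#'
#' Divides each sample's counts by its median-of-ratios size factor and also
#' returns `log2(normalized + 1)`, the transform used downstream for PCA and
#' network construction. Multiplying column j of `values` by `size_factors[j]`
#' reconstructs the raw counts exactly.
#'
#' @param counts gene x sample integer matrix.
#' @param sf optional precomputed size factors; computed from `counts` when
#'   missing.
#' @return An object of class `normalized_matrix`: list with `values`,
#'   `log_values` and `size_factors`.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  stop_if_not_count_matrix(counts)
  sf <- sf %||% size_factors(counts)
  if (any(sf <= 0)) stop("size factors must be positive", call. = FALSE)
  values <- sweep(counts, 2, sf, "/")
  structure(list(values = values,
                 log_values = log2(values + 1),
                 size_factors = sf),
            class = "normalized_matrix")
}

#' Filter genes by a minimum count in a minimum fraction of samples
#'
#' Keeps a gene when at least `ceiling(min_fraction * n_samples)` samples have
#' at least `min_count` counts. Defaults implement the "at least 30 counts in
#' 10 percent of individuals" expression filter.
#'
#' @param counts gene x sample matrix.
#' @param min_count count threshold per sample (default 30).
#' @param min_fraction fraction of samples required to reach it (default 0.1).
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(counts, min_count = 30, min_fraction = 0.10) {
  stop_if_not_count_matrix(counts)
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  rownames(counts)[keep]
}

#' Filter samples by minimum total counts
#'
#' Keeps samples whose column sum meets a read-depth threshold (e.g. 1.5
#' million reads for hearts, 1 million for brains). Equality is retained.
#'
#' @param counts gene x sample matrix.
#' @param min_total_reads minimum column sum.
#' @return Character vector of retained sample ids.
#' @export
filter_samples <- function(counts, min_total_reads) {
  stop_if_not_count_matrix(counts)
  if (min_total_reads < 0) stop("min_total_reads must be >= 0", call. = FALSE)
  keep <- colSums(counts) >= min_total_reads
  if (!any(keep)) {
    stop("all samples fall below the read-depth threshold", call. = FALSE)
  }
  colnames(counts)[keep]
}

#' Per-gene coefficient of variation profile
#'
#' CV = 100 * sd / mean per gene over a sample group, on median-ratio
#' normalized values (sample standard deviation, n - 1 denominator). Genes
#' with mean zero get `NA` CV and an `undefined` flag rather than being
#' dropped.
#'
#' @param normalized a [normalize_counts()] object (or a plain numeric
#'   matrix of normalized values).
#' @param group character or integer subset of samples; default all.
#' @param label group label stored in the profile.
#' @param log_scale compute CV on `log2(normalized + 1)` instead of the
#'   normalized scale.
#' @return data.frame with `gene_id`, `cv` (percent), `undefined`, `group`.
#' @export
cv_profile <- function(normalized, group = NULL, label = "all",
                       log_scale = FALSE) {
  values <- if (inherits(normalized, "normalized_matrix")) {
    if (log_scale) normalized$log_values else normalized$values
  } else {
    if (log_scale) log2(normalized + 1) else normalized
  }
  if (!is.null(group)) values <- values[, group, drop = FALSE]
  if (ncol(values) < 2) stop("need at least 2 samples in group", call. = FALSE)
  m <- rowMeans(values)
  sd_g <- apply(values, 1, stats::sd)
  cv <- ifelse(m == 0, NA_real_, 100 * sd_g / m)
  data.frame(gene_id = rownames(values), cv = cv, undefined = m == 0,
             group = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two CV profiles
#'
#' Tests whether average per-gene coefficient of variation differs between two
#' sample groups over the genes defined in both. The default is a paired
#' t-test on per-gene CV differences (the same genes are measured in both
#' groups); Welch's unpaired test is available by flag.
#'
#' @param profile_a,profile_b [cv_profile()] results over the same gene set.
#' @param paired paired t-test (default) or Welch two-sample.
#' @return list with `t`, `p`, `df`, `mean_diff` (a minus b), `n_genes`,
#'   `method`.
#' @export
compare_cv <- function(profile_a, profile_b, paired = TRUE) {
  shared <- merge(profile_a[!profile_a$undefined & !is.na(profile_a$cv),
                            c("gene_id", "cv")],
                  profile_b[!profile_b$undefined & !is.na(profile_b$cv),
                            c("gene_id", "cv")],
                  by = "gene_id")
  if (nrow(shared) < 3) {
    stop("need at least 3 genes with defined CV in both groups",
         call. = FALSE)
  }
  d <- shared$cv.x - shared$cv.y
  if (paired && stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-10) {
      # identical profiles: no difference at all
      return(list(t = 0, p = 1, df = nrow(shared) - 1, mean_diff = 0,
                  n_genes = nrow(shared), method = "paired t-test"))
    }
    stop("paired CV differences have zero variance; t statistic undefined",
         call. = FALSE)
  }
  ht <- if (paired) {
    stats::t.test(shared$cv.x, shared$cv.y, paired = TRUE)
  } else {
    stats::t.test(shared$cv.x, shared$cv.y, var.equal = FALSE)
  }
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d),
       n_genes = nrow(shared),
       method = if (paired) "paired t-test" else "Welch t-test")
}

#' PCA screen of samples on the most variable genes
#'
#' Selects the `top_n` most variable genes on the log scale, centers genes
#' (no scaling), and computes sample scores by singular value decomposition.
#' A sample is flagged as an outlier when its binary label (e.g. tissue)
#' disagrees with a two-group partition of the PC1 scores obtained by
#' one-dimensional 2-means: each cluster is assigned the majority label of
#' its samples, and members carrying the other label are flagged.
#'
#' @param normalized a [normalize_counts()] object or a log-expression
#'   matrix (genes x samples).
#' @param labels binary per-sample labels (factor/character), used for the
#'   outlier rule; `NULL` disables flagging.
#' @param top_n number of most-variable genes used (default 500, capped at
#'   the number of genes available).
#' @param n_components number of PCs returned (default 4).
#' @return list with `scores` (samples x PCs), `variance_explained`
#'   (proportion per returned PC), `outliers` (logical per sample),
#'   `genes_used`.
#' @export
pca_screen <- function(normalized, labels = NULL, top_n = 500,
                       n_components = 4) {
  x <- if (inherits(normalized, "normalized_matrix")) {
    normalized$log_values
  } else {
    normalized
  }
  if (ncol(x) < 3) stop("PCA screen needs at least 3 samples", call. = FALSE)
  if (top_n > nrow(x)) {
    stop("top_n exceeds the number of genes (", nrow(x), ")", call. = FALSE)
  }
  v <- apply(x, 1, stats::var)
  genes <- rownames(x)[order(v, decreasing = TRUE)[seq_len(top_n)]]
  xc <- x[genes, , drop = FALSE] - rowMeans(x[genes, , drop = FALSE])
  sv <- svd(t(xc))
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(k)))
  var_expl <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]

  outliers <- rep(FALSE, ncol(x))
  names(outliers) <- colnames(x)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(x)) {
      stop("labels must have one entry per sample", call. = FALSE)
    }
    pc1 <- scores[, 1]
    # deterministic 1-d 2-means: seed centers at the extremes
    km <- stats::kmeans(pc1, centers = c(min(pc1), max(pc1)))
    cl <- km$cluster
    for (g in unique(cl)) {
      in_g <- cl == g
      tab <- sort(table(labels[in_g]), decreasing = TRUE)
      majority <- names(tab)[1]
      outliers[in_g & labels != majority] <- TRUE
    }
  }
  list(scores = scores, variance_explained = var_expl, outliers = outliers,
       genes_used = genes)
}
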