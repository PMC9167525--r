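# Weighted co-expression network construction and module detection.
#
# Expression input throughout is log2(normalized + 1), genes in rows.

#' Correlation-power adjacency matrix
#'
#' Unsigned: `|cor(x_i, x_j)|^beta`; signed: `((1 + cor)/2)^beta`. The
#' diagonal is set to 1. Soft thresholding with beta >= 1 suppresses weak
#' correlations so that the connectivity distribution approximates a
#' scale-free topology.
#'
#' @param expr gene x sample log-expression matrix.
#' @param beta soft-threshold power (>= 1).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return Symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
adjacency_matrix <- function(expr, beta, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  r <- stats::cor(t(expr))
  a <- if (type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' For i != j, `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{j != i} a_ij`;
#' `TOM_ii = 1`. High TOM means two genes share neighbours as well as being
#' directly connected.
#'
#' @param a symmetric adjacency matrix with values in `[0, 1]`.
#' @return Symmetric TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(a < 0) || any(a > 1)) {
    stop("adjacency values must lie in [0, 1]", call. = FALSE)
  }
  diag(a) <- 1
  k <- rowSums(a) - 1
  # l_ij over u != i, j: subtract the u = i and u = j terms (diag(a) = 1)
  l <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Scale-free topology scan over candidate soft-threshold powers
#'
#' For each power, builds the adjacency, computes connectivity k, bins k into
#' `n_bins` equal-width bins, and regresses log10(bin frequency) on
#' log10(mean bin connectivity). The fit R^2 is reported with a negative sign
#' when the slope is positive (scale-free topology requires a decreasing
#' relationship). Degenerate connectivity (all equal) yields `NA` R^2 with a
#' flag.
#'
#' @param expr gene x sample log-expression matrix (>= 20 genes).
#' @param powers candidate powers (default 1:10).
#' @param type network type, see [adjacency_matrix()].
#' @param n_bins connectivity bins (default 10).
#' @return data.frame: `power`, `r_squared` (signed), `slope`,
#'   `mean_connectivity`, `degenerate`.
#' @export
soft_threshold_scan <- function(expr, powers = 1:10,
                                type = c("unsigned", "signed"),
                                n_bins = 10) {
  type <- match.arg(type)
  if (nrow(expr) < 20) {
    stop("soft-threshold scan needs at least 20 genes", call. = FALSE)
  }
  out <- lapply(powers, function(p) {
    a <- adjacency_matrix(expr, p, type)
    k <- rowSums(a) - 1
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = p, r_squared = fit$r_squared, slope = fit$slope,
               mean_connectivity = mean(k), degenerate = fit$degenerate)
  })
  do.call(rbind, out)
}

scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) == 1) {
    return(list(r_squared = NA_real_, slope = NA_real_, degenerate = TRUE))
  }
  # equal-width connectivity bins; frequency = share of genes per bin
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- as.numeric(table(bin)) / length(k)
  ok <- !is.na(mean_k) & mean_k > 0 & freq > 0
  if (sum(ok) < 3) {
    return(list(r_squared = NA_real_, slope = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(r_squared = if (!is.na(slope) && slope > 0) -r2 else r2,
       slope = slope, degenerate = FALSE)
}

#' Hierarchical clustering with dynamic tree cutting
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity followed
#' by a tree-variant dynamic cut. Each (sub)dendrogram is scanned over
#' candidate cut heights (midpoints between consecutive joining heights); the
#' accepted cut is the highest one producing the largest number of branches
#' with at least `min_module_size` genes. A multi-branch split is accepted
#' only when the branches are genuinely separated — mean between-branch
#' dissimilarity exceeding mean within-branch dissimilarity by `min_gap` — so
#' homogeneous modules are never fragmented; loosely attached genes
#' (background chaff joining a branch near its top) are stripped under the
#' same separation rule. Accepted branches are recursively re-clustered and
#' re-cut; genes falling off as fragments smaller than `min_module_size` are
#' assigned label 0 (unassigned).
#'
#' @param diss symmetric dissimilarity matrix (1 - TOM).
#' @param min_module_size smallest retained module (default 30).
#' @param min_gap minimum between-minus-within mean-dissimilarity separation
#'   for a split (or chaff strip) to be accepted (default 0.1 on the TOM
#'   dissimilarity scale).
#' @return Named integer vector of module labels (0 = unassigned), label 1
#'   the largest module.
#' @export
cluster_and_cut <- function(diss, min_module_size = 30, min_gap = 0.1) {
  n <- nrow(diss)
  ids <- rownames(diss) %||% sprintf("g%0*d", nchar(n), seq_len(n))
  # canonical gene order so results do not depend on input row order
  ord <- order(ids)
  dd <- diss[ord, ord, drop = FALSE]
  groups <- dynamic_cut_recursive(dd, seq_len(n), min_module_size, min_gap)
  labels <- integer(n)
  sizes <- vapply(groups, length, integer(1))
  for (i in seq_along(groups)) {
    labels[groups[[order(-sizes)[i]]]] <- i
  }
  out <- integer(n)
  out[ord] <- labels
  stats::setNames(out, ids)
}

# mean within-part dissimilarity over parts of a partition
mean_within <- function(diss, parts) {
  vals <- unlist(lapply(parts, function(p) {
    dd <- diss[p, p, drop = FALSE]
    dd[upper.tri(dd)]
  }))
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# mean dissimilarity between all pairs of distinct parts
mean_between <- function(diss, parts) {
  vals <- unlist(lapply(seq_along(parts)[-1], function(i) {
    lapply(seq_len(i - 1), function(j) diss[parts[[i]], parts[[j]]])
  }))
  mean(vals)
}

dynamic_cut_recursive <- function(diss, idx, min_size, min_gap) {
  if (length(idx) < min_size) return(list())
  d <- stats::as.dist(diss[idx, idx, drop = FALSE])
  hc <- stats::hclust(d, method = "average")
  hs <- sort(unique(hc$height))
  if (length(hs) < 2) return(list(idx))
  mids <- (hs[-1] + hs[-length(hs)]) / 2
  cls <- stats::cutree(hc, h = mids)
  if (is.null(dim(cls))) cls <- matrix(cls, ncol = 1)
  n_big <- apply(cls, 2, function(cl) sum(table(cl) >= min_size))
  best <- max(n_big)
  if (best == 0) return(list(idx))

  # cap the number of candidate cuts examined in detail
  subsample <- function(js, k = 20) {
    if (length(js) <= k) js else js[unique(round(seq(1, length(js),
                                                     length.out = k)))]
  }

  if (best >= 2) {
    # among cuts yielding the most large branches, take the highest cut
    # whose branches remain separated (maximal branches subject to
    # separation); if none separates, fall back to the most separated one
    js <- subsample(which(n_big == best))
    gaps <- vapply(js, function(j) {
      parts <- split(idx, cls[, j])
      big <- parts[vapply(parts, length, integer(1)) >= min_size]
      mean_between(diss, big) - mean_within(diss, big)
    }, numeric(1))
    j <- if (any(gaps >= min_gap)) {
      max(js[gaps >= min_gap])
    } else {
      js[which.max(gaps)]
    }
    parts <- split(idx, cls[, j])
    sizes <- vapply(parts, length, integer(1))
    big <- parts[sizes >= min_size]
    rest <- unlist(parts[sizes < min_size], use.names = FALSE)
    if (max(gaps) >= min_gap) {
      out <- list()
      for (p in big) {
        out <- c(out, dynamic_cut_recursive(diss, p, min_size, min_gap))
      }
      return(if (length(out) == 0) list(idx) else out)
    }
    # branches not separated (one module split in half); strip separated
    # chaff if any, else keep whole
    keep <- sort(unlist(big, use.names = FALSE))
    if (length(rest) > 0 && length(keep) < length(idx) &&
        mean(diss[keep, rest]) - mean_within(diss, big) >= min_gap) {
      return(dynamic_cut_recursive(diss, keep, min_size, min_gap))
    }
    return(list(idx))
  }

  # best == 1: scan from the highest cut down for a separated chaff strip
  for (j in rev(subsample(which(n_big == 1)))) {
    parts <- split(idx, cls[, j])
    sizes <- vapply(parts, length, integer(1))
    core <- parts[[which.max(sizes)]]
    rest <- setdiff(idx, core)
    if (length(rest) == 0) next
    if (mean(diss[core, rest]) - mean_within(diss, list(core)) >= min_gap) {
      return(dynamic_cut_recursive(diss, core, min_size, min_gap))
    }
  }
  list(idx)
}

#' Module eigengene
#'
#' Standardizes each member gene across samples (mean 0, sd 1) and takes the
#' first right singular vector of the member x sample matrix, scaled to unit
#' variance. The sign is oriented so that the average correlation between
#' member genes and the eigengene is positive.
#'
#' @param expr gene x sample log-expression matrix.
#' @param genes member gene ids (>= 3).
#' @return list with `me` (per-sample scores, unit variance),
#'   `variance_explained` (proportion of standardized member variance).
#' @export
eigengene <- function(expr, genes) {
  if (length(genes) < 3) {
    stop("eigengene needs a module of at least 3 genes", call. = FALSE)
  }
  x <- expr[genes, , drop = FALSE]
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0)) {
    # constant genes carry no sample variation; drop from the SVD
    x <- x[sdv > 0, , drop = FALSE]
    if (nrow(x) < 1) stop("all member genes are constant", call. = FALSE)
  }
  xs <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  sv <- svd(xs, nu = 0, nv = 1)
  me <- drop(sv$v)
  me <- me / stats::sd(me)
  mean_cor <- mean(stats::cor(t(xs), me))
  if (mean_cor < 0) me <- -me
  names(me) <- colnames(expr)
  list(me = me, variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Merge modules with highly correlated eigengenes
#'
#' Repeatedly finds the module pair whose eigengenes correlate most strongly;
#' if the correlation exceeds `merge_threshold` the pair is merged (the merged
#' eigengene is recomputed) and the search restarts. Ties are broken toward
#' the smallest label pair, so merging is deterministic, and a second pass
#' changes nothing.
#'
#' @param expr gene x sample log-expression matrix.
#' @param labels integer module labels per gene (0 = unassigned).
#' @param merge_threshold eigengene correlation above which modules merge
#'   (default 0.75).
#' @return list with `labels` (relabelled 1..M by decreasing size), `mes`
#'   (sample x module eigengene matrix), `variance_explained`, `merged`
#'   (number of merge events).
#' @export
merge_close_modules <- function(expr, labels, merge_threshold = 0.75) {
  if (merge_threshold <= 0 || merge_threshold >= 1) {
    stop("merge_threshold must be in (0, 1)", call. = FALSE)
  }
  labels <- as.integer(labels)
  names(labels) <- rownames(expr)
  merged <- 0L
  repeat {
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) < 2) break
    mes <- vapply(mods, function(m) {
      eigengene(expr, rownames(expr)[labels == m])$me
    }, numeric(ncol(expr)))
    cm <- stats::cor(mes)
    diag(cm) <- -Inf
    best <- which(cm == max(cm), arr.ind = TRUE)
    # ties: smallest label pair
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    if (max(cm) <= merge_threshold) break
    from <- mods[max(best)]
    to <- mods[min(best)]
    labels[labels == from] <- to
    merged <- merged + 1L
  }
  # relabel by decreasing size
  mods <- setdiff(unique(labels), 0L)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new <- stats::setNames(seq_along(mods), mods[order(-sizes, mods)])
  out <- labels
  out[labels != 0] <- new[as.character(labels[labels != 0])]
  mods_out <- sort(unique(out[out != 0]))
  eg <- lapply(mods_out, function(m) eigengene(expr, names(out)[out == m]))
  mes <- vapply(eg, `[[`, numeric(ncol(expr)), "me")
  colnames(mes) <- paste0("ME", mods_out)
  rownames(mes) <- colnames(expr)
  list(labels = out,
       mes = mes,
       variance_explained = stats::setNames(
         vapply(eg, `[[`, numeric(1), "variance_explained"),
         colnames(mes)),
       merged = merged)
}

#' Module membership, hub genes and positive-membership fraction
#'
#' Module membership (MM) of gene g in module m is the Pearson correlation
#' between the gene's expression and the module eigengene. The hub gene of a
#' module is the member maximizing |MM| (signed MM reported; ties broken by
#' lexicographically smallest gene id). The positive-MM fraction is computed
#' over member genes.
#'
#' @param expr gene x sample log-expression matrix.
#' @param mes sample x module eigengene matrix.
#' @param labels module labels per gene (named), 0 = unassigned; module m
#'   corresponds to column `MEm`.
#' @return list with `mm` (gene x module correlations), `hubs` (data.frame:
#'   module, hub gene, MM), `positive_fraction` per module.
#' @export
module_membership <- function(expr, mes, labels) {
  mm <- stats::cor(t(expr), mes)
  mods <- sort(setdiff(unique(labels), 0))
  hubs <- do.call(rbind, lapply(mods, function(m) {
    members <- sort(names(labels)[labels == m])
    v <- mm[members, paste0("ME", m)]
    hub <- members[which.max(abs(v))]  # which.max takes the first tie = smallest id
    data.frame(module = m, size = length(members), hub = hub,
               mm = unname(v[hub]), stringsAsFactors = FALSE)
  }))
  pos <- vapply(mods, function(m) {
    members <- names(labels)[labels == m]
    mean(mm[members, paste0("ME", m)] > 0)
  }, numeric(1))
  list(mm = mm, hubs = hubs,
       positive_fraction = stats::setNames(pos, paste0("ME", mods)))
}

#' Full network stage: adjacency to merged modules
#'
#' Convenience wrapper running [adjacency_matrix()], [tom_similarity()],
#' [cluster_and_cut()], [merge_close_modules()] and [module_membership()].
#'
#' @param expr gene x sample log-expression matrix.
#' @param beta soft-threshold power.
#' @param type network type.
#' @param min_module_size minimum module size (default 30).
#' @param merge_threshold eigengene-correlation merge threshold (default
#'   0.75).
#' @return list with `labels`, `mes`, `variance_explained`, `mm`, `hubs`,
#'   `positive_fraction`.
#' @export
detect_modules <- function(expr, beta, type = c("unsigned", "signed"),
                           min_module_size = 30, merge_threshold = 0.75) {
  type <- match.arg(type)
  a <- adjacency_matrix(expr, beta, type)
  tom <- tom_similarity(a)
  labels <- cluster_and_cut(1 - tom, min_module_size)
  if (all(labels == 0)) {
    return(list(labels = labels, mes = NULL, variance_explained = NULL,
                mm = NULL, hubs = NULL, positive_fraction = NULL))
  }
  mg <- merge_close_modules(expr, labels, merge_threshold)
  memb <- module_membership(expr, mg$mes, mg$labels)
  c(mg[c("labels", "mes", "variance_explained")],
    memb[c("mm", "hubs", "positive_fraction")])
}
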