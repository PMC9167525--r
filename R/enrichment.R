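# Hypergeometric over-representation of annotation terms in module gene
# lists against a tissue-expressed gene universe.

#' Load gene-set annotations
#'
#' Reads either GMT (term, description, genes...) or a two-column
#' term-to-gene TSV into a term -> gene-set map; an optional two-column
#' term -> pathway TSV adds the pathway grouping used for pathway-level
#' ranking. Duplicate genes within a set are removed; malformed lines are
#' skipped with a warning.
#'
#' @param file path to a `.gmt` file or a two-column TSV (term, gene).
#' @param pathway_file optional two-column TSV (term, pathway).
#' @return An `annotation_map`: list with `sets` (term -> character vector)
#'   and `pathways` (term -> character vector of pathway ids, possibly
#'   many-to-many).
#' @export
load_gene_sets <- function(file, pathway_file = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty annotation file: ", file, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_gmt <- grepl("\\.gmt$", file, ignore.case = TRUE) ||
    all(vapply(fields, length, integer(1)) >= 3)
  sets <- list()
  bad <- 0L
  if (is_gmt) {
    for (f in fields) {
      if (length(f) < 3) { bad <- bad + 1L; next }
      sets[[f[1]]] <- unique(c(sets[[f[1]]], f[-(1:2)]))
    }
  } else {
    for (f in fields) {
      if (length(f) < 2) { bad <- bad + 1L; next }
      sets[[f[1]]] <- unique(c(sets[[f[1]]], f[2]))
    }
  }
  if (bad > 0) warning(bad, " malformed annotation line(s) skipped")
  if (length(sets) == 0) stop("no usable gene sets in ", file, call. = FALSE)
  pathways <- list()
  if (!is.null(pathway_file)) {
    pl <- strsplit(readLines(pathway_file), "\t", fixed = TRUE)
    pl <- pl[vapply(pl, length, integer(1)) >= 2]
    for (f in pl) pathways[[f[1]]] <- unique(c(pathways[[f[1]]], f[2]))
  }
  structure(list(sets = sets, pathways = pathways),
            class = "annotation_map")
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' p = P(X >= k) for X ~ hypergeometric(N, K, n): the probability of drawing
#' at least the observed overlap when `n` module genes are sampled without
#' replacement from a universe of `N` genes of which `K` carry the term. The
#' term set is restricted to the universe before counting.
#'
#' @param module_genes character vector, must be a subset of `universe`.
#' @param term_genes character vector (restricted to `universe` internally).
#' @param universe character vector of expressed genes.
#' @return list with `p`, `k` (overlap), `K` (term size in universe),
#'   `n` (module size), `N` (universe size).
#' @export
hypergeom_test <- function(module_genes, term_genes, universe) {
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  missing <- setdiff(module_genes, universe)
  if (length(missing) > 0) {
    stop("module genes not in universe: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  term <- intersect(unique(term_genes), universe)
  k <- length(intersect(module_genes, term))
  K <- length(term)
  n <- length(module_genes)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, k = k, K = K, n = n, N = N)
}

#' Term over-representation for one module
#'
#' Tests every annotation term with at least one universe gene against the
#' module gene list and applies BH correction across the tested terms.
#'
#' @param module_genes module gene ids (subset of `universe`).
#' @param annotation an [load_gene_sets()] `annotation_map`, or a plain named
#'   list of term -> gene vectors.
#' @param universe expressed-gene universe.
#' @param fdr q-value significance threshold (default 0.05).
#' @return data.frame per tested term: `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, sorted by p. Terms with no universe genes are dropped.
#' @export
enrich_module <- function(module_genes, annotation, universe, fdr = 0.05) {
  sets <- if (inherits(annotation, "annotation_map")) {
    annotation$sets
  } else {
    annotation
  }
  universe <- unique(universe)
  rows <- lapply(names(sets), function(term) {
    tg <- intersect(unique(sets[[term]]), universe)
    if (length(tg) == 0) return(NULL)
    ht <- hypergeom_test(module_genes, tg, universe)
    data.frame(term = term, k = ht$k, K = ht$K, n = ht$n, N = ht$N,
               p = ht$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical()))
  }
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < fdr
  res[order(res$p, res$term), ]
}

#' Top pathway by enriched-term count
#'
#' Ranks pathways by how many enriched terms map to them and returns the
#' winner. When several pathways tie on the count, the tie is flagged and the
#' alphabetically first pathway is returned (a deterministic stand-in for a
#' curator's "most informative" choice).
#'
#' @param enriched character vector of significantly enriched term ids.
#' @param term_pathways named list term -> character vector of pathway ids
#'   (e.g. `annotation$pathways`).
#' @return list with `pathway` (NA when no enriched term maps), `count`,
#'   `tie` flag, and `terms_in_pathway`.
#' @export
top_pathway <- function(enriched, term_pathways) {
  hits <- list()
  for (term in intersect(enriched, names(term_pathways))) {
    for (pw in term_pathways[[term]]) {
      hits[[pw]] <- unique(c(hits[[pw]], term))
    }
  }
  if (length(hits) == 0) {
    return(list(pathway = NA_character_, count = 0L, tie = FALSE,
                terms_in_pathway = character()))
  }
  counts <- vapply(hits, length, integer(1))
  best <- max(counts)
  winners <- sort(names(counts)[counts == best])
  list(pathway = winners[1], count = best, tie = length(winners) > 1,
       terms_in_pathway = hits[[winners[1]]])
}
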