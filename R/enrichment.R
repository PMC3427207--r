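#' Category annotation
#'
#' Flat many-to-many gene -> category mapping (e.g. a Gene Ontology
#' biological-process table with ancestors already propagated by the
#' caller).
#'
#' @param mapping data.frame with columns `gene` and `category`.
#' @return object of class `CategoryAnnotation` (internally a split list
#'   of gene vectors per category).
#' @export
category_annotation <- function(mapping) {
  stopifnot(all(c("gene", "category") %in% names(mapping)))
  cats <- split(as.character(mapping$gene), as.character(mapping$category))
  cats <- lapply(cats, unique)
  structure(list(categories = cats,
                 genes = unique(as.character(mapping$gene))),
            class = "CategoryAnnotation")
}

#' @export
print.CategoryAnnotation <- function(x, ...) {
  cat(sprintf("CategoryAnnotation: %d categories over %d genes\n",
              length(x$categories), length(x$genes)))
  invisible(x)
}

# Per-category in-set counts for a gene set, given a logical membership
# matrix (categories x universe).
category_counts <- function(memb, universe, genes) {
  ind <- universe %in% genes
  as.vector(memb %*% ind)
}

#' Category over-representation test
#'
#' One-sided Fisher's exact test (hypergeometric tail) per category, over
#' the universe `test_set` union `background` restricted to annotated
#' genes. Only categories with at least `min_size` annotated universe genes
#' are tested. The test set and background must be disjoint (the background
#' is "expressed but no effect").
#'
#' @param test_set gene set of interest.
#' @param background background gene set (disjoint from `test_set`).
#' @param annotation a [category_annotation()].
#' @param min_size minimum annotated genes per tested category.
#' @return data.frame with `category`, `n_category`, `n_overlap`,
#'   `odds_ratio`, `p`, sorted by p.
#' @export
category_enrichment <- function(test_set, background, annotation,
                                min_size = 10) {
  if (length(intersect(test_set, background)) > 0L)
    stop("test set and background must be disjoint")
  universe <- intersect(union(test_set, background), annotation$genes)
  test_ann <- intersect(test_set, universe)
  if (length(universe) == 0L || length(test_ann) == 0L) {
    message("no annotated genes overlap the input sets; empty result")
    return(data.frame(category = character(0), n_category = integer(0),
                      n_overlap = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  }
  cats <- lapply(annotation$categories, intersect, universe)
  sizes <- lengths(cats)
  keep <- sizes >= min_size
  cats <- cats[keep]
  sizes <- sizes[keep]
  n_t <- length(test_ann)
  n_u <- length(universe)
  a <- vapply(cats, function(cg) length(intersect(cg, test_ann)), integer(1))
  b <- n_t - a
  cc <- sizes - a
  d <- n_u - n_t - cc
  p <- stats::phyper(a - 1, sizes, n_u - sizes, n_t, lower.tail = FALSE)
  or <- ifelse(b * cc == 0, ifelse(a * d == 0, NA_real_, Inf),
               (a * d) / (b * cc))
  out <- data.frame(category = names(cats), n_category = as.integer(sizes),
                    n_overlap = as.integer(a), odds_ratio = or, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), , drop = FALSE]
}

#' Resampling-based FDR and global p for category enrichment
#'
#' Draws `n_resample` random gene sets of the test-set size from the
#' annotated background, recomputes the enrichment analysis for each, and
#' for every p cutoff in `p_grid` reports (i) the FDR, the ratio of the
#' median permutation enriched-category count to the observed count, and
#' (ii) the global p, the fraction of resamples with at least as many
#' enriched categories as observed. The reporting cutoff is the largest
#' grid value at which FDR < `fdr_target` and global p < `global_alpha`.
#'
#' @inheritParams category_enrichment
#' @param n_resample number of resampled gene sets (default 1000).
#' @param p_grid candidate p cutoffs (default `c(0.05, 0.01, 0.005,
#'   0.001)`).
#' @param fdr_target,global_alpha reporting thresholds (defaults 0.10,
#'   0.05).
#' @param seed RNG seed.
#' @return list with `grid` (data.frame: cutoff, observed count, median
#'   permutation count, fdr, global_p), `reporting_cutoff` (NA when no grid
#'   value qualifies), `observed` (the [category_enrichment()] table),
#'   `n_resample`, `seed`.
#' @export
resampling_fdr <- function(test_set, background, annotation,
                           n_resample = 1000,
                           p_grid = c(0.05, 0.01, 0.005, 0.001),
                           min_size = 10, fdr_target = 0.10,
                           global_alpha = 0.05, seed = 1) {
  local_seed_if(seed)
  bg_ann <- intersect(background, annotation$genes)
  test_ann <- intersect(test_set, annotation$genes)
  n_draw <- length(test_ann)
  if (n_draw > length(bg_ann))
    stop("test set larger than annotated background")
  obs <- category_enrichment(test_set, background, annotation, min_size)
  obs_counts <- vapply(p_grid, function(cut) sum(obs$p < cut), integer(1))
  perm_counts <- matrix(0L, nrow = n_resample, ncol = length(p_grid))
  for (i in seq_len(n_resample)) {
    draw <- sample(bg_ann, n_draw)
    pe <- category_enrichment(draw, setdiff(background, draw), annotation,
                              min_size)
    perm_counts[i, ] <- vapply(p_grid, function(cut) sum(pe$p < cut),
                               integer(1))
  }
  med <- apply(perm_counts, 2L, stats::median)
  fdr <- ifelse(obs_counts > 0, med / obs_counts, NA_real_)
  global_p <- vapply(seq_along(p_grid), function(j)
    mean(perm_counts[, j] >= obs_counts[j]), numeric(1))
  grid <- data.frame(cutoff = p_grid, n_observed = obs_counts,
                     perm_median = med, fdr = fdr, global_p = global_p)
  ok <- which(!is.na(fdr) & fdr < fdr_target & global_p < global_alpha)
  reporting <- if (length(ok)) max(p_grid[ok]) else NA_real_
  list(grid = grid, reporting_cutoff = reporting, observed = obs,
       n_resample = n_resample, seed = seed)
}
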