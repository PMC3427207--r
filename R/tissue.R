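#' Tissue expression atlas
#'
#' Gene x tissue expression matrix for one species with a designated focal
#' tissue, used to derive per-gene tissue-specificity z-scores.
#'
#' @param values numeric gene x tissue matrix (tissue names as columns).
#' @param species species identifier.
#' @param focal_tissue column name of the focal tissue (e.g. `"liver"`).
#' @return object of class `TissueAtlas`.
#' @export
tissue_atlas <- function(values, species, focal_tissue) {
  values <- as.matrix(values)
  if (ncol(values) < 3L) stop("need at least 3 tissues for a z-score")
  if (!focal_tissue %in% colnames(values))
    stop(sprintf("focal tissue '%s' not in atlas", focal_tissue))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%05d", seq_len(nrow(values)))
  structure(list(values = values, species = as.character(species),
                 focal_tissue = as.character(focal_tissue)),
            class = "TissueAtlas")
}

#' @export
print.TissueAtlas <- function(x, ...) {
  cat(sprintf("TissueAtlas %s: %d genes x %d tissues (focal: %s)\n",
              x$species, nrow(x$values), ncol(x$values), x$focal_tissue))
  invisible(x)
}

#' Tissue-specificity z-score per gene
#'
#' The focal-tissue expression of each gene expressed as its distance from
#' the gene's mean across all tissues, in units of the gene's cross-tissue
#' standard deviation. Genes with zero cross-tissue SD get `NA` (warning).
#'
#' @param atlas a [tissue_atlas()].
#' @return named numeric vector of z-scores.
#' @export
specificity_z <- function(atlas) {
  v <- atlas$values
  m <- rowMeans(v)
  s <- apply(v, 1L, stats::sd)
  z <- (v[, atlas$focal_tissue] - m) / s
  if (any(s == 0)) {
    warning(sprintf("%d gene(s) constant across tissues: z undefined",
                    sum(s == 0)))
    z[s == 0] <- NA_real_
  }
  stats::setNames(z, rownames(v))
}

#' Compare tissue specificity of a foreground gene set between species
#'
#' Aligns the two species' specificity scales on a background gene set
#' expected to show no difference (species 2 scores are shifted so the
#' background medians are exactly equal), then tests the foreground genes
#' for higher specificity in species 2 with a one-sided rank-sum test
#' (or the supplied alternative).
#'
#' Genes with an undefined z in either species are dropped pairwise from
#' both the foreground and the background.
#'
#' @param z_a,z_b named per-gene z-score vectors ([specificity_z()]) for
#'   species 1 and 2.
#' @param foreground,background disjoint gene sets present in both vectors.
#' @param alternative `"greater"` tests foreground z higher in species 2.
#' @return list of class `SpecificityResult`: `z1`, `z2` (aligned
#'   foreground scores), `shift_applied`, `p`, `n_foreground`,
#'   `n_background`.
#' @export
compare_specificity <- function(z_a, z_b, foreground, background,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(intersect(foreground, background)) > 0L)
    stop("foreground and background must be disjoint")
  usable <- function(g) g[g %in% names(z_a) & g %in% names(z_b) &
                            !is.na(z_a[g]) & !is.na(z_b[g])]
  fg <- usable(foreground)
  bg <- usable(background)
  if (length(fg) == 0L || length(bg) == 0L)
    stop("empty usable foreground or background")
  shift <- stats::median(z_a[bg]) - stats::median(z_b[bg])
  z_b_adj <- z_b + shift
  ht <- ranksum_test(z_b_adj[fg], z_a[fg], alternative = alternative)
  res <- list(z1 = z_a[fg], z2 = z_b_adj[fg], shift_applied = shift,
              p = ht$p.value, n_foreground = length(fg),
              n_background = length(bg))
  class(res) <- "SpecificityResult"
  res
}

#' @export
print.SpecificityResult <- function(x, ...) {
  cat(sprintf("SpecificityResult: %d foreground genes, shift %.4f, p = %.3g\n",
              x$n_foreground, x$shift_applied, x$p))
  invisible(x)
}

#' Relative expression level within one tissue
#'
#' z-score of each gene's expression relative to all expressed genes within
#' a single tissue: distance to the within-tissue mean in units of the
#' within-tissue standard deviation. Used to check that tissue-specific
#' genes are not simply higher-expressed overall.
#'
#' @param x numeric vector of per-gene expression within one tissue
#'   (length >= 3).
#' @return numeric vector of z-scores (mean 0, SD 1).
#' @export
relative_within_tissue_level <- function(x) {
  if (length(x) < 3L) stop("need at least 3 genes")
  (x - mean(x)) / stats::sd(x)
}
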