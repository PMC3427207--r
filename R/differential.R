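#' Per-gene differential expression between two groups
#'
#' Tests every gene for a difference between two group levels and returns a
#' gene-effect table: p-value, pooled-SD effect size `d`, and direction.
#' `method = "t"` is the pooled-variance Student t-test (identical p-values
#' to a two-level one-way ANOVA, by the F = t^2 identity); `"welch"` relaxes
#' the equal-variance assumption; `"anova"` accepts more than two levels via
#' `contrast = NULL` (then `d`/`direction` are `NA`). One-sided tests
#' (`sided = "one"`) report evidence for level A > level B.
#'
#' Genes with zero within-group variance in both groups and equal means get
#' `p = 1`, `d = 0`.
#'
#' @param study an [expression_study()].
#' @param contrast character vector `c(levelA, levelB)`, or `NULL` with
#'   `method = "anova"` to test all group levels jointly.
#' @param method `"t"`, `"welch"` or `"anova"`.
#' @param sided `"two"` or `"one"`.
#' @return data.frame of class `gene_effects` with columns `gene`, `p`, `d`,
#'   `direction` (sign of mean(A) - mean(B)), `cohort`.
#' @export
test_differential <- function(study, contrast, method = c("t", "welch", "anova"),
                              sided = c("two", "one")) {
  method <- match.arg(method)
  sided <- match.arg(sided)
  v <- study$values
  if (method == "anova" && (missing(contrast) || is.null(contrast))) {
    lev <- unique(study$group)
    if (any(table(study$group) < 2L))
      stop("every group level needs at least 2 samples")
    res <- row_anova(v, study$group)
    out <- data.frame(gene = rownames(v), p = res$p, d = NA_real_,
                      direction = NA_integer_, cohort = study$dataset,
                      stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("gene_effects", class(out))
    return(out)
  }
  stopifnot(length(contrast) == 2L)
  i1 <- group_idx(study, contrast[1])
  i2 <- group_idx(study, contrast[2])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each contrast level needs at least 2 samples")
  if (method == "anova") {
    sub <- c(i1, i2)
    res <- row_anova(v[, sub, drop = FALSE], study$group[sub])
    p <- res$p
  } else {
    tt <- row_t_test(v, i1, i2, pooled = (method == "t"), sided = sided)
    p <- tt$p
  }
  d <- effect_size_matrix(v, i1, i2)
  out <- data.frame(gene = rownames(v), p = p, d = d,
                    direction = as.integer(sign(rowMeans(v[, i1, drop = FALSE]) -
                                                rowMeans(v[, i2, drop = FALSE]))),
                    cohort = study$dataset, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("gene_effects", class(out))
  out
}

# Shared kernel: pooled-SD effect size d = (M1 - M2) / SDp with
# SDp = sqrt(((N1-1) SD1^2 + (N2-1) SD2^2) / (N1 + N2 - 2)).
effect_size_matrix <- function(v, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("effect size needs N1, N2 >= 2")
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m2 <- rowMeans(v[, i2, drop = FALSE])
  v1 <- rowSums((v[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((v[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  sdp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sdp
  if (any(sdp == 0)) {
    warning(sprintf("%d gene(s) with zero pooled SD: d undefined (NA)",
                    sum(sdp == 0)))
    d[sdp == 0] <- NA_real_
  }
  d
}

#' Pooled-SD effect size per gene
#'
#' `d = (M1 - M2) / SDp`, the between-group mean difference in pooled
#' standard-deviation units. `|d| > 0.8` is the conventional gate for modest
#' effects used throughout the pipeline.
#'
#' @param study an [expression_study()].
#' @param levelA,levelB group levels (d > 0 means higher in `levelA`).
#' @return named numeric vector of d per gene (NA where the pooled SD is 0,
#'   with a warning).
#' @export
effect_size <- function(study, levelA, levelB) {
  i1 <- group_idx(study, levelA)
  i2 <- group_idx(study, levelB)
  d <- effect_size_matrix(study$values, i1, i2)
  names(d) <- study_genes(study)
  d
}

#' Permutation-calibrated FDR cutoff for differential expression
#'
#' Shuffles group labels `n_perm` times, recomputes all per-gene p-values
#' each time, and searches the grid of observed p-values for the largest
#' cutoff at which the median permutation significant-gene count is at most
#' `target_fdr` times the observed count (the FDR estimate at that cutoff).
#' Ties in the selected significant set are broken toward the smaller
#' cutoff. The returned grid also carries a monotonized (running-maximum)
#' copy of the estimate for diagnostic use.
#' Permutations are sampled with replacement from the label-permutation
#' group, excluding the identity labelling.
#'
#' @param study an [expression_study()].
#' @param contrast `c(levelA, levelB)`.
#' @param method test passed to [test_differential()].
#' @param n_perm number of label permutations.
#' @param target_fdr target false-discovery fraction.
#' @param seed RNG seed for the permutations.
#' @return list of class `fdr_calibration` with elements `cutoff_p`,
#'   `n_observed`, `significant` (gene ids), `perm_counts` (per-permutation
#'   counts at the chosen cutoff), `fdr_grid` (data.frame over the cutoff
#'   grid), `target_fdr`, `n_perm`, `seed`. When no cutoff satisfies the
#'   criterion, `cutoff_p` is `NA` and the significant set is empty.
#' @export
calibrate_permutation_fdr <- function(study, contrast, method = "t",
                                      n_perm = 1000, target_fdr = 0.10,
                                      seed = 1) {
  local_seed_if(seed)
  eff <- test_differential(study, contrast, method = method)
  obs_p <- eff$p
  cutoffs <- sort(unique(obs_p))
  sorted_obs <- sort(obs_p)
  obs_counts <- findInterval(cutoffs, sorted_obs)
  n_distinct <- choose(length(study$group), sum(study$group == contrast[1]))
  if (n_distinct < n_perm)
    warning(sprintf("only %d distinct label permutations exist (< n_perm)",
                    n_distinct))
  perm_study <- study
  perm_counts_mat <- matrix(0L, nrow = n_perm, ncol = length(cutoffs))
  for (i in seq_len(n_perm)) {
    repeat {
      g <- sample(study$group)
      if (!identical(g, study$group)) break
    }
    perm_study$group <- g
    pp <- sort(test_differential(perm_study, contrast, method = method)$p)
    perm_counts_mat[i, ] <- findInterval(cutoffs, pp)
  }
  med <- apply(perm_counts_mat, 2L, stats::median)
  fdr_raw <- ifelse(obs_counts > 0, med / obs_counts, NA_real_)
  ok <- which(!is.na(fdr_raw) & fdr_raw <= target_fdr)
  grid <- data.frame(cutoff = cutoffs, n_observed = obs_counts,
                     perm_median = med, fdr = fdr_raw,
                     fdr_monotone = cummax(ifelse(is.na(fdr_raw), 0,
                                                  fdr_raw)))
  if (length(ok) == 0L) {
    res <- list(cutoff_p = NA_real_, n_observed = 0L,
                significant = character(0),
                perm_counts = perm_counts_mat[, 1L],
                fdr_grid = grid, target_fdr = target_fdr, n_perm = n_perm,
                seed = seed,
                note = "no cutoff met the FDR criterion; empty significant set")
  } else {
    best <- max(ok)
    # ties toward the smaller cutoff among cutoffs selecting the same set
    same <- ok[obs_counts[ok] == obs_counts[best] & fdr_raw[ok] <= target_fdr]
    best <- min(same)
    res <- list(cutoff_p = cutoffs[best], n_observed = obs_counts[best],
                significant = eff$gene[obs_p <= cutoffs[best]],
                perm_counts = perm_counts_mat[, best],
                fdr_grid = grid, target_fdr = target_fdr, n_perm = n_perm,
                seed = seed, note = NULL)
  }
  class(res) <- "fdr_calibration"
  res
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat("Permutation-calibrated FDR\n")
  if (is.na(x$cutoff_p)) {
    cat("  no cutoff met target FDR", x$target_fdr, "- empty set\n")
  } else {
    cat(sprintf("  cutoff p = %.4g -> %d significant genes (target FDR %.2f, %d permutations)\n",
                x$cutoff_p, x$n_observed, x$target_fdr, x$n_perm))
    cat(sprintf("  median permutation count at cutoff: %.1f\n",
                stats::median(x$perm_counts)))
  }
  invisible(x)
}

#' Cross-cohort consistent differentially expressed genes
#'
#' Returns genes called in both cohorts with the same direction of change,
#' either by each cohort's significance call (`rule = "fdr_both"`, using
#' `cutoffs` as the per-cohort p cutoffs) or by the effect-size gate
#' (`rule = "es_both"`, `|d| > cutoff` in both).
#'
#' @param a,b `gene_effects` tables from [test_differential()].
#' @param rule `"fdr_both"` or `"es_both"`.
#' @param cutoffs for `fdr_both`, numeric length-2 p cutoffs (cohort a, b);
#'   for `es_both`, a single |d| cutoff (default 0.8).
#' @return character vector of gene ids.
#' @export
consistent_de <- function(a, b, rule = c("fdr_both", "es_both"),
                          cutoffs = 0.8) {
  rule <- match.arg(rule)
  shared <- intersect(a$gene, b$gene)
  if (length(shared) == 0L) stop("no shared genes")
  ia <- match(shared, a$gene)
  ib <- match(shared, b$gene)
  same_dir <- a$direction[ia] == b$direction[ib] & a$direction[ia] != 0L
  hit <- switch(rule,
    fdr_both = {
      cut2 <- rep_len(cutoffs, 2L)
      a$p[ia] <= cut2[1] & b$p[ib] <= cut2[2]
    },
    es_both = abs(a$d[ia]) > cutoffs[1] & abs(b$d[ib]) > cutoffs[1]
  )
  shared[which(hit & same_dir)]
}

#' One-sided overlap test between two gene sets
#'
#' Fisher's exact test (alternative: over-representation) on the 2x2 table
#' of membership in `set1` x `set2` over `background`.
#'
#' @param set1,set2 gene sets, subsets of `background`.
#' @param background universe of genes.
#' @return list with `odds_ratio` (sample OR; `Inf` sentinel when a zero
#'   cell makes it unbounded) and `p`.
#' @export
overlap_test <- function(set1, set2, background) {
  if (length(background) == 0L) stop("empty background")
  set1 <- intersect(set1, background)
  set2 <- intersect(set2, background)
  a <- length(intersect(set1, set2))
  b <- length(setdiff(set1, set2))
  cc <- length(setdiff(set2, set1))
  d <- length(background) - a - b - cc
  fisher_greater(a, b, cc, d)
}
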