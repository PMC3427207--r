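#' Log-transform and quantile-normalize an expression matrix
#'
#' Applies `log2(x + pseudocount)` followed by quantile normalization: every
#' column's sorted value vector is replaced by the rank-wise mean of all
#' columns' sorted log values, so that after the step all columns share an
#' identical empirical distribution. Tied values within a column receive the
#' mean of the reference quantiles of their tied ranks.
#'
#' @param study an [expression_study()].
#' @param pseudocount added before the log; use 1 for raw counts, 0 for
#'   already-continuous values (values must then be positive).
#' @return the study with normalized `values`.
#' @export
log_quantile_normalize <- function(study, pseudocount = 0) {
  v <- study$values
  if (ncol(v) < 2L)
    stop("quantile normalization is undefined for a single-sample matrix")
  if (pseudocount > 0 && any(v < 0))
    stop("`values` must be non-negative when a pseudocount is used")
  study$values <- quantile_normalize(log2(v + pseudocount))
  study
}

#' Quantile-normalize the columns of a matrix
#'
#' The quantile step of [log_quantile_normalize()], exposed separately: the
#' reference distribution is the rank-wise mean of the sorted columns; tied
#' values within a column receive the mean of the reference quantiles of
#' their tied ranks. The operation is idempotent.
#'
#' @param v numeric matrix (features x samples).
#' @return matrix of the same dimensions with identical column distributions.
#' @export
quantile_normalize <- function(v) {
  sorted <- apply(v, 2L, sort)
  ref <- rowMeans(sorted)
  out <- apply(v, 2L, function(col) {
    tmp <- numeric(length(col))
    tmp[order(col)] <- ref
    # average reference values within tie groups
    stats::ave(tmp, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  out
}

#' Filter to reliably detected genes
#'
#' A gene is retained if (1) it is detected (detection p-value below
#' `detect_alpha`) in at least half of all samples, or (2) its
#' detected/undetected counts are significantly uneven across sample groups
#' (Fisher's exact test at `uneven_alpha`), which indicates group-specific
#' expression. For count data (no detection p-values) detection is
#' `count > 0`; genes with zero counts in more than half of samples and no
#' detection unevenness are removed.
#'
#' @param study an [expression_study()]; must carry `detection_p`, or
#'   `mode = "counts"`.
#' @param detect_alpha per-sample detection p-value threshold.
#' @param uneven_alpha significance level of the unevenness test.
#' @param mode `"auto"` uses `detection_p` when present, else counts.
#' @return the study restricted to retained genes.
#' @export
filter_detected <- function(study, detect_alpha = 0.05, uneven_alpha = 0.1,
                            mode = c("auto", "detection", "counts")) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (!is.null(study$detection_p)) "detection" else "counts"
  detected <- switch(mode,
    detection = {
      if (is.null(study$detection_p))
        stop("detection p-values missing for all ", nrow(study$values),
             " genes; supply `detection_p` or use mode = 'counts'")
      study$detection_p < detect_alpha
    },
    counts = study$values > 0
  )
  frac <- rowMeans(detected)
  crit1 <- frac >= 0.5
  groups <- unique(study$group)
  crit2 <- vapply(seq_len(nrow(detected)), function(i) {
    tab <- table(factor(detected[i, ], levels = c(FALSE, TRUE)),
                 factor(study$group, levels = groups))
    if (all(rowSums(tab) > 0) && length(groups) >= 2) {
      stats::fisher.test(tab)$p.value < uneven_alpha
    } else {
      FALSE
    }
  }, logical(1))
  keep <- crit1 | crit2
  subset_genes(study, study_genes(study)[keep])
}

#' Remove batch effects by batch-mean subtraction
#'
#' For every gene, subtracts each batch's mean from the samples of that
#' batch, so within-batch gene means become zero. A single-sample batch is
#' allowed but collapses that sample to zero (a warning is issued).
#'
#' @param study an [expression_study()] with `batch` labels.
#' @return the batch-centred study.
#' @export
remove_batch_effect <- function(study) {
  if (is.null(study$batch)) stop("`batch` labels are required")
  v <- study$values
  for (b in unique(study$batch)) {
    idx <- which(study$batch == b)
    if (length(idx) == 1L)
      warning(sprintf("batch '%s' has a single sample; it becomes 0", b))
    v[, idx] <- v[, idx, drop = FALSE] -
      rowMeans(v[, idx, drop = FALSE])
  }
  study$values <- v
  study
}

#' Combine two cohorts on shared genes by two-stage standardization
#'
#' Restricts both studies to their gene intersection, z-scores each gene
#' within each cohort (mean subtracted, divided by the sample SD, computed
#' over the samples whose group is in `groups_for_scaling`, or all samples
#' when `NULL`), concatenates the cohorts, and z-scores each gene again
#' across all combined samples. Output rows have mean 0 and SD 1. Genes with
#' zero variance in either cohort are dropped with a warning.
#'
#' @param a,b [expression_study()] objects.
#' @param groups_for_scaling group labels over which first-stage mean/SD are
#'   computed (the scaling is applied to all samples).
#' @return a combined `ExpressionStudy`; `dataset` records both sources and
#'   per-sample provenance is kept in `batch` when neither input has batches.
#' @export
standardize_and_combine <- function(a, b, groups_for_scaling = NULL) {
  shared <- intersect(study_genes(a), study_genes(b))
  if (length(shared) == 0L) stop("no shared genes between cohorts")
  stage1 <- function(st) {
    v <- st$values[shared, , drop = FALSE]
    idx <- if (is.null(groups_for_scaling)) seq_len(ncol(v)) else
      which(st$group %in% groups_for_scaling)
    if (length(idx) < 2L) stop("fewer than 2 samples selected for scaling")
    m <- rowMeans(v[, idx, drop = FALSE])
    s <- apply(v[, idx, drop = FALSE], 1L, stats::sd)
    list(z = (v - m) / s, sd = s)
  }
  za <- stage1(a); zb <- stage1(b)
  bad <- za$sd == 0 | zb$sd == 0 | !is.finite(za$sd) | !is.finite(zb$sd)
  if (any(bad)) {
    warning(sprintf("%d gene(s) with zero variance dropped", sum(bad)))
    shared <- shared[!bad]
    za$z <- za$z[!bad, , drop = FALSE]
    zb$z <- zb$z[!bad, , drop = FALSE]
  }
  comb <- cbind(za$z, zb$z)
  m <- rowMeans(comb)
  s <- apply(comb, 1L, stats::sd)
  comb <- (comb - m) / s
  colnames(comb) <- make.unique(c(study_samples(a), study_samples(b)))
  expression_study(
    comb,
    group = c(a$group, b$group),
    batch = c(a$batch %||% rep(a$dataset, ncol(a$values)),
              b$batch %||% rep(b$dataset, ncol(b$values))),
    dataset = paste(a$dataset, b$dataset, sep = "+")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
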