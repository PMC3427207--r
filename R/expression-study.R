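#' Expression study container
#'
#' A light S3 container holding a gene x sample expression matrix together
#' with per-sample group/batch/dataset labels and (optionally) a matrix of
#' per-gene detection p-values. All downstream operations in the package
#' consume and return this class.
#'
#' @param values numeric gene x sample matrix. Row names are gene
#'   identifiers, column names sample identifiers; defaults are generated
#'   when absent.
#' @param group character/factor of per-sample group labels (one per column).
#' @param batch optional per-sample batch labels.
#' @param dataset cohort identifier (single string).
#' @param detection_p optional gene x sample matrix of detection p-values
#'   (probability that the signal is background), same dimensions as
#'   `values`.
#' @return an object of class `ExpressionStudy`.
#' @examples
#' m <- matrix(rnorm(40), nrow = 10)
#' st <- expression_study(m, group = rep(c("A", "B"), each = 2))
#' st
#' @export
expression_study <- function(values, group, batch = NULL, dataset = "cohort1",
                             detection_p = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` must have one label per sample")
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != ncol(values))
      stop("`batch` must have one label per sample")
  }
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stop("`detection_p` must match the dimensions of `values`")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(
    list(values = values, group = group, batch = batch,
         dataset = as.character(dataset)[1], detection_p = detection_p),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s': %d genes x %d samples\n",
              x$dataset, nrow(x$values), ncol(x$values)))
  cat("  groups:", paste(sprintf("%s(%d)", names(table(x$group)),
                                 table(x$group)), collapse = " "), "\n")
  if (!is.null(x$batch))
    cat("  batches:", length(unique(x$batch)), "\n")
  if (!is.null(x$detection_p))
    cat("  detection p-values present\n")
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$values)

#' Gene identifiers of an expression study
#' @param study an `ExpressionStudy`.
#' @return character vector of gene ids.
#' @export
study_genes <- function(study) rownames(study$values)

#' Sample identifiers of an expression study
#' @param study an `ExpressionStudy`.
#' @return character vector of sample ids.
#' @export
study_samples <- function(study) colnames(study$values)

# Subset a study to a gene set (order preserved as given).
subset_genes <- function(study, genes) {
  study$values <- study$values[genes, , drop = FALSE]
  if (!is.null(study$detection_p))
    study$detection_p <- study$detection_p[genes, , drop = FALSE]
  study
}

# Column indices of a group level, with cardinality checks for contrasts.
group_idx <- function(study, level) {
  idx <- which(study$group == level)
  if (length(idx) == 0L)
    stop(sprintf("group level '%s' not present", level))
  idx
}
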