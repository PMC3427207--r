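#' Transcription-factor regulon
#'
#' A TF, one binding-motif identifier, and the predicted target gene set
#' (genes carrying at least one conserved predicted binding site of that
#' motif in their promoter). A TF annotated with several motifs gets one
#' regulon per motif.
#'
#' @param tf TF gene identifier.
#' @param motif motif identifier.
#' @param targets character vector of target gene ids (must not contain the
#'   TF itself; non-empty).
#' @param sites optional data.frame of per-target binding sites (as returned
#'   by [scan_pwm()]).
#' @return object of class `TFRegulon`.
#' @export
tf_regulon <- function(tf, motif, targets, sites = NULL) {
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("`targets` must be non-empty")
  if (tf %in% targets) stop("a TF cannot be its own target")
  structure(list(tf = as.character(tf), motif = as.character(motif),
                 targets = targets, sites = sites),
            class = "TFRegulon")
}

#' @export
print.TFRegulon <- function(x, ...) {
  cat(sprintf("TFRegulon %s [%s]: %d targets\n", x$tf, x$motif,
              length(x$targets)))
  invisible(x)
}

# Pool of genes annotated as targets of at least one *other* TF, used as
# the non-target comparison background.
other_targets_pool <- function(regulons, tf) {
  unique(unlist(lapply(regulons, function(r)
    if (r$tf != tf) r$targets else character(0))))
}

#' Regulatory-effect test for one TF regulon
#'
#' Computes Pearson correlations (across all samples) between the TF's
#' expression profile and (i) each of its predicted targets within the
#' `eligible` gene set, and (ii) each eligible non-target (genes annotated
#' as targets of other TFs but not of this one), then compares the two
#' correlation sets with a two-sided rank-sum test. A TF regulating its
#' targets should show systematically more positive or more negative
#' correlations with them than with other TFs' targets. With
#' `use_absolute = TRUE` absolute correlations are compared instead
#' (one-sided, targets more strongly correlated), for replication analyses
#' where the TF may act as both activator and repressor.
#'
#' @param study an [expression_study()].
#' @param regulon a [tf_regulon()].
#' @param eligible gene ids passing the effect-size gate (`|d| > 0.8`
#'   upstream).
#' @param nontarget_pool genes annotated as targets of other TFs; defaults
#'   to all eligible genes outside the regulon (use
#'   [scan_tf_regulators()] for the properly restricted pool).
#' @param use_absolute compare `|r|` one-sided instead of signed `r`
#'   two-sided.
#' @param min_targets minimum eligible targets for a testable result.
#' @return list of class `RegulatoryEffect`: `tf`, `motif`, `p`,
#'   `direction` (`"more_positive"`/`"more_negative"`), `n_targets_tested`,
#'   `n_nontargets`, `median_target_r`, `median_nontarget_r`, `untestable`.
#' @export
regulatory_effect_test <- function(study, regulon, eligible,
                                   nontarget_pool = NULL,
                                   use_absolute = FALSE, min_targets = 5) {
  genes <- study_genes(study)
  if (!regulon$tf %in% genes) stop("TF not expressed in study")
  eligible <- intersect(eligible, genes)
  targets <- setdiff(intersect(regulon$targets, eligible), regulon$tf)
  if (is.null(nontarget_pool))
    nontarget_pool <- setdiff(eligible, regulon$targets)
  nontargets <- setdiff(intersect(nontarget_pool, eligible),
                        c(regulon$targets, regulon$tf))
  res <- list(tf = regulon$tf, motif = regulon$motif, p = NA_real_,
              direction = NA_character_,
              n_targets_tested = length(targets),
              n_nontargets = length(nontargets),
              median_target_r = NA_real_, median_nontarget_r = NA_real_,
              untestable = FALSE)
  if (length(targets) < min_targets || length(nontargets) < 1L) {
    res$untestable <- TRUE
    class(res) <- "RegulatoryEffect"
    return(res)
  }
  tfp <- study$values[regulon$tf, ]
  r_t <- as.vector(stats::cor(tfp, t(study$values[targets, , drop = FALSE])))
  r_n <- as.vector(stats::cor(tfp, t(study$values[nontargets, , drop = FALSE])))
  if (use_absolute) {
    ht <- ranksum_test(abs(r_t), abs(r_n), alternative = "greater")
  } else {
    ht <- ranksum_test(r_t, r_n, alternative = "two.sided")
  }
  res$p <- ht$p.value
  res$median_target_r <- stats::median(r_t)
  res$median_nontarget_r <- stats::median(r_n)
  res$direction <- if (res$median_target_r >= res$median_nontarget_r)
    "more_positive" else "more_negative"
  class(res) <- "RegulatoryEffect"
  res
}

#' @export
print.RegulatoryEffect <- function(x, ...) {
  if (x$untestable) {
    cat(sprintf("RegulatoryEffect %s [%s]: untestable (%d eligible targets)\n",
                x$tf, x$motif, x$n_targets_tested))
  } else {
    cat(sprintf("RegulatoryEffect %s [%s]: p = %.3g (%s), %d targets vs %d non-targets\n",
                x$tf, x$motif, x$p, x$direction, x$n_targets_tested,
                x$n_nontargets))
  }
  invisible(x)
}

#' Scan all qualifying TF regulons for regulatory effects
#'
#' Restricts to regulons whose TF is expressed in the study and passes the
#' effect-size gate (`|d| > es_cutoff`), defines the eligible gene set as
#' genes with `|d| > es_cutoff`, and runs [regulatory_effect_test()] for
#' each qualifying (TF, motif) pair. Non-targets for each TF are eligible
#' genes annotated as targets of at least one other TF.
#'
#' @param study an [expression_study()].
#' @param regulons list of [tf_regulon()] objects.
#' @param effects `gene_effects` table for this study (from
#'   [test_differential()]) supplying per-gene `d`.
#' @param es_cutoff effect-size gate (default 0.8).
#' @param alpha significance cutoff for the pass flag (default 0.01,
#'   two-sided).
#' @param min_targets,use_absolute passed to [regulatory_effect_test()].
#' @return data.frame with one row per tested regulon: `tf`, `motif`, `p`,
#'   `direction`, `n_targets_tested`, `n_nontargets`, `median_target_r`,
#'   `median_nontarget_r`, `untestable`, `pass`.
#' @export
scan_tf_regulators <- function(study, regulons, effects, es_cutoff = 0.8,
                               alpha = 0.01, min_targets = 5,
                               use_absolute = FALSE) {
  d <- stats::setNames(effects$d, effects$gene)
  eligible <- effects$gene[!is.na(effects$d) & abs(effects$d) > es_cutoff]
  qual <- Filter(function(r) {
    r$tf %in% study_genes(study) && !is.na(d[r$tf]) &&
      abs(d[r$tf]) > es_cutoff
  }, regulons)
  if (length(qual) == 0L) {
    message("no TF passes the effect-size gate; empty result")
    return(empty_regulatory_table())
  }
  rows <- lapply(qual, function(r) {
    pool <- other_targets_pool(regulons, r$tf)
    re <- regulatory_effect_test(study, r, eligible, nontarget_pool = pool,
                                 use_absolute = use_absolute,
                                 min_targets = min_targets)
    as.data.frame(unclass(re), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass <- !out$untestable & !is.na(out$p) & out$p < alpha
  out
}

empty_regulatory_table <- function() {
  data.frame(tf = character(0), motif = character(0), p = numeric(0),
             direction = character(0), n_targets_tested = integer(0),
             n_nontargets = integer(0), median_target_r = numeric(0),
             median_nontarget_r = numeric(0), untestable = logical(0),
             pass = logical(0), stringsAsFactors = FALSE)
}

#' Global significance of the number of passing TFs by regulon permutation
#'
#' Permutes TF-target relationships: each permutation applies a random
#' bijection of the eligible annotated genes (the union of all eligible
#' target sets) to every regulon's eligible target set, preserving
#' target-set sizes and overlap structure, then re-runs the regulatory
#' effect test for every qualifying regulon and records how many pass.
#'
#' @inheritParams scan_tf_regulators
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed_pass` (count in the unpermuted data),
#'   `perm_pass` (per-permutation counts), `expected_pass_count` (their
#'   mean) and `global_p` (fraction of permutations with at least the
#'   observed count).
#' @export
permute_regulon_labels <- function(study, regulons, effects, es_cutoff = 0.8,
                                   alpha = 0.01, min_targets = 5,
                                   n_perm = 1000, seed = 1,
                                   use_absolute = FALSE) {
  if (length(regulons) < 2L) stop("need at least 2 regulons")
  local_seed_if(seed)
  d <- stats::setNames(effects$d, effects$gene)
  eligible <- effects$gene[!is.na(effects$d) & abs(effects$d) > es_cutoff]
  qual <- Filter(function(r) {
    r$tf %in% study_genes(study) && !is.na(d[r$tf]) &&
      abs(d[r$tf]) > es_cutoff
  }, regulons)
  pool <- intersect(
    unique(unlist(lapply(regulons, `[[`, "targets"))),
    intersect(eligible, study_genes(study))
  )
  # precompute, per qualifying TF, its correlation with every pool gene and
  # its target / non-target index sets within the pool
  prep <- lapply(qual, function(r) {
    tfp <- study$values[r$tf, ]
    rr <- as.vector(stats::cor(tfp, t(study$values[pool, , drop = FALSE])))
    t_idx <- which(pool %in% setdiff(r$targets, r$tf))
    nt_idx <- which(pool %in% setdiff(other_targets_pool(regulons, r$tf),
                                      c(r$targets, r$tf)))
    list(r = rr, t_idx = t_idx, nt_idx = nt_idx, self = match(r$tf, pool))
  })
  pass_count <- function(perm) {
    sum(vapply(prep, function(pr) {
      ti <- perm[pr$t_idx]; nti <- perm[pr$nt_idx]
      if (!is.na(pr$self)) {
        ti <- setdiff(ti, pr$self); nti <- setdiff(nti, pr$self)
      }
      if (length(ti) < min_targets || length(nti) < 1L) return(FALSE)
      if (use_absolute) {
        p <- ranksum_test(abs(pr$r[ti]), abs(pr$r[nti]),
                          alternative = "greater")$p.value
      } else {
        p <- ranksum_test(pr$r[ti], pr$r[nti])$p.value
      }
      p < alpha
    }, logical(1)))
  }
  observed <- pass_count(seq_along(pool))
  perm_pass <- vapply(seq_len(n_perm), function(i)
    pass_count(sample(length(pool))), integer(1))
  list(observed_pass = observed, perm_pass = perm_pass,
       expected_pass_count = mean(perm_pass),
       global_p = mean(perm_pass >= observed))
}

#' Correlation of TF-target correlations between two cohorts
#'
#' For every regulon target eligible in both cohorts, computes the Pearson
#' correlation between the TF and the target within each cohort, then
#' correlates the two per-target correlation vectors with Spearman's rho.
#' Consistent positive rho across independent cohorts indicates a conserved
#' regulatory relationship.
#'
#' @param a,b [expression_study()] cohorts (both containing the TF).
#' @param regulon a [tf_regulon()].
#' @param eligible_a,eligible_b per-cohort eligible gene sets
#'   (`|d| > 0.8`).
#' @return list of class `CoCResult`: `tf`, `motif`, `rho`, `p`,
#'   `n_shared_targets`, `target_r` (data.frame of per-target r in each
#'   cohort), `untestable` (TRUE when fewer than 3 shared targets).
#' @export
correlation_of_correlations <- function(a, b, regulon, eligible_a,
                                        eligible_b) {
  shared <- Reduce(intersect, list(regulon$targets, eligible_a, eligible_b,
                                   study_genes(a), study_genes(b)))
  shared <- setdiff(shared, regulon$tf)
  res <- list(tf = regulon$tf, motif = regulon$motif, rho = NA_real_,
              p = NA_real_, n_shared_targets = length(shared),
              target_r = NULL, untestable = length(shared) < 3L)
  if (res$untestable) {
    class(res) <- "CoCResult"
    return(res)
  }
  r_a <- as.vector(stats::cor(a$values[regulon$tf, ],
                              t(a$values[shared, , drop = FALSE])))
  r_b <- as.vector(stats::cor(b$values[regulon$tf, ],
                              t(b$values[shared, , drop = FALSE])))
  st <- spearman_test(r_a, r_b)
  res$rho <- st$rho
  res$p <- st$p
  res$target_r <- data.frame(gene = shared, r_a = r_a, r_b = r_b,
                             stringsAsFactors = FALSE)
  class(res) <- "CoCResult"
  res
}

#' @export
print.CoCResult <- function(x, ...) {
  if (x$untestable) {
    cat(sprintf("CoC %s [%s]: untestable (%d shared targets)\n", x$tf,
                x$motif, x$n_shared_targets))
  } else {
    cat(sprintf("CoC %s [%s]: Spearman rho = %.3f, p = %.3g over %d shared targets\n",
                x$tf, x$motif, x$rho, x$p, x$n_shared_targets))
  }
  invisible(x)
}

#' Global significance of a TF's cross-cohort CoC by regulon permutation
#'
#' Permutes TF-target relationships over genes eligible in both cohorts
#' (random bijection of the annotated eligible pool applied to the focal
#' regulon's targets), recomputes the CoC each round, and reports the
#' fraction of permutations whose CoC is at least as significant as
#' observed.
#'
#' @inheritParams correlation_of_correlations
#' @param regulons full regulon list (defines the annotated gene pool).
#' @param focal_tf TF whose regulon is assessed.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed` (the focal `CoCResult`), `global_p`, and
#'   `perm_p` (per-permutation CoC p-values).
#' @export
coc_global_significance <- function(a, b, regulons, focal_tf, eligible_a,
                                    eligible_b, n_perm = 1000, seed = 1) {
  local_seed_if(seed)
  focal <- Filter(function(r) r$tf == focal_tf, regulons)
  if (length(focal) == 0L) stop("focal TF has no regulon")
  focal <- focal[[1L]]
  obs <- correlation_of_correlations(a, b, focal, eligible_a, eligible_b)
  if (obs$untestable) stop("focal regulon untestable (<3 shared targets)")
  pool <- Reduce(intersect, list(
    unique(unlist(lapply(regulons, `[[`, "targets"))),
    eligible_a, eligible_b, study_genes(a), study_genes(b)))
  pool <- setdiff(pool, focal_tf)
  t_idx <- which(pool %in% obs$target_r$gene)
  r_a_pool <- as.vector(stats::cor(a$values[focal_tf, ],
                                   t(a$values[pool, , drop = FALSE])))
  r_b_pool <- as.vector(stats::cor(b$values[focal_tf, ],
                                   t(b$values[pool, , drop = FALSE])))
  perm_p <- vapply(seq_len(n_perm), function(i) {
    idx <- sample(length(pool))[seq_along(t_idx)]
    spearman_test(r_a_pool[idx], r_b_pool[idx])$p
  }, numeric(1))
  list(observed = obs, global_p = mean(perm_p <= obs$p), perm_p = perm_p)
}

#' Excess of common candidate TFs between two cohorts
#'
#' One-sided Fisher's exact test for the overlap of the candidate TF sets
#' from two cohorts over a background of TFs testable in both.
#'
#' @param candidates_a,candidates_b candidate TF sets.
#' @param background_tfs TFs detected/testable in both cohorts.
#' @return list with `odds_ratio` and `p`.
#' @export
common_candidate_excess <- function(candidates_a, candidates_b,
                                    background_tfs) {
  overlap_test(candidates_a, candidates_b, background_tfs)
}
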