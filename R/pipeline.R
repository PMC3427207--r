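#' Run the full analysis pipeline from a declarative config
#'
#' Orchestrates, in dependency order: synthetic-data simulation (or input
#' loading), preprocessing (log/quantile normalization, detection filter,
#' batch removal), permutation-calibrated differential expression and
#' effect sizes per cohort, cross-cohort consistent DE and overlap, TF
#' regulatory-effect scans with regulon-permutation global significance,
#' cross-cohort correlation of correlations for candidate TFs, optional
#' motif/tissue-specificity/enrichment stages, and writes per-stage TSV and
#' JSON results plus a manifest (seeds, thresholds, gene-count funnel, file
#' checksums).
#'
#' The single `seed` is expanded into fixed per-stage seeds
#' (`seed + stage offset`, offsets 100, 200, ...) so every stochastic stage
#' is independently reproducible.
#'
#' @param config nested list, or path to a JSON file with the same
#'   structure. Recognized top-level entries: `seed`; `simulate` (list of
#'   [scenario_config()] arguments); `inputs` (paths: `expr_a`, `meta_a`,
#'   `expr_b`, `meta_b`, `regulons`, and optionally `promoters`,
#'   `conservation`, `dnase`, `pwm`, `atlas_a`, `atlas_b`, `annotation`);
#'   `thresholds` (`fdr` 0.10, `es` 0.8, `tf_alpha` 0.01, `min_coverage`
#'   0.8, `min_conservation` 0.6, `gc_floor` 0.79, `min_score` 0.85,
#'   `min_core_score` 0.90); `n_perm` (`de`, `tf`, `coc`, `motif_batches`,
#'   `enrich` counts).
#' @param out_dir run directory (created; must not pre-exist unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (dir.exists(out_dir) && !overwrite)
    stop("`out_dir` exists; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  th <- utils::modifyList(
    list(fdr = 0.10, es = 0.8, tf_alpha = 0.01, min_coverage = 0.8,
         min_conservation = 0.6, gc_floor = 0.79, min_score = 0.85,
         min_core_score = 0.90, min_targets = 5),
    config$thresholds %||% list())
  np <- utils::modifyList(
    list(de = 200, tf = 200, coc = 200, motif_batches = 100, enrich = 200),
    config$n_perm %||% list())
  manifest <- list(package = "regulonscan",
                   version = as.character(utils::packageVersion("regulonscan")),
                   seed = seed, thresholds = th, n_perm = np,
                   counts = list(), stages = character(0))
  log_info <- function(...) message(sprintf(...))

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    log_info("stage simulate: seed %d", seed + 100L)
    sim_args <- config$simulate
    sim_args$seed <- seed + 100L
    cfg <- do.call(scenario_config, sim_args)
    scen <- generate_regulatory_scenario(cfg)
    a <- scen$cohort_a; b <- scen$cohort_b; regulons <- scen$regulons
    write_expression_tsv(a, file.path(out_dir, "cohort_a_expr.tsv"),
                         file.path(out_dir, "cohort_a_meta.tsv"))
    write_expression_tsv(b, file.path(out_dir, "cohort_b_expr.tsv"),
                         file.path(out_dir, "cohort_b_meta.tsv"))
    write_regulon_tsv(regulons, file.path(out_dir, "regulons.tsv"))
    truth <- data.frame(gene = names(scen$truth$planted_d),
                        planted_d = scen$truth$planted_d)
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    contrast <- c("A", "B")
  } else {
    ip <- config$inputs
    if (is.null(ip)) stop("config needs either `simulate` or `inputs`")
    a <- read_expression_tsv(ip$expr_a, ip$meta_a)
    b <- read_expression_tsv(ip$expr_b, ip$meta_b)
    regulons <- read_regulon_tsv(ip$regulons)
    contrast <- config$contrast %||% stop("config needs `contrast`")
  }
  manifest$stages <- c(manifest$stages, "inputs")
  manifest$counts$genes_a <- nrow(a$values)
  manifest$counts$genes_b <- nrow(b$values)

  # --- stage: preprocess ---------------------------------------------------
  prep <- function(st) {
    if (isTRUE(config$normalize)) st <- log_quantile_normalize(
      st, pseudocount = config$pseudocount %||% 0)
    if (!is.null(st$detection_p)) st <- filter_detected(st)
    if (!is.null(st$batch)) st <- remove_batch_effect(st)
    st
  }
  a <- prep(a); b <- prep(b)
  manifest$stages <- c(manifest$stages, "preprocess")
  manifest$counts$detected_a <- nrow(a$values)
  manifest$counts$detected_b <- nrow(b$values)
  log_info("stage preprocess: %d / %d genes retained",
           nrow(a$values), nrow(b$values))

  # --- stage: differential expression --------------------------------------
  eff_a <- test_differential(a, contrast)
  eff_b <- test_differential(b, contrast)
  cal_a <- calibrate_permutation_fdr(a, contrast, n_perm = np$de,
                                     target_fdr = th$fdr, seed = seed + 200L)
  cal_b <- calibrate_permutation_fdr(b, contrast, n_perm = np$de,
                                     target_fdr = th$fdr, seed = seed + 201L)
  for (nm in c("a", "b")) {
    eff <- get(paste0("eff_", nm)); cal <- get(paste0("cal_", nm))
    eff$significant <- eff$gene %in% cal$significant
    utils::write.table(eff, file.path(out_dir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(cutoff_p = cal$cutoff_p, n_observed = cal$n_observed,
           target_fdr = cal$target_fdr, n_perm = cal$n_perm,
           seed = cal$seed,
           perm_count_median = stats::median(cal$perm_counts)),
      file.path(out_dir, paste0("fdr_calibration_", nm, ".json")),
      auto_unbox = TRUE, na = "null")
  }
  consistent <- consistent_de(
    within(eff_a, p <- ifelse(gene %in% cal_a$significant, 0, 1)),
    within(eff_b, p <- ifelse(gene %in% cal_b$significant, 0, 1)),
    rule = "fdr_both", cutoffs = c(0.5, 0.5))
  es_consistent <- consistent_de(eff_a, eff_b, rule = "es_both",
                                 cutoffs = th$es)
  shared <- intersect(eff_a$gene, eff_b$gene)
  ov <- overlap_test(cal_a$significant, cal_b$significant, shared)
  manifest$stages <- c(manifest$stages, "de")
  manifest$counts$significant_a <- cal_a$n_observed
  manifest$counts$significant_b <- cal_b$n_observed
  manifest$counts$consistent_fdr <- length(consistent)
  manifest$counts$consistent_es <- length(es_consistent)
  manifest$de_overlap <- ov
  log_info("stage de: %d + %d significant, %d consistent (FDR), %d (effect size)",
           cal_a$n_observed, cal_b$n_observed, length(consistent),
           length(es_consistent))

  # --- stage: tf scan ------------------------------------------------------
  scan_a <- scan_tf_regulators(a, regulons, eff_a, es_cutoff = th$es,
                               alpha = th$tf_alpha,
                               min_targets = th$min_targets)
  scan_b <- scan_tf_regulators(b, regulons, eff_b, es_cutoff = th$es,
                               alpha = th$tf_alpha,
                               min_targets = th$min_targets)
  utils::write.table(scan_a, file.path(out_dir, "tf_scan_a.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan_b, file.path(out_dir, "tf_scan_b.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  glob_a <- permute_regulon_labels(a, regulons, eff_a, es_cutoff = th$es,
                                   alpha = th$tf_alpha,
                                   min_targets = th$min_targets,
                                   n_perm = np$tf, seed = seed + 300L)
  cand_a <- scan_a$tf[scan_a$pass]
  cand_b <- scan_b$tf[scan_b$pass]
  bg_tfs <- intersect(
    unique(vapply(regulons, `[[`, "", "tf")),
    intersect(study_genes(a), study_genes(b)))
  common <- common_candidate_excess(cand_a, cand_b, bg_tfs)
  manifest$stages <- c(manifest$stages, "tf_scan")
  manifest$counts$candidates_a <- length(unique(cand_a))
  manifest$counts$candidates_b <- length(unique(cand_b))
  manifest$tf_global <- list(observed_pass = glob_a$observed_pass,
                             expected_pass_count = glob_a$expected_pass_count,
                             global_p = glob_a$global_p)
  manifest$common_candidates <- list(
    tfs = intersect(unique(cand_a), unique(cand_b)),
    odds_ratio = common$odds_ratio, p = common$p)
  log_info("stage tf_scan: %d / %d candidates, global p = %.3g",
           length(unique(cand_a)), length(unique(cand_b)), glob_a$global_p)

  # --- stage: coc ----------------------------------------------------------
  eligible_a <- eff_a$gene[!is.na(eff_a$d) & abs(eff_a$d) > th$es]
  eligible_b <- eff_b$gene[!is.na(eff_b$d) & abs(eff_b$d) > th$es]
  coc_tfs <- union(unique(cand_a), unique(cand_b))
  coc_rows <- list()
  for (tf in coc_tfs) {
    reg <- Filter(function(r) r$tf == tf, regulons)
    for (r in reg) {
      cr <- correlation_of_correlations(a, b, r, eligible_a, eligible_b)
      gp <- NA_real_
      if (!cr$untestable) {
        gp <- coc_global_significance(a, b, regulons, tf, eligible_a,
                                      eligible_b, n_perm = np$coc,
                                      seed = seed + 400L)$global_p
      }
      coc_rows[[length(coc_rows) + 1L]] <-
        data.frame(tf = tf, motif = r$motif, rho = cr$rho, p = cr$p,
                   n_shared_targets = cr$n_shared_targets, global_p = gp,
                   stringsAsFactors = FALSE)
    }
  }
  coc_tab <- if (length(coc_rows)) do.call(rbind, coc_rows) else
    data.frame(tf = character(0), motif = character(0), rho = numeric(0),
               p = numeric(0), n_shared_targets = integer(0),
               global_p = numeric(0))
  utils::write.table(coc_tab, file.path(out_dir, "coc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages <- c(manifest$stages, "coc")

  # --- optional stages -----------------------------------------------------
  ip <- config$inputs
  if (!is.null(ip$promoters) && !is.null(ip$pwm)) {
    if (is.null(ip$conservation))
      stop("motif stage requested but no conservation file given")
    promoters <- read_promoters_fasta(ip$promoters, ip$conservation)
    pwms <- read_transfac_pwm(ip$pwm)
    tf_map <- stats::setNames(
      vapply(regulons, `[[`, "", "tf"),
      vapply(regulons, `[[`, "", "motif"))
    pred <- predict_regulons(promoters, pwms, tf_map,
                             min_score = th$min_score,
                             min_core_score = th$min_core_score,
                             min_coverage = th$min_coverage,
                             min_mean = th$min_conservation)
    write_regulon_tsv(pred, file.path(out_dir, "predicted_regulons.tsv"))
    all_sites <- do.call(rbind, lapply(pred, `[[`, "sites"))
    if (!is.null(all_sites) && nrow(all_sites)) {
      tss <- tss_proximity_test(all_sites)
      manifest$tss_proximity <- tss
      bsn <- binding_site_null(promoters, pwms[[1]],
                               n_batches = np$motif_batches,
                               min_score = th$min_score,
                               min_core_score = th$min_core_score,
                               min_coverage = th$min_coverage,
                               min_mean = th$min_conservation,
                               seed = seed + 500L)
      manifest$binding_site_null <- bsn[c("observed", "expected_count",
                                          "fdr")]
      if (!is.null(ip$dnase)) {
        dn <- read_bed_intervals(ip$dnase, promoters)
        manifest$dnase_overlap <- dnase_overlap_test(
          all_sites, dn, promoters, gc_floor = th$gc_floor,
          n_rand = np$motif_batches, seed = seed + 501L
        )[c("n_genes_overlapping", "expected", "p")]
      }
    }
    manifest$stages <- c(manifest$stages, "motif")
  }
  if (!is.null(ip$atlas_a) && !is.null(ip$atlas_b)) {
    at_a <- read_atlas_tsv(ip$atlas_a, "speciesA",
                           config$focal_tissue %||% "liver")
    at_b <- read_atlas_tsv(ip$atlas_b, "speciesB",
                           config$focal_tissue %||% "liver")
    z_a <- specificity_z(at_a); z_b <- specificity_z(at_b)
    fg <- config$specificity_foreground %||% es_consistent
    bgset <- setdiff(intersect(names(z_a), names(z_b)), fg)
    if (length(intersect(fg, names(z_a))) && length(bgset)) {
      sp <- compare_specificity(z_a, z_b, intersect(fg, names(z_a)), bgset)
      manifest$specificity <- list(p = sp$p, shift = sp$shift_applied,
                                   n_foreground = sp$n_foreground)
    }
    manifest$stages <- c(manifest$stages, "specificity")
  }
  if (!is.null(ip$annotation)) {
    ann <- read_annotation_tsv(ip$annotation)
    test_set <- es_consistent
    bgset <- setdiff(shared, test_set)
    enr <- resampling_fdr(test_set, bgset, ann, n_resample = np$enrich,
                          seed = seed + 600L)
    utils::write.table(enr$observed,
                       file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$enrichment <- list(grid = enr$grid,
                                reporting_cutoff = enr$reporting_cutoff)
    manifest$stages <- c(manifest$stages, "enrichment")
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null", digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Validate pipeline input files
#'
#' Checks matrix/metadata consistency, FASTA/conservation/BED coherence
#' (track lengths, coordinate bounds) and that regulon TF/target references
#' resolve against the expression matrices. Nothing fails: all violations
#' are listed in the returned report.
#'
#' @param paths named list of file paths, as in `config$inputs` of
#'   [run_pipeline()].
#' @return data.frame with columns `file`, `problem` (zero rows when
#'   clean).
#' @export
validate_inputs <- function(paths) {
  probs <- list()
  note <- function(file, problem)
    probs[[length(probs) + 1L]] <<- data.frame(file = file,
                                               problem = problem,
                                               stringsAsFactors = FALSE)
  studies <- list()
  for (side in c("a", "b")) {
    ek <- paste0("expr_", side); mk <- paste0("meta_", side)
    if (is.null(paths[[ek]])) next
    expr <- utils::read.delim(paths[[ek]], check.names = FALSE)
    meta <- utils::read.delim(paths[[mk]])
    miss <- setdiff(colnames(expr)[-1], meta$sample)
    if (length(miss))
      note(paths[[mk]], paste("samples missing from metadata:",
                              paste(miss, collapse = ",")))
    extra <- setdiff(meta$sample, colnames(expr)[-1])
    if (length(extra))
      note(paths[[mk]], paste("metadata samples missing from matrix:",
                              paste(extra, collapse = ",")))
    studies[[side]] <- expr[[1]]
  }
  if (!is.null(paths$regulons)) {
    tab <- utils::read.delim(paths$regulons)
    for (side in names(studies)) {
      bad <- setdiff(unique(tab$tf), studies[[side]])
      if (length(bad))
        note(paths$regulons,
             sprintf("%d TF(s) absent from cohort %s matrix", length(bad),
                     side))
    }
  }
  if (!is.null(paths$promoters)) {
    proms <- tryCatch(
      read_promoters_fasta(paths$promoters, paths$conservation),
      error = function(e) { note(paths$promoters, conditionMessage(e)); NULL })
    if (!is.null(proms) && !is.null(paths$dnase)) {
      iv <- tryCatch(read_bed_intervals(paths$dnase, proms),
                     error = function(e) {
                       note(paths$dnase, conditionMessage(e)); NULL })
      if (!is.null(iv)) {
        lens <- stats::setNames(
          vapply(proms, function(p) nchar(p$sequence), 1L),
          vapply(proms, `[[`, "", "gene"))
        tss <- stats::setNames(vapply(proms, `[[`, 1L, "tss_offset"),
                               vapply(proms, `[[`, "", "gene"))
        known <- iv$gene %in% names(lens)
        if (any(!known))
          note(paths$dnase, sprintf("%d interval(s) on unknown genes",
                                    sum(!known)))
        iv <- iv[known, , drop = FALSE]
        out_of_bounds <- iv$start + tss[iv$gene] < 1 |
          iv$end + tss[iv$gene] - 1 > lens[iv$gene]
        if (any(out_of_bounds))
          note(paths$dnase, sprintf("%d interval(s) beyond promoter bounds",
                                    sum(out_of_bounds)))
      }
    }
  }
  if (length(probs) == 0L)
    return(data.frame(file = character(0), problem = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, probs)
}
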