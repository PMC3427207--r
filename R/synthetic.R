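#' Configuration for a synthetic regulatory scenario
#'
#' Describes the stated world of the generator: two cohorts of two
#' contrasted groups whose "driver" TFs shift between groups and drag their
#' targets along through expression coupling, with batch structure and
#' planted per-gene effect sizes.
#'
#' Expression is generated on a log-like additive scale: gene values are
#' Gaussian with SD `noise_sd`, batch effects are additive gene-wise
#' offsets, and planted group differences are mean shifts of
#' `planted_effect_size` pooled-SD units. Every TF (driver or not) carries
#' a planted shift so that it passes the downstream effect-size gate; all
#' non-driver-TF targets carry independent planted shifts (making them
#' eligible non-targets) but are uncoupled from their TF. Driver targets
#' additionally follow the TF profile with correlation strength
#' `tf_target_coupling`.
#'
#' @param n_genes total genes (TFs included).
#' @param n_tfs number of TFs (the first `n_tfs` genes).
#' @param samples_per_group samples in each of the two groups, per cohort.
#' @param n_batches batches per cohort (samples assigned round-robin).
#' @param planted_effect_size planted between-group shift in pooled-SD
#'   units (Cohen's d).
#' @param driver_tfs integer indices (within `1:n_tfs`) of driver TFs.
#' @param targets_per_tf targets per TF; recycled over TFs, so drivers may
#'   get a different regulon size than the rest.
#' @param tf_target_coupling correlation strength in `[0, 1]` between a
#'   driver TF and its targets.
#' @param noise_sd residual expression SD.
#' @param sign_mix fraction of driver targets coupled with negative sign
#'   (signs are shared between cohorts; default 0, all positive).
#' @param batch_sd SD of the additive gene-wise batch offsets (default
#'   `noise_sd / 2`).
#' @param seed integer seed; the whole scenario is reproducible from it.
#' @return validated list of class `ScenarioConfig`.
#' @export
scenario_config <- function(n_genes = 2000, n_tfs = 20,
                            samples_per_group = 6, n_batches = 2,
                            planted_effect_size = 1.5, driver_tfs = 1L,
                            targets_per_tf = 30, tf_target_coupling = 0.7,
                            noise_sd = 1, sign_mix = 0,
                            batch_sd = noise_sd / 2, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              samples_per_group = as.integer(samples_per_group),
              n_batches = as.integer(n_batches),
              planted_effect_size = planted_effect_size,
              driver_tfs = as.integer(driver_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              tf_target_coupling = tf_target_coupling,
              noise_sd = noise_sd, sign_mix = sign_mix,
              batch_sd = batch_sd, seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_genes, n_tfs, samples_per_group, n_batches) <= 0L))
      stop("counts must be positive")
    if (tf_target_coupling < 0 || tf_target_coupling > 1)
      stop("`tf_target_coupling` must be in [0, 1]")
    if (noise_sd <= 0) stop("`noise_sd` must be > 0")
    if (length(driver_tfs) && any(driver_tfs > n_tfs))
      stop("`driver_tfs` out of range")
    if (n_tfs + sum(rep_len(targets_per_tf, n_tfs)) > n_genes)
      stop("targets_per_tf x n_tfs exceeds n_genes")
  })
  class(cfg) <- "ScenarioConfig"
  cfg
}

#' Generate a synthetic two-cohort regulatory scenario
#'
#' Produces two independent cohorts with identical planted structure and a
#' shared regulon annotation, plus ground-truth labels for
#' parameter-recovery tests. See [scenario_config()] for the generative
#' model.
#'
#' @param config a [scenario_config()].
#' @return list of class `SyntheticStudy` with `cohort_a`, `cohort_b`
#'   ([expression_study()] objects, groups `"A"`/`"B"`), `regulons` (list
#'   of [tf_regulon()]), and `truth` (list: `planted_d` per gene, `driver`
#'   per TF, `coupling_sign` per driver target).
#' @export
generate_regulatory_scenario <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  local_seed_if(config$seed)
  n <- config$n_genes
  genes <- c(sprintf("TF%03d", seq_len(config$n_tfs)),
             sprintf("g%05d", seq_len(n - config$n_tfs)))
  tfs <- genes[seq_len(config$n_tfs)]
  sizes <- rep_len(config$targets_per_tf, config$n_tfs)
  pool <- genes[-seq_len(config$n_tfs)]
  stopifnot(sum(sizes) <= length(pool))
  # disjoint target sets drawn from the non-TF genes
  shuffled <- sample(pool)
  splits <- rep(seq_len(config$n_tfs), times = sizes)
  target_sets <- split(shuffled[seq_along(splits)], splits)
  names(target_sets) <- tfs
  regulons <- lapply(tfs, function(tf)
    tf_regulon(tf, paste0("M_", tf), target_sets[[tf]]))
  driver <- stats::setNames(seq_len(config$n_tfs) %in% config$driver_tfs,
                            tfs)
  # planted per-gene effect size: all TFs, and all targets, carry a shift
  d <- config$planted_effect_size
  sd0 <- config$noise_sd
  planted_d <- stats::setNames(rep(0, n), genes)
  planted_d[tfs] <- d
  coupling_sign <- list()
  for (tf in tfs) {
    tg <- target_sets[[tf]]
    if (driver[tf]) {
      sg <- ifelse(stats::runif(length(tg)) < config$sign_mix, -1, 1)
      coupling_sign[[tf]] <- stats::setNames(sg, tg)
      # driver targets inherit the shift through the coupling
      planted_d[tg] <- sg * config$tf_target_coupling * d
    } else {
      planted_d[tg] <- sample(c(-d, d), length(tg), replace = TRUE)
    }
  }
  gen_cohort <- function(dataset) {
    n_s <- 2L * config$samples_per_group
    group <- rep(c("A", "B"), each = config$samples_per_group)
    batch <- paste0("b", rep_len(seq_len(config$n_batches), n_s))
    shift_sample <- ifelse(group == "A", d * sd0 / 2, -d * sd0 / 2)
    vals <- matrix(stats::rnorm(n * n_s, sd = sd0), nrow = n,
                   dimnames = list(genes, sprintf("%s_s%02d", dataset,
                                                  seq_len(n_s))))
    # TFs: between-group shift for every TF (drivers and non-drivers)
    for (tf in tfs)
      vals[tf, ] <- vals[tf, ] + shift_sample
    # driver targets: coupled to the TF profile
    cc <- config$tf_target_coupling
    for (tf in tfs[driver]) {
      tfp <- vals[tf, ]
      for (tg in target_sets[[tf]]) {
        s <- coupling_sign[[tf]][tg]
        vals[tg, ] <- s * cc * tfp +
          sqrt(1 - cc^2) * stats::rnorm(n_s, sd = sd0)
      }
    }
    # non-driver targets: independent own shifts
    for (tf in tfs[!driver]) {
      for (tg in target_sets[[tf]])
        vals[tg, ] <- vals[tg, ] + sign(planted_d[tg]) * shift_sample
    }
    # additive gene-wise batch offsets
    for (b in unique(batch)) {
      off <- stats::rnorm(n, sd = config$batch_sd)
      idx <- which(batch == b)
      vals[, idx] <- vals[, idx] + off
    }
    expression_study(vals, group = group, batch = batch, dataset = dataset)
  }
  out <- list(cohort_a = gen_cohort("cohortA"),
              cohort_b = gen_cohort("cohortB"),
              regulons = regulons,
              truth = list(planted_d = planted_d, driver = driver,
                           coupling_sign = coupling_sign),
              config = config)
  class(out) <- "SyntheticStudy"
  out
}

#' @export
print.SyntheticStudy <- function(x, ...) {
  cat(sprintf("SyntheticStudy: %d genes, %d TFs (%d driver), 2 cohorts of %d samples\n",
              x$config$n_genes, x$config$n_tfs, sum(x$truth$driver),
              2L * x$config$samples_per_group))
  invisible(x)
}

#' Expected TF-target correlation under the generative model
#'
#' Closed form implied by the generator: the target equals
#' `coupling * TF + sqrt(1 - coupling^2) * noise`, and the TF profile has
#' variance `noise_sd^2 * (1 + d^2/4)` across equally sized groups, so the
#' correlation is \eqn{c \sqrt{v} / \sqrt{c^2 v + 1 - c^2}} with
#' \eqn{v = 1 + d^2/4}.
#'
#' @param coupling coupling strength `c`.
#' @param d planted effect size of the TF.
#' @return expected Pearson correlation between TF and target profiles.
#' @export
expected_target_correlation <- function(coupling, d) {
  v <- 1 + d^2 / 4
  coupling * sqrt(v) / sqrt(coupling^2 * v + 1 - coupling^2)
}

#' Generate synthetic promoters with planted motif matches
#'
#' Backgrounds are i.i.d. bases at the stated G/C fraction; planted
#' positions carry the PWM consensus (reverse-complemented on the minus
#' strand) with high per-base conservation (Uniform(0.75, 1), mean >= 0.6),
#' while background conservation is drawn from Beta(1, 3) with a fraction
#' of positions missing. The record spans TSS-length/2 .. TSS+length/2.
#'
#' @param n_genes number of promoters (genes `p00001`, ...).
#' @param length window size in bp (default 4000, i.e. +/- 2000 around the
#'   TSS).
#' @param planted data.frame with columns `gene`, `offset` (TSS-relative
#'   leftmost base of the site), `strand`; or `NULL`.
#' @param pwm [pwm_matrix()] whose consensus is planted.
#' @param gc background G/C fraction.
#' @param missing_fraction fraction of background bases without a
#'   conservation score.
#' @param seed RNG seed.
#' @return list of [promoter_record()] objects (each carries its `planted`
#'   table).
#' @export
generate_promoters <- function(n_genes, length = 4000, planted = NULL,
                               pwm = NULL, gc = 0.5,
                               missing_fraction = 0.1, seed = 1) {
  local_seed_if(seed)
  tss <- as.integer(length / 2)
  genes <- sprintf("p%05d", seq_len(n_genes))
  if (!is.null(planted)) {
    stopifnot(!is.null(pwm),
              all(planted$gene %in% genes),
              all(abs(planted$offset) <= length / 2),
              pwm$width <= length)
    cons_seq <- pwm_consensus(pwm)
  }
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lapply(genes, function(g) {
    chars <- sample(names(base_p), length, replace = TRUE, prob = base_p)
    cons <- stats::rbeta(length, 1, 3)
    cons[stats::runif(length) < missing_fraction] <- NA_real_
    pl <- NULL
    if (!is.null(planted)) {
      pl <- planted[planted$gene == g, , drop = FALSE]
      if (nrow(pl) > 1L) {
        o <- order(pl$offset)
        if (any(diff(pl$offset[o]) < pwm$width))
          stop(sprintf("overlapping planted sites on gene '%s'", g))
      }
      for (i in seq_len(nrow(pl))) {
        s <- cons_seq
        if (pl$strand[i] == "-")
          s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        idx <- (tss + pl$offset[i]):(tss + pl$offset[i] + pwm$width - 1L)
        if (idx[1] < 1L || idx[length(idx)] > length)
          stop("planted site outside promoter window")
        chars[idx] <- strsplit(s, "")[[1]]
        cons[idx] <- stats::runif(pwm$width, 0.75, 1)
      }
    }
    promoter_record(g, paste(chars, collapse = ""), tss_offset = tss,
                    conservation = cons, planted = pl)
  })
}

#' Generate synthetic open-chromatin (DNase) interval tracks
#'
#' Per promoter: optional intervals covering every planted site, plus
#' random background intervals (150 bp) until approximately
#' `background_fraction` of promoter bases are covered.
#'
#' @param promoters list of [promoter_record()] objects (from
#'   [generate_promoters()]).
#' @param cover_planted if TRUE, each planted site lies within an interval.
#' @param background_fraction target fractional coverage of background
#'   intervals.
#' @param site_width width assumed for planted sites (taken from the
#'   planted table's PWM; default 14).
#' @param seed RNG seed.
#' @return data.frame of intervals: `gene`, `start`, `end` (TSS-relative,
#'   half-open).
#' @export
generate_dnase_tracks <- function(promoters, cover_planted = TRUE,
                                  background_fraction = 0.06,
                                  site_width = 14, seed = 1) {
  local_seed_if(seed)
  stopifnot(background_fraction >= 0, background_fraction <= 1)
  iv_w <- 150L
  rows <- list()
  for (pr in promoters) {
    L <- nchar(pr$sequence)
    tss <- pr$tss_offset
    if (cover_planted && !is.null(pr$planted) && nrow(pr$planted)) {
      pad <- 20L
      for (i in seq_len(nrow(pr$planted))) {
        st <- max(pr$planted$offset[i] - pad, 1L - tss)
        en <- min(pr$planted$offset[i] + site_width + pad, L - tss)
        rows[[length(rows) + 1L]] <-
          data.frame(gene = pr$gene, start = st, end = en)
      }
    }
    n_iv <- round(background_fraction * L / iv_w)
    if (n_iv > 0) {
      starts <- sample.int(L - iv_w, n_iv) - tss
      rows[[length(rows) + 1L]] <-
        data.frame(gene = pr$gene, start = starts, end = starts + iv_w)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a paired two-species tissue atlas
#'
#' Both atlases are i.i.d. Gaussian (per-gene cross-tissue SD about 1); in
#' species 2 the focal-tissue value of `specific_genes` is raised by
#' `shift` standard deviations, everything else being exchangeable between
#' species.
#'
#' @param n_genes genes (shared identifiers across species).
#' @param n_tissues_a,n_tissues_b tissue counts for the two species
#'   (defaults 79 and 61, the sizes of the classical human and mouse
#'   multi-tissue expression atlases).
#' @param specific_genes genes given the species-2 focal shift.
#' @param shift z-score units added (must be >= 0).
#' @param focal_tissue tissue name (default `"liver"`).
#' @param seed RNG seed.
#' @return list with [tissue_atlas()] elements `species_a`, `species_b`.
#' @export
generate_tissue_atlas <- function(n_genes, n_tissues_a = 79,
                                  n_tissues_b = 61,
                                  specific_genes = character(0), shift = 0,
                                  focal_tissue = "liver", seed = 1) {
  local_seed_if(seed)
  stopifnot(shift >= 0)
  genes <- sprintf("g%05d", seq_len(n_genes))
  mk <- function(n_t, species, shifted) {
    tn <- c(focal_tissue, sprintf("tissue%02d", seq_len(n_t - 1L)))
    v <- matrix(stats::rnorm(n_genes * n_t), nrow = n_genes,
                dimnames = list(genes, tn))
    if (length(shifted))
      v[shifted, focal_tissue] <- v[shifted, focal_tissue] + shift
    tissue_atlas(v, species, focal_tissue)
  }
  list(species_a = mk(n_tissues_a, "speciesA", character(0)),
       species_b = mk(n_tissues_b, "speciesB",
                      intersect(specific_genes, genes)))
}
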