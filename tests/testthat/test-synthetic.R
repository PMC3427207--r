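test_that("scenario generation is byte-identical under one seed", {
  cfg <- scenario_config(n_genes = 100, n_tfs = 4, samples_per_group = 4,
                         targets_per_tf = 8, seed = 77)
  s1 <- generate_regulatory_scenario(cfg)
  s2 <- generate_regulatory_scenario(cfg)
  expect_identical(s1$cohort_a$values, s2$cohort_a$values)
  expect_identical(s1$cohort_b$values, s2$cohort_b$values)
  expect_identical(lapply(s1$regulons, `[[`, "targets"),
                   lapply(s2$regulons, `[[`, "targets"))
})

test_that("config invariants are enforced", {
  expect_error(scenario_config(n_genes = 10, n_tfs = 2,
                               targets_per_tf = 20), "exceeds")
  expect_error(scenario_config(tf_target_coupling = 1.2), "\\[0, 1\\]")
  expect_error(scenario_config(noise_sd = 0), "noise_sd")
  expect_error(scenario_config(driver_tfs = 99), "out of range")
})

test_that("global null scenario gives uniform per-gene p-values", {
  cfg <- scenario_config(n_genes = 1200, n_tfs = 4, samples_per_group = 6,
                         planted_effect_size = 0, tf_target_coupling = 0,
                         targets_per_tf = 10, batch_sd = 0, seed = 5)
  scen <- generate_regulatory_scenario(cfg)
  p <- test_differential(scen$cohort_a, c("A", "B"))$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("driver-target correlations match the generating equation", {
  cc <- 0.9; d <- 1.5
  cfg <- scenario_config(n_genes = 300, n_tfs = 1, samples_per_group = 25,
                         planted_effect_size = d, tf_target_coupling = cc,
                         targets_per_tf = 50, batch_sd = 0, seed = 31)
  r_exp <- expected_target_correlation(cc, d)
  rs <- replicate(20, {
    scen <- generate_regulatory_scenario(cfg)
    a <- scen$cohort_a
    tg <- scen$regulons[[1]]$targets
    cfg$seed <<- cfg$seed + 1L
    mean(cor(a$values["TF001", ], t(a$values[tg, ])))
  })
  expect_equal(mean(rs), r_exp, tolerance = 0.03)
})

test_that("planted effect sizes are recovered on average", {
  # batch-free world: batch centring and batch noise both perturb the
  # pooled SD, so self-consistency is checked on the clean generator
  cfg <- scenario_config(n_genes = 150, n_tfs = 5, samples_per_group = 20,
                         planted_effect_size = 1.5, targets_per_tf = 8,
                         batch_sd = 0, seed = 41)
  dmat <- replicate(50, {
    scen <- generate_regulatory_scenario(cfg)
    cfg$seed <<- cfg$seed + 1L
    effect_size(scen$cohort_a, "A", "B")[sprintf("TF%03d", 1:5)]
  })
  expect_lt(abs(mean(dmat) - 1.5), 0.1)
})

test_that("promoter backgrounds honour the stated G/C fraction", {
  prs <- generate_promoters(30, length = 2000, gc = 0.5, seed = 8)
  gcf <- mean(vapply(prs, function(p) {
    x <- strsplit(p$sequence, "")[[1]]
    mean(x %in% c("G", "C"))
  }, numeric(1)))
  n_bases <- 30 * 2000
  ci <- qbinom(c(0.0005, 0.9995), n_bases, 0.5) / n_bases
  expect_gt(gcf, ci[1]); expect_lt(gcf, ci[2])
})

test_that("planted consensus sites are recoverable at their offsets", {
  pwm <- fixture_pwm()
  planted <- data.frame(gene = "p00001", offset = -392L, strand = "+")
  prs <- generate_promoters(3, length = 4000, planted = planted,
                            pwm = pwm, seed = 9)
  pr <- prs[[1]]
  expect_equal(nchar(pr$sequence), 4000) # spans TSS-2000..TSS+2000
  idx <- pr$tss_offset - 392
  expect_equal(substr(pr$sequence, idx, idx + pwm$width - 1L),
               pwm_consensus(pwm))
  expect_gte(mean(pr$conservation[idx:(idx + pwm$width - 1L)]), 0.6)
  # overlapping planted sites error out
  bad <- data.frame(gene = "p00001", offset = c(0L, 5L), strand = "+")
  expect_error(generate_promoters(1, 4000, bad, pwm, seed = 1),
               "overlapping")
})

test_that("dnase tracks cover planted sites and hit the target fraction", {
  pwm <- fixture_pwm()
  planted <- data.frame(gene = sprintf("p%05d", 1:10), offset = -300L,
                        strand = "+")
  prs <- generate_promoters(100, length = 2000, planted = planted,
                            pwm = pwm, seed = 10)
  iv <- generate_dnase_tracks(prs, cover_planted = TRUE,
                              background_fraction = 0.06, seed = 11)
  # every planted site inside >= 1 interval
  for (g in planted$gene) {
    sub <- iv[iv$gene == g, ]
    expect_true(any(sub$start <= -300 & sub$end >= -300 + pwm$width))
  }
  # realized background coverage near 6%
  cov <- vapply(prs[11:100], function(p) {
    sub <- iv[iv$gene == p$gene, , drop = FALSE]
    covered <- rep(FALSE, 2000)
    for (i in seq_len(nrow(sub))) {
      lo <- max(1, sub$start[i] + p$tss_offset)
      hi <- min(2000, sub$end[i] + p$tss_offset - 1)
      if (lo <= hi) covered[lo:hi] <- TRUE
    }
    mean(covered)
  }, numeric(1))
  expect_gt(mean(cov), 0.04); expect_lt(mean(cov), 0.08)
  # empty settings give an empty track
  iv0 <- generate_dnase_tracks(generate_promoters(5, 1000, seed = 2),
                               cover_planted = FALSE,
                               background_fraction = 0, seed = 3)
  expect_equal(nrow(iv0), 0)
})

test_that("tissue atlases carry the planted focal shift", {
  spec <- sprintf("g%05d", 1:100)
  at <- generate_tissue_atlas(2000, specific_genes = spec, shift = 2,
                              seed = 12)
  expect_equal(ncol(at$species_a$values), 79)
  expect_equal(ncol(at$species_b$values), 61)
  z_a <- specificity_z(at$species_a)
  z_b <- specificity_z(at$species_b)
  expect_gt(median(z_b[spec]), median(z_a)) # planted genes exceed sp1 median
  expect_gt(median(z_b[spec]) - median(z_b[setdiff(names(z_b), spec)]), 1)
  # shift = 0 -> downstream comparison is null
  at0 <- generate_tissue_atlas(500, specific_genes = spec, shift = 0,
                               seed = 13)
  res0 <- compare_specificity(specificity_z(at0$species_a),
                              specificity_z(at0$species_b),
                              spec, setdiff(sprintf("g%05d", 1:500), spec))
  expect_gt(res0$p, 0.01)
})
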