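test_that("TRANSFAC parsing round-trips the fixture matrix", {
  pwm <- fixture_pwm()
  expect_s3_class(pwm, "PWM")
  expect_equal(pwm$width, 14)
  expect_equal(pwm$core, c(6L, 10L))
  expect_equal(unname(rowSums(pwm$counts)), rep(23, 14))
  expect_equal(substr(pwm_consensus(pwm), 6, 10), "GGGGG")
})

test_that("a planted consensus scores exactly 1 at the planted offset", {
  pwm <- fixture_pwm()
  planted <- data.frame(gene = c("p00001", "p00002"),
                        offset = c(-392L, 37L), strand = c("+", "-"))
  prs <- generate_promoters(2, 4000, planted, pwm, seed = 51)
  s1 <- scan_pwm(prs[[1]], pwm)
  expect_true(any(s1$start == -392 & s1$strand == "+" &
                    abs(s1$score - 1) < 1e-12))
  # reverse complement reported on the minus strand at the same leftmost
  # coordinate
  s2 <- scan_pwm(prs[[2]], pwm)
  expect_true(any(s2$start == 37 & s2$strand == "-" &
                    abs(s2$score - 1) < 1e-12))
})

test_that("a uniform PWM scores every window identically", {
  pwm <- pwm_matrix("uniform", matrix(1, nrow = 4, ncol = 4))
  pr <- promoter_record("g1", "ACGTACGTACGT", tss_offset = 6)
  s <- scan_pwm(pr, pwm, min_score = 0, min_core_score = 0)
  # degenerate min-max range: all windows collapse to the same score
  expect_equal(length(unique(round(s$score, 12))), 1)
})

test_that("windows containing N are skipped", {
  pwm <- fixture_pwm()
  seqc <- paste0(strrep("A", 100), "N", strrep("A", 100))
  pr <- promoter_record("g1", seqc, tss_offset = 100)
  s <- scan_pwm(pr, pwm, min_score = 0, min_core_score = 0)
  # no reported site window may cover the N at index 101
  expect_true(all(s$start + pr$tss_offset > 101 |
                    s$start + pr$tss_offset + pwm$width - 1 < 101))
})

test_that("conservation filter applies inclusive thresholds", {
  sites <- data.frame(coverage = c(1, 10 / 14, 0.8, 1),
                      mean_conservation = c(0.7, 0.9, 0.6, NA))
  expect_identical(conservation_filter(sites),
                   c(TRUE, FALSE, TRUE, FALSE))
})

test_that("predict_regulons finds exactly the planted targets", {
  pwm <- fixture_pwm()
  planted <- data.frame(gene = sprintf("p%05d", 1:8), offset = -100L,
                        strand = "+")
  prs <- generate_promoters(20, 2000, planted, pwm, seed = 52)
  regs <- predict_regulons(prs, list(pwm), c(M_SYNGC1 = "TF1"))
  expect_length(regs, 1)
  expect_setequal(intersect(regs[[1]]$targets, planted$gene), planted$gene)
  # stray unplanted targets are possible in principle but must be rare
  expect_lte(length(setdiff(regs[[1]]$targets, planted$gene)), 1)
  # destroying conservation over the planted sites excludes the genes
  prs_uncons <- lapply(prs, function(p) {
    p$conservation <- rep(0.2, nchar(p$sequence))
    p
  })
  expect_length(predict_regulons(prs_uncons, list(pwm),
                                 c(M_SYNGC1 = "TF1")), 0)
})

test_that("TSS proximity test behaves at the extremes and under the null", {
  near <- data.frame(start = rep(0L, 27))
  expect_lt(tss_proximity_test(near)$ks_p, 1e-6)
  set.seed(53)
  unif <- data.frame(start = as.integer(runif(500, -2000, 2000)))
  res <- tss_proximity_test(unif)
  expect_gt(res$ks_p, 0.001)
  expect_equal(res$n, 500)
})

test_that("dinucleotide shuffle preserves the exact transition counts", {
  expect_identical(dinucleotide_shuffle("AAAA"), "AAAA")
  expect_identical(dinucleotide_shuffle("ACGT"), "ACGT")
  set.seed(54)
  for (i in 1:50) {
    n <- sample(2:1500, 1)
    s <- random_dna(n, gc = runif(1, 0.2, 0.8))
    sh <- dinucleotide_shuffle(s)
    expect_identical(dinuc_counts(sh), dinuc_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, n, n), substr(s, n, n))
  }
  # seeded reproducibility
  s <- random_dna(500)
  expect_identical(dinucleotide_shuffle(s, seed = 7),
                   dinucleotide_shuffle(s, seed = 7))
})

test_that("conservation shuffle preserves per-base-type score multisets", {
  set.seed(55)
  pr <- generate_promoters(1, 1000, seed = 56)[[1]]
  sh <- shuffle_conservation(pr, seed = 57)
  chars <- strsplit(pr$sequence, "")[[1]]
  for (b in unique(chars)) {
    idx <- which(chars == b)
    expect_identical(sort(sh[idx]), sort(pr$conservation[idx]))
  }
  # single-occurrence base keeps its score
  pr2 <- promoter_record("g1", "AAAC", 2, conservation = c(.1, .2, .3, .9))
  expect_identical(shuffle_conservation(pr2, seed = 1)[4], 0.9)
})

test_that("binding_site_null reports chance-level target counts", {
  pwm <- fixture_pwm()
  planted <- data.frame(gene = sprintf("p%05d", 1:6), offset = -250L,
                        strand = "+")
  prs <- generate_promoters(6, 1500, planted, pwm, seed = 58)
  bn <- binding_site_null(prs, pwm, n_batches = 15, seed = 59)
  expect_equal(bn$observed, 6)
  expect_lte(bn$expected_count, 1)
  expect_lt(bn$fdr, 0.2)
  expect_length(bn$batch_counts, 15)
})

test_that("dnase overlap test separates planted from random placement", {
  pwm <- fixture_pwm()
  planted <- data.frame(gene = sprintf("p%05d", 1:20), offset = -300L,
                        strand = "+")
  prs <- generate_promoters(20, 2000, planted, pwm, seed = 60)
  iv <- generate_dnase_tracks(prs, cover_planted = TRUE,
                              background_fraction = 0.06, seed = 61)
  sites <- do.call(rbind, lapply(prs, function(p) {
    s <- scan_pwm(p, pwm)
    s[conservation_filter(s), , drop = FALSE]
  }))
  res <- dnase_overlap_test(sites, iv, prs, n_rand = 150, seed = 62)
  expect_equal(res$n_genes_overlapping, 20)
  expect_lt(res$p, 0.05)
  expect_lt(res$expected, 20)
  # no intervals: observed 0, p 1
  res0 <- dnase_overlap_test(sites, iv[0, ], prs, n_rand = 10, seed = 63)
  expect_equal(res0$n_genes_overlapping, 0)
  expect_equal(res0$p, 1)
})

test_that("score-distribution comparison has the stated alternative", {
  set.seed(64)
  fg <- rbeta(100, 2, 5) - 0.1
  bg <- rbeta(300, 2, 5)
  expect_lt(compare_score_distributions(fg, bg, "less"), 0.05)
  expect_gt(compare_score_distributions(bg, fg, "less"), 0.5)
})
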