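test_that("regulon construction enforces its invariants", {
  expect_error(tf_regulon("TF1", "m1", character(0)), "non-empty")
  expect_error(tf_regulon("TF1", "m1", c("g1", "TF1")), "own target")
  r <- tf_regulon("TF1", "m1", c("g1", "g2", "g2"))
  expect_identical(r$targets, c("g1", "g2"))
})

# shared planted scenario for the TF tests
make_scenario <- function(seed, coupling = 0.7, sign_mix = 0) {
  cfg <- scenario_config(n_genes = 600, n_tfs = 20, samples_per_group = 6,
                         planted_effect_size = 1.5,
                         tf_target_coupling = coupling,
                         targets_per_tf = c(30, rep(11, 19)),
                         sign_mix = sign_mix, batch_sd = 0, seed = seed)
  generate_regulatory_scenario(cfg)
}

test_that("the planted driver is flagged and non-drivers are not", {
  scen <- make_scenario(101)
  a <- scen$cohort_a
  # gate on the planted effect sizes: the test isolates the regulatory
  # statistic from d-estimation noise (covered elsewhere)
  eff <- data.frame(gene = names(scen$truth$planted_d),
                    p = NA_real_, d = scen$truth$planted_d,
                    direction = sign(scen$truth$planted_d), cohort = "a")
  res <- scan_tf_regulators(a, scen$regulons, eff)
  expect_equal(nrow(res), 20) # every TF qualifies by construction
  expect_true(res$pass[res$tf == "TF001"])
  expect_identical(res$direction[res$tf == "TF001"], "more_positive")
  expect_lte(sum(res$pass[res$tf != "TF001"]), 1) # ~1% chance level
})

test_that("regulatory_effect_test is null-calibrated on exchangeable data", {
  set.seed(30)
  st <- null_study(250, 6)
  genes <- study_genes(st)
  reg <- tf_regulon(genes[1], "m1", genes[2:21])
  ps <- replicate(200, {
    perm <- sample(genes[-1])
    r <- tf_regulon(genes[1], "m1", perm[1:20])
    regulatory_effect_test(st, r, eligible = genes,
                           nontarget_pool = setdiff(genes[-1], perm[1:20]))$p
  })
  # discrete exact p-values tie; the KS approximation is still informative
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(mean(ps < 0.01), 0.04)
})

test_that("untestable regulons are flagged, not dropped", {
  set.seed(31)
  st <- null_study(50, 4)
  genes <- study_genes(st)
  reg <- tf_regulon(genes[1], "m1", genes[2:4])
  res <- regulatory_effect_test(st, reg, eligible = genes[1:10])
  expect_true(res$untestable)
  expect_true(is.na(res$p))
})

test_that("regulon permutation reproduces from seed and sees planted excess", {
  scen <- make_scenario(102)
  a <- scen$cohort_a
  eff <- test_differential(a, c("A", "B"))
  g1 <- permute_regulon_labels(a, scen$regulons, eff, n_perm = 60,
                               seed = 12)
  g2 <- permute_regulon_labels(a, scen$regulons, eff, n_perm = 60,
                               seed = 12)
  expect_identical(g1$perm_pass, g2$perm_pass)
  expect_gte(g1$observed_pass, 1)
  # permuted regulons pass only at chance level
  expect_lt(g1$expected_pass_count, 2)
})

test_that("CoC is 1 on identical cohorts and symmetric between cohorts", {
  scen <- make_scenario(103)
  a <- scen$cohort_a; b <- scen$cohort_b
  reg <- scen$regulons[[1]]
  eligible <- names(scen$truth$planted_d)[scen$truth$planted_d != 0]
  same <- correlation_of_correlations(a, a, reg, eligible, eligible)
  expect_equal(same$rho, 1)
  ab <- correlation_of_correlations(a, b, reg, eligible, eligible)
  ba <- correlation_of_correlations(b, a, reg, eligible, eligible)
  expect_equal(ab$rho, ba$rho)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$n_shared_targets, 30)
})

test_that("CoC recovers a sign-mixed planted driver across cohorts", {
  scen <- make_scenario(104, sign_mix = 0.5)
  eligible <- names(scen$truth$planted_d)[scen$truth$planted_d != 0]
  cr <- correlation_of_correlations(scen$cohort_a, scen$cohort_b,
                                    scen$regulons[[1]], eligible, eligible)
  expect_gt(cr$rho, 0)
  expect_lt(cr$p, 0.05)
})

test_that("CoC global permutation isolates coupling from shared shifts", {
  # a large shared group shift makes *any* consistently shifted gene set
  # CoC-consistent across cohorts; the permutation null is informative
  # when the within-group coupling dominates, so a small-shift world is
  # the right stage for it
  cfg <- scenario_config(n_genes = 600, n_tfs = 20, samples_per_group = 6,
                         planted_effect_size = 0.5,
                         tf_target_coupling = 0.7,
                         targets_per_tf = c(30, rep(11, 19)),
                         sign_mix = 0.5, batch_sd = 0, seed = 104)
  scen <- generate_regulatory_scenario(cfg)
  eligible <- names(scen$truth$planted_d)[scen$truth$planted_d != 0]
  gp <- coc_global_significance(scen$cohort_a, scen$cohort_b,
                                scen$regulons, "TF001", eligible, eligible,
                                n_perm = 100, seed = 3)
  expect_lt(gp$global_p, 0.05)
  # seeded reproducibility
  gp2 <- coc_global_significance(scen$cohort_a, scen$cohort_b,
                                 scen$regulons, "TF001", eligible,
                                 eligible, n_perm = 100, seed = 3)
  expect_identical(gp$perm_p, gp2$perm_p)
})

test_that("fewer than 3 shared targets makes CoC untestable", {
  scen <- make_scenario(105)
  cr <- correlation_of_correlations(scen$cohort_a, scen$cohort_b,
                                    scen$regulons[[1]],
                                    scen$regulons[[1]]$targets[1:2],
                                    scen$regulons[[1]]$targets[1:2])
  expect_true(cr$untestable)
})

test_that("common-candidate excess matches the enumeration oracle", {
  bg <- sprintf("TF%02d", 1:36)
  res <- common_candidate_excess(bg[1:2], bg[c(1, 10:14)], bg)
  # a=1, b=1, c=5, d=29
  expect_equal(res$p, oracle_fisher_greater(1, 1, 5, 29), tolerance = 1e-12)
  # disjoint candidate sets are unsurprising
  res2 <- common_candidate_excess(bg[1:3], bg[4:6], bg)
  expect_gte(res2$p, 0.5)
})
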