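test_that("effect size follows the pooled-SD formula exactly", {
  st <- tiny_study(rbind(c(3, 4, 5, 1, 2, 3), c(1, 2, 3, 1, 2, 3)),
                   group = rep(c("A", "B"), each = 3))
  d <- effect_size(st, "A", "B")
  expect_equal(unname(d), c(2, 0)) # SD1 = SD2 = SDp = 1
  # antisymmetry under group swap, exact
  set.seed(21)
  st2 <- null_study(50, 5)
  expect_equal(effect_size(st2, "A", "B"), -effect_size(st2, "B", "A"))
  # zero pooled SD -> NA with warning
  st3 <- tiny_study(matrix(c(1, 1, 1, 2, 2, 2), nrow = 1),
                    group = rep(c("A", "B"), each = 3))
  expect_warning(d3 <- effect_size(st3, "A", "B"), "zero pooled SD")
  expect_true(is.na(d3))
})

test_that("test_differential matches the textbook two-sample t", {
  st <- tiny_study(matrix(c(3, 4, 5, 1, 2, 3), nrow = 1),
                   group = rep(c("A", "B"), each = 3))
  eff <- test_differential(st, c("A", "B"))
  ref <- t.test(c(3, 4, 5), c(1, 2, 3), var.equal = TRUE)
  expect_equal(eff$p, ref$p.value, tolerance = 1e-12)
  expect_equal(eff$direction, 1L)
  effw <- test_differential(st, c("A", "B"), method = "welch")
  refw <- t.test(c(3, 4, 5), c(1, 2, 3))
  expect_equal(effw$p, refw$p.value, tolerance = 1e-12)
  eff1 <- test_differential(st, c("A", "B"), sided = "one")
  ref1 <- t.test(c(3, 4, 5), c(1, 2, 3), var.equal = TRUE,
                 alternative = "greater")
  expect_equal(eff1$p, ref1$p.value, tolerance = 1e-12)
})

test_that("two-level ANOVA p equals the pooled t p (F = t^2)", {
  set.seed(22)
  st <- null_study(30, 4)
  p_t <- test_differential(st, c("A", "B"), method = "t")$p
  p_f <- test_differential(st, c("A", "B"), method = "anova")$p
  expect_equal(p_t, p_f, tolerance = 1e-10)
})

test_that("degenerate genes get p = 1, d = 0 semantics", {
  st <- tiny_study(matrix(c(2, 2, 2, 2, 2, 2), nrow = 1),
                   group = rep(c("A", "B"), each = 3))
  eff <- suppressWarnings(test_differential(st, c("A", "B")))
  expect_equal(eff$p, 1)
  expect_equal(eff$direction, 0L)
})

test_that("null per-gene p-values are uniform", {
  set.seed(23)
  st <- null_study(2000, 6)
  p <- test_differential(st, c("A", "B"))$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("permutation FDR calibration is seeded, monotone, and honest on null data", {
  set.seed(24)
  st <- null_study(400, 6)
  cal1 <- calibrate_permutation_fdr(st, c("A", "B"), n_perm = 40, seed = 9)
  cal2 <- calibrate_permutation_fdr(st, c("A", "B"), n_perm = 40, seed = 9)
  expect_identical(cal1$significant, cal2$significant)
  # monotonized diagnostic curve is non-decreasing and dominates the raw one
  expect_true(all(diff(cal1$fdr_grid$fdr_monotone) >= 0))
  expect_true(all(cal1$fdr_grid$fdr_monotone >= cal1$fdr_grid$fdr,
                  na.rm = TRUE))
  # null data: at most a handful of calls
  expect_lte(cal1$n_observed, 10)
  # by construction: median perm count <= target * observed at the cutoff
  if (cal1$n_observed > 0)
    expect_lte(median(cal1$perm_counts),
               cal1$target_fdr * cal1$n_observed)
})

test_that("calibration recovers planted signal with controlled FDR", {
  set.seed(25)
  st <- planted_study(800, 80, d = 1.5, n_per_group = 6)
  cal <- calibrate_permutation_fdr(st, c("A", "B"), n_perm = 60, seed = 4)
  called <- cal$significant
  truth <- study_genes(st)[1:80]
  expect_gte(length(intersect(called, truth)), 8) # non-trivial power
  realized <- length(setdiff(called, truth)) / max(1, length(called))
  expect_lt(realized, 0.35) # single replicate; acceptance tests average
})

test_that("consistent_de applies direction and both-cohort rules", {
  a <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  p = c(0.001, 0.001, 0.5, 0.001),
                  d = c(2, 2, 0.2, 1), direction = c(1L, 1L, 1L, -1L),
                  cohort = "a")
  b <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  p = c(0.001, 0.001, 0.6, 0.001),
                  d = c(1.5, 1.5, 0.1, 1), direction = c(1L, -1L, 1L, -1L),
                  cohort = "b")
  expect_setequal(consistent_de(a, b, "fdr_both", cutoffs = c(0.01, 0.01)),
                  c("g1", "g4")) # g2 flips direction, g3 not significant
  expect_setequal(consistent_de(a, b, "es_both", cutoffs = 0.8),
                  c("g1", "g4"))
  expect_setequal(consistent_de(a, a, "fdr_both", cutoffs = c(0.01, 0.01)),
                  c("g1", "g2", "g4"))
})

test_that("overlap_test returns the sample OR and hypergeometric tail", {
  bg <- sprintf("g%03d", 1:200)
  s1 <- bg[1:20]; s2 <- bg[c(1:10, 21:30)] # a=10 b=10 c=10 d=170
  res <- overlap_test(s1, s2, bg)
  expect_equal(res$odds_ratio, 17)
  expect_equal(res$p, oracle_fisher_greater(10, 10, 10, 170),
               tolerance = 1e-12)
  res2 <- overlap_test(bg[1:100], bg[1:100], bg)
  expect_identical(res2$odds_ratio, Inf)
  expect_lt(res2$p, 1e-10)
  expect_error(overlap_test(s1, s2, character(0)), "empty background")
})
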