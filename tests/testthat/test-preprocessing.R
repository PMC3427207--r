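test_that("quantile step leaves identical columns at their log values", {
  v <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)
  st <- log_quantile_normalize(tiny_study(v, group = c("A", "B")),
                               pseudocount = 0)
  expect_equal(unname(st$values), log2(v))
})

test_that("two-column quantile normalization equals rank-wise log means", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2)
  st <- log_quantile_normalize(tiny_study(v, group = c("A", "B")),
                               pseudocount = 0)
  ref <- rowMeans(log2(v)) # both columns already sorted
  expect_equal(unname(st$values[, 1]), ref)
  expect_equal(unname(st$values[, 2]), ref)
})

test_that("columns that are permutations map onto one shared vector", {
  set.seed(4)
  base <- rnorm(20, 8, 2)^2
  v <- unname(cbind(base, sample(base), sample(base)))
  st <- log_quantile_normalize(tiny_study(v, group = c("A", "A", "B")),
                               pseudocount = 0)
  for (j in 2:3)
    expect_equal(unname(sort(st$values[, j])),
                 unname(sort(st$values[, 1])))
  expect_equal(order(st$values[, 2]), order(v[, 2]))
})

test_that("quantile normalization is idempotent (tie-free data)", {
  set.seed(5)
  v <- matrix(rnorm(60), ncol = 4)
  once <- quantile_normalize(v)
  expect_equal(quantile_normalize(once), once)
})

test_that("single-sample matrices are rejected", {
  expect_error(log_quantile_normalize(
    expression_study(matrix(1:3, ncol = 1), group = "A")),
    "single-sample")
})

test_that("detection filter keeps criterion (1) or criterion (2) genes", {
  # 12 samples, 6 per group
  det <- matrix(1, nrow = 3, ncol = 12)
  det[1, ] <- 0.01                 # detected everywhere -> kept via (1)
  det[2, 1:6] <- 0.01              # all of group A, none of B -> kept via (2)
  det[3, 1] <- 0.01                # 1 of 12, evenly split -> dropped
  st <- expression_study(matrix(rnorm(36), nrow = 3),
                         group = rep(c("A", "B"), each = 6),
                         detection_p = det)
  kept <- study_genes(filter_detected(st))
  expect_setequal(kept, study_genes(st)[1:2])
})

test_that("count-mode detection uses count > 0 and the half rule", {
  v <- matrix(5, nrow = 2, ncol = 8)
  v[1, 1:5] <- 0                    # zero in >half the samples, even split
  st <- expression_study(v, group = rep(c("A", "B"), each = 4))
  kept <- study_genes(filter_detected(st, mode = "counts"))
  expect_identical(kept, study_genes(st)[2])
  st2 <- expression_study(matrix(rnorm(8), nrow = 1), group = rep("A", 8))
  expect_error(filter_detected(st2, mode = "detection"), "missing")
})

test_that("batch-mean removal zeroes within-batch means", {
  set.seed(6)
  st <- null_study(10, 4, batch = rep(c("b1", "b2"), 4))
  out <- remove_batch_effect(st)
  for (b in c("b1", "b2")) {
    m <- rowMeans(out$values[, out$batch == b, drop = FALSE])
    expect_equal(unname(m), rep(0, 10), tolerance = 1e-12)
  }
  # single batch: output = input minus gene means
  st1 <- null_study(5, 2, batch = rep("b1", 4))
  out1 <- remove_batch_effect(st1)
  expect_equal(out1$values, st1$values - rowMeans(st1$values))
  # two batches with equal gene means: unchanged up to global centring
  v <- matrix(rnorm(8), nrow = 2)
  v2 <- cbind(v, v)
  st2 <- expression_study(v2, group = rep(c("A", "B"), 4),
                          batch = rep(c("b1", "b2"), each = 4))
  out2 <- remove_batch_effect(st2)
  expect_equal(unname(out2$values), v2 - rowMeans(v2), tolerance = 1e-12)
})

test_that("standardize_and_combine yields z-scored rows on shared genes", {
  set.seed(7)
  a <- null_study(8, 3)
  b <- null_study(8, 4)
  rownames(b$values)[8] <- "other" # drop one from the intersection
  comb <- standardize_and_combine(a, b)
  expect_equal(nrow(comb$values), 7)
  expect_equal(unname(rowMeans(comb$values)), rep(0, 7), tolerance = 1e-12)
  expect_equal(unname(apply(comb$values, 1, sd)), rep(1, 7),
               tolerance = 1e-12)
  # identical cohorts: combined rows are repeated z-scores of the matrix
  comb2 <- standardize_and_combine(a, a)
  z <- (a$values - rowMeans(a$values)) / apply(a$values, 1, sd)
  sd_ratio <- apply(cbind(z, z), 1, sd)
  expect_equal(unname(comb2$values[, 1:6]), unname(z / sd_ratio),
               tolerance = 1e-12)
  # zero-variance gene is dropped with a warning
  a2 <- a
  a2$values[1, ] <- 5
  expect_warning(comb3 <- standardize_and_combine(a2, b), "zero variance")
  expect_false(study_genes(a)[1] %in% study_genes(comb3))
})

test_that("gene and sample ordering survive the preprocessing chain", {
  set.seed(8)
  st <- null_study(12, 3, batch = rep(c("b1", "b2"), 3))
  st$values <- abs(st$values) + 1
  out <- remove_batch_effect(log_quantile_normalize(st, pseudocount = 1))
  expect_identical(study_genes(out), study_genes(st))
  expect_identical(study_samples(out), study_samples(st))
})
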