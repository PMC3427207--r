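# Small shared statistical kernels. These are deliberately self-contained so
# that permutation loops elsewhere in the package stay fast, and so that each
# can be checked against enumeration oracles in the test suite.

#' Rank-sum (Mann-Whitney / Wilcoxon) two-sample test
#'
#' Exact null distribution (via [stats::pwilcox()]) when both samples have at
#' most 25 observations and there are no ties; otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` (x stochastically larger) or
#'   `"less"`.
#' @param exact force exact/approximate computation; default decides as above.
#' @return list with `statistic` (the Mann-Whitney U for `x`) and `p.value`.
#' @export
ranksum_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- !ties && n1 <= 25 && n2 <= 25
  if (exact && !ties) {
    p <- switch(alternative,
      two.sided = {
        if (u > n1 * n2 / 2) {
          min(1, 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(u, n1, n2))
        }
      },
      greater = stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE),
      less = stats::pwilcox(u, n1, n2)
    )
  } else {
    mu <- n1 * n2 / 2
    tab <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n1 + n2 + 1) -
      sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1)))
    sigma <- sqrt(sigma2)
    z <- u - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
    z <- if (sigma > 0) (z - cc) / sigma else 0
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    p <- min(1, p)
  }
  list(statistic = u, p.value = p)
}

# One-sided ("greater") Fisher's exact test on the 2x2 table
#   a = in both, b = in set1 only, c = in set2 only, d = in neither.
# Returns the sample odds ratio (Inf sentinel when b*c == 0 and a*d > 0)
# and the hypergeometric tail probability.
fisher_greater <- function(a, b, c, d) {
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  list(odds_ratio = or, p = p)
}

# Spearman correlation test; wraps cor.test and silences the tie warning
# (exact p is unavailable with ties; the approximation is then used).
spearman_test <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# Seed scoping: set the seed locally when given, restoring the caller's RNG
# state afterwards; NULL means "use the ambient RNG stream".
local_seed_if <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = envir)
  invisible(NULL)
}

# Row-wise two-sample t statistics for a genes x samples matrix split by
# column index sets. pooled = Student (equals the one-way ANOVA F for two
# groups); otherwise Welch.
row_t_test <- function(values, idx1, idx2, pooled = TRUE,
                       sided = c("two", "one")) {
  sided <- match.arg(sided)
  x1 <- values[, idx1, drop = FALSE]
  x2 <- values[, idx2, drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[!is.finite(df)] <- n1 + n2 - 2
  }
  tstat <- (m1 - m2) / se
  # degenerate rows: zero variance in both groups
  degen <- se == 0
  tstat[degen & m1 == m2] <- 0
  tstat[degen & m1 != m2] <- Inf * sign(m1 - m2)[degen & m1 != m2]
  p <- if (sided == "two") {
    2 * stats::pt(-abs(tstat), df)
  } else {
    stats::pt(tstat, df, lower.tail = FALSE)
  }
  p[degen & m1 == m2] <- 1
  list(statistic = tstat, p = p, mean1 = m1, mean2 = m2, var1 = v1, var2 = v2,
       n1 = n1, n2 = n2)
}

# Row-wise one-way ANOVA F test for >= 2 groups.
row_anova <- function(values, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- ncol(values)
  gm <- rowMeans(values)
  ssb <- 0
  ssw <- 0
  for (lev in levels(group)) {
    idx <- which(group == lev)
    m <- rowMeans(values[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (m - gm)^2
    ssw <- ssw + rowSums((values[, idx, drop = FALSE] - m)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  degen <- ssw == 0
  p[degen & ssb == 0] <- 1
  p[degen & ssb > 0] <- 0
  list(statistic = f, p = p)
}
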