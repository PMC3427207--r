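# Independent enumeration / simulation oracles used to check the package's
# statistical kernels. These deliberately share no code with the
# implementation.

# Exhaustive rank-sum test: enumerate all assignments of the pooled values
# to group 1 (sizes n1), compute the Mann-Whitney U for each, and report
# the proportion at least as extreme as observed.
oracle_ranksum <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  switch(alternative,
    two.sided = mean(abs(us - mu) >= abs(obs - mu)),
    greater = mean(us >= obs),
    less = mean(us <= obs)
  )
}

# Exact one-sided Fisher p by direct hypergeometric enumeration.
oracle_fisher_greater <- function(a, b, c, d) {
  n1 <- a + b          # size of set 1
  k <- a + c           # size of set 2
  n <- a + b + c + d
  ks <- max(0, n1 + k - n):min(n1, k)
  pmf <- choose(k, ks) * choose(n - k, n1 - ks) / choose(n, n1)
  sum(pmf[ks >= a])
}

# Exact two-sided Spearman p by enumerating all permutations of one rank
# vector (n <= 8).
oracle_spearman <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- permutations_of(n)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow = nrow(sub)))
  }))
}

# Brute-force one-sided (D+) Kolmogorov-Smirnov statistic against
# Uniform(0, b), maximizing ECDF - CDF over a fine grid.
oracle_ks_stat <- function(x, b) {
  grid <- sort(unique(c(x, seq(0, b, length.out = 2001))))
  ecdf_x <- stats::ecdf(x)
  max(ecdf_x(grid) - grid / b)
}

# Monte-Carlo null distribution of the one-sided KS D+ statistic.
oracle_ks_null <- function(n, nsim = 20000, seed = 99) {
  withr::with_seed(seed, {
    replicate(nsim, {
      u <- sort(stats::runif(n))
      max(seq_len(n) / n - u)
    })
  })
}

# dinucleotide count table over a fixed 16-key layout
dinuc_counts <- function(s) {
  x <- strsplit(s, "")[[1]]
  di <- paste0(x[-length(x)], x[-1])
  keys <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0))
  table(factor(di, levels = keys))
}
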