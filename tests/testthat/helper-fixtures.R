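# Small fixture builders shared across test files.

tiny_study <- function(values, group = NULL, ...) {
  v <- as.matrix(values)
  if (is.null(group)) group <- rep(c("A", "B"), each = ncol(v) / 2)
  expression_study(v, group = group, ...)
}

# pure-null gaussian study
null_study <- function(n_genes, n_per_group, sd = 1, seed = NULL,
                       batch = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n_genes * 2 * n_per_group, sd = sd), nrow = n_genes)
  expression_study(v, group = rep(c("A", "B"), each = n_per_group),
                   batch = batch)
}

# study with the first `n_planted` genes shifted by `d` pooled-SD units
planted_study <- function(n_genes, n_planted, d, n_per_group, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n_genes * 2 * n_per_group), nrow = n_genes)
  if (n_planted > 0)
    v[seq_len(n_planted), seq_len(n_per_group)] <-
      v[seq_len(n_planted), seq_len(n_per_group)] + d
  expression_study(v, group = rep(c("A", "B"), each = n_per_group))
}

fixture_pwm <- function() {
  read_transfac_pwm(system.file("extdata", "synthetic_gc_motif.transfac",
                                package = "regulonscan"))[[1]]
}

# random DNA string
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
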