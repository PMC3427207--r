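#' Position weight matrix with a core sub-range
#'
#' Count matrix (positions x bases A,C,G,T) plus the core element range used
#' for the separate core similarity score.
#'
#' @param id motif identifier.
#' @param counts numeric matrix, one row per motif position, columns
#'   A, C, G, T, non-negative with positive row sums.
#' @param core integer length-2 `(start, end)` positions of the core element
#'   within the motif; defaults to the full width.
#' @return object of class `PWM`.
#' @export
pwm_matrix <- function(id, counts, core = NULL) {
  counts <- as.matrix(counts)
  colnames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0) || any(rowSums(counts) <= 0))
    stop("`counts` must be non-negative with positive row sums")
  w <- nrow(counts)
  if (is.null(core)) core <- c(1L, w)
  core <- as.integer(core)
  if (core[1] < 1L || core[2] > w || core[1] > core[2])
    stop("`core` must lie within [1, width]")
  structure(list(id = as.character(id), counts = counts, width = w,
                 core = core),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM %s: width %d, core %d-%d\n", x$id, x$width, x$core[1],
              x$core[2]))
  cat("  consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm a [pwm_matrix()].
#' @return character string of the per-position maximal bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm$counts)[max.col(pwm$counts, ties.method = "first")],
        collapse = "")
}

# Similarity weight matrix in the MATCH style: frequencies from counts with
# a 0.25 pseudocount per base, information vector I(i) = sum_b f ln(4 f),
# per-position weighted scores I(i) * f(i, b). Returns the weight matrix and
# the min/max attainable sums for min-max normalization (consensus -> 1,
# worst sequence -> 0).
similarity_weights <- function(counts, pseudo = 0.25) {
  f <- (counts + pseudo) / rowSums(counts + pseudo)
  info <- rowSums(f * log(4 * f))
  w <- f * info
  list(w = w, lo = apply(w, 1, min), hi = apply(w, 1, max))
}

# score all windows of an integer-coded sequence (1=A..4=T, NA=N) against a
# weight matrix; returns numeric vector over leftmost positions, NA where
# any window base is N.
window_scores <- function(codes, w) {
  width <- nrow(w)
  L <- length(codes)
  if (L < width) return(numeric(0))
  npos <- L - width + 1L
  s <- numeric(npos)
  for (j in seq_len(width)) {
    s <- s + w[j, ][codes[j:(j + npos - 1L)]]
  }
  s
}

revcomp_codes <- function(codes) rev(5L - codes)

seq_to_codes <- function(sequence) {
  codes <- match(strsplit(toupper(sequence), "")[[1]],
                 c("A", "C", "G", "T"))
  codes
}

codes_to_seq <- function(codes) {
  paste(c("A", "C", "G", "T", "N")[ifelse(is.na(codes), 5L, codes)],
        collapse = "")
}

#' Promoter record
#'
#' Promoter sequence around a gene's transcription start site together with
#' an optional per-base conservation score track. By default the window
#' spans TSS-2000..TSS+2000.
#'
#' @param gene gene identifier.
#' @param sequence DNA string over A,C,G,T,N.
#' @param tss_offset 1-based index of the TSS within the sequence.
#' @param conservation numeric vector of per-base scores in `[0,1]`
#'   (`NA` = missing), same length as the sequence, or `NULL`.
#' @param planted optional data.frame describing planted sites (synthetic
#'   data bookkeeping).
#' @return object of class `PromoterRecord`.
#' @export
promoter_record <- function(gene, sequence, tss_offset,
                            conservation = NULL, planted = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (!is.null(conservation) && length(conservation) != n)
    stop("conservation track length must equal sequence length")
  if (tss_offset < 1L || tss_offset > n)
    stop("`tss_offset` outside sequence")
  structure(list(gene = as.character(gene), sequence = sequence,
                 tss_offset = as.integer(tss_offset),
                 conservation = conservation, planted = planted),
            class = "PromoterRecord")
}

#' @export
print.PromoterRecord <- function(x, ...) {
  cat(sprintf("PromoterRecord %s: %d bp, TSS at index %d%s\n", x$gene,
              nchar(x$sequence), x$tss_offset,
              if (is.null(x$conservation)) "" else ", conservation track"))
  invisible(x)
}

#' Scan a promoter with a PWM (MATCH-style similarity score)
#'
#' Scores every window on both strands with the information-vector-weighted
#' matrix similarity score, min-max normalized so a consensus match scores
#' exactly 1 and the worst-scoring sequence 0, and the analogous core score
#' over the PWM's core positions. Windows containing N are skipped.
#' Minus-strand matches are scored against the reverse complement and
#' reported at plus-strand coordinates (leftmost base, TSS-relative,
#' downstream positive).
#'
#' @param promoter a [promoter_record()].
#' @param pwm a [pwm_matrix()].
#' @param min_score minimum full-matrix similarity (default 0.85).
#' @param min_core_score minimum core similarity (default 0.90).
#' @return data.frame of binding sites: `gene`, `start` (TSS-relative),
#'   `strand`, `score`, `core_score`, `width`, `coverage` (fraction of site
#'   bases with conservation scores), `mean_conservation` (mean over covered
#'   bases; NA when the track is absent or the site uncovered).
#' @export
scan_pwm <- function(promoter, pwm, min_score = 0.85, min_core_score = 0.90) {
  codes <- seq_to_codes(promoter$sequence)
  w <- pwm$width
  if (length(codes) < w) stop("promoter shorter than PWM width")
  sw <- similarity_weights(pwm$counts)
  lo <- sum(sw$lo); hi <- sum(sw$hi)
  cs <- pwm$core[1]:pwm$core[2]
  lo_c <- sum(sw$lo[cs]); hi_c <- sum(sw$hi[cs])

  norm <- function(x, l, h) if (h > l) (x - l) / (h - l) else
    rep(1, length(x))

  hits <- list()
  for (strand in c("+", "-")) {
    wm <- sw$w
    core_rows <- cs
    if (strand == "-") {
      # reverse-complemented weight matrix scans the plus strand directly
      wm <- sw$w[w:1, 4:1, drop = FALSE]
      colnames(wm) <- c("A", "C", "G", "T")
      core_rows <- (w + 1L - pwm$core[2]):(w + 1L - pwm$core[1])
    }
    s <- norm(window_scores(codes, wm), lo, hi)
    score_core <- norm(window_scores_rows(codes, wm, core_rows), lo_c, hi_c)
    sel <- which(!is.na(s) & s >= min_score & !is.na(score_core) &
                   score_core >= min_core_score)
    if (length(sel)) {
      hits[[strand]] <- data.frame(
        gene = promoter$gene,
        start = sel - promoter$tss_offset,
        strand = strand,
        score = s[sel],
        core_score = score_core[sel],
        width = w,
        stringsAsFactors = FALSE
      )
      cons <- promoter$conservation
      if (!is.null(cons)) {
        covmean <- t(vapply(sel, function(i) {
          cv <- cons[i:(i + w - 1L)]
          c(mean(!is.na(cv)),
            if (all(is.na(cv))) NA_real_ else mean(cv, na.rm = TRUE))
        }, numeric(2)))
        hits[[strand]]$coverage <- covmean[, 1]
        hits[[strand]]$mean_conservation <- covmean[, 2]
      } else {
        hits[[strand]]$coverage <- 0
        hits[[strand]]$mean_conservation <- NA_real_
      }
    }
  }
  if (length(hits) == 0L) return(empty_sites())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

empty_sites <- function() {
  data.frame(gene = character(0), start = integer(0), strand = character(0),
             score = numeric(0), core_score = numeric(0), width = integer(0),
             coverage = numeric(0), mean_conservation = numeric(0),
             stringsAsFactors = FALSE)
}

# window scores using only a subset of matrix rows (core positions), still
# indexed at the window's leftmost base.
window_scores_rows <- function(codes, w, rows) {
  width <- nrow(w)
  L <- length(codes)
  npos <- L - width + 1L
  s <- numeric(npos)
  for (j in rows) {
    s <- s + w[j, ][codes[j:(j + npos - 1L)]]
  }
  s
}

#' Conservation filter for predicted binding sites
#'
#' A site passes when at least `min_coverage` of its bases carry
#' conservation scores and the mean score over covered bases is at least
#' `min_mean` (both thresholds inclusive).
#'
#' @param sites data.frame from [scan_pwm()].
#' @param min_coverage minimum covered fraction (default 0.8).
#' @param min_mean minimum mean conservation (default 0.6).
#' @return logical vector, one element per site.
#' @export
conservation_filter <- function(sites, min_coverage = 0.8, min_mean = 0.6) {
  sites$coverage >= min_coverage & !is.na(sites$mean_conservation) &
    sites$mean_conservation >= min_mean
}

#' Predict TF regulons from promoter scans
#'
#' Scans every promoter with every PWM, applies the conservation filter,
#' and emits one [tf_regulon()] per (TF, motif) pair; a gene is a target
#' iff it carries at least one conserved passing site.
#'
#' @param promoters list of [promoter_record()] objects.
#' @param pwms list of [pwm_matrix()] objects.
#' @param tf_map named character vector mapping motif id -> TF gene id.
#' @param min_score,min_core_score passed to [scan_pwm()].
#' @param min_coverage,min_mean passed to [conservation_filter()].
#' @return list of `TFRegulon` (motifs with no targets are omitted).
#' @export
predict_regulons <- function(promoters, pwms, tf_map, min_score = 0.85,
                             min_core_score = 0.90, min_coverage = 0.8,
                             min_mean = 0.6) {
  out <- list()
  for (pwm in pwms) {
    sites <- lapply(promoters, scan_pwm, pwm = pwm, min_score = min_score,
                    min_core_score = min_core_score)
    sites <- do.call(rbind, sites)
    if (!is.null(sites) && nrow(sites)) {
      keep <- conservation_filter(sites, min_coverage, min_mean)
      sites <- sites[keep, , drop = FALSE]
    }
    if (is.null(sites) || nrow(sites) == 0L) next
    tf <- unname(tf_map[pwm$id])
    if (is.na(tf)) stop(sprintf("no TF mapped for motif '%s'", pwm$id))
    targets <- setdiff(unique(sites$gene), tf)
    if (length(targets) == 0L) next
    out[[length(out) + 1L]] <-
      tf_regulon(tf, pwm$id, targets,
                 sites = sites[sites$gene %in% targets, , drop = FALSE])
  }
  out
}

#' Test whether binding sites cluster near the TSS
#'
#' One-sided Kolmogorov-Smirnov test of the absolute TSS distances against
#' Uniform(0, `half_window`), alternative: distances stochastically smaller
#' than uniform (sites closer to the TSS than random placement).
#'
#' @param sites data.frame with a `start` column of TSS-relative positions.
#' @param half_window promoter half-width in bp (default 2000).
#' @return list with `ks_p`, `median_abs_distance`, `n`.
#' @export
tss_proximity_test <- function(sites, half_window = 2000) {
  if (nrow(sites) == 0L) stop("`sites` must be non-empty")
  d <- abs(sites$start)
  ks <- suppressWarnings(
    stats::ks.test(d, "punif", 0, half_window, alternative = "greater"))
  list(ks_p = ks$p.value, median_abs_distance = stats::median(d),
       n = length(d))
}

#' Dinucleotide-preserving sequence shuffle (Euler-path method)
#'
#' Randomizes a DNA sequence while keeping all 16 dinucleotide counts
#' exactly fixed (Altschul-Erickson algorithm): the sequence is viewed as an
#' Eulerian path on the 4-letter transition multigraph, a random last-edge
#' arborescence toward the final letter is drawn, the remaining out-edges
#' are shuffled, and the path is re-walked. First and last base are
#' invariant.
#'
#' @param sequence DNA string (length >= 2; letters beyond A,C,G,T are
#'   handled as additional vertices).
#' @param seed optional RNG seed; `NULL` uses the ambient RNG stream.
#' @return shuffled character string.
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  local_seed_if(seed)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < 2L) stop("sequence must have length >= 2")
  letters_u <- unique(chars)
  v <- match(chars, letters_u)
  k <- length(letters_u)
  last <- v[n]
  # out-edge target lists per vertex
  out_edges <- split(v[-1L], v[-n])
  out_edges <- lapply(seq_len(k), function(i)
    out_edges[[as.character(i)]] %||% integer(0))
  # choose designated last edges forming an arborescence toward `last`
  has_out <- which(vapply(out_edges, length, integer(1)) > 0L)
  need <- setdiff(has_out, last)
  pick_ok <- FALSE
  for (attempt in seq_len(1000L)) {
    f <- rep(NA_integer_, k)
    for (vv in need) {
      targ <- out_edges[[vv]]
      f[vv] <- targ[sample.int(length(targ), 1L)]
    }
    ok <- TRUE
    for (vv in need) {
      cur <- vv
      steps <- 0L
      while (!is.na(cur) && cur != last && steps <= k) {
        cur <- f[cur]
        steps <- steps + 1L
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) { pick_ok <- TRUE; break }
  }
  if (!pick_ok) return(sequence) # degenerate; keep original ordering
  # build shuffled out-edge queues: remaining edges in random order, the
  # designated last edge appended at the end
  queues <- vector("list", k)
  for (vv in seq_len(k)) {
    e <- out_edges[[vv]]
    if (vv %in% need) {
      li <- match(f[vv], e)
      e <- e[-li]
      e <- c(if (length(e)) e[sample.int(length(e))] else integer(0), f[vv])
    } else if (length(e)) {
      e <- e[sample.int(length(e))]
    }
    queues[[vv]] <- e
  }
  ptr <- rep(1L, k)
  res <- integer(n)
  res[1L] <- v[1L]
  cur <- v[1L]
  for (i in 2:n) {
    nxt <- queues[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(letters_u[res], collapse = "")
}

#' Shuffle conservation scores within base types
#'
#' Permutes the per-base conservation scores only among positions sharing
#' the same base letter, so the multiset of scores per nucleotide type is
#' preserved exactly.
#'
#' @param promoter a [promoter_record()] with a conservation track.
#' @param seed optional RNG seed.
#' @return shuffled conservation vector.
#' @export
shuffle_conservation <- function(promoter, seed = NULL) {
  local_seed_if(seed)
  if (is.null(promoter$conservation)) stop("conservation track absent")
  cons <- promoter$conservation
  chars <- strsplit(promoter$sequence, "")[[1]]
  for (b in unique(chars)) {
    idx <- which(chars == b)
    if (length(idx) > 1L)
      cons[idx] <- cons[idx[sample.int(length(idx))]]
  }
  cons
}

#' Binding-site prediction null by promoter shuffling
#'
#' Generates `n_batches` randomized versions of every promoter
#' (dinucleotide-preserving sequence shuffle plus per-base-type conservation
#' shuffle), reruns the conserved-site prediction on each batch, and counts
#' how many genes would still be predicted as targets by chance.
#'
#' @param promoters list of [promoter_record()] objects.
#' @param pwm a [pwm_matrix()].
#' @param n_batches number of shuffled batches (default 1000).
#' @param min_score,min_core_score,min_coverage,min_mean prediction
#'   thresholds as in [predict_regulons()].
#' @param seed RNG seed.
#' @return list with `observed` (genes predicted on the real promoters),
#'   `batch_counts`, `expected_count` (median batch count) and `fdr`
#'   (`expected_count / observed`; NA when observed is 0).
#' @export
binding_site_null <- function(promoters, pwm, n_batches = 1000,
                              min_score = 0.85, min_core_score = 0.90,
                              min_coverage = 0.8, min_mean = 0.6,
                              seed = 1) {
  local_seed_if(seed)
  predicted_count <- function(proms) {
    sum(vapply(proms, function(pr) {
      s <- scan_pwm(pr, pwm, min_score, min_core_score)
      any(conservation_filter(s, min_coverage, min_mean))
    }, logical(1)))
  }
  observed <- predicted_count(promoters)
  batch_counts <- vapply(seq_len(n_batches), function(b) {
    sh <- lapply(promoters, function(pr) {
      pr$sequence <- dinucleotide_shuffle(pr$sequence)
      if (!is.null(pr$conservation))
        pr$conservation <- shuffle_conservation(pr)
      pr
    })
    predicted_count(sh)
  }, numeric(1))
  expected <- stats::median(batch_counts)
  list(observed = observed, batch_counts = batch_counts,
       expected_count = expected,
       fdr = if (observed > 0) expected / observed else NA_real_)
}

#' Overlap between binding sites and open-chromatin intervals
#'
#' Observed statistic: number of genes with at least one predicted site
#' overlapping (>= 1 base) a DNase-hypersensitive interval. Null: for each
#' gene, width-matched stretches are drawn uniformly from the positions of
#' its promoter whose G/C content is at least `gc_floor` (matching the
#' G/C-richness of the real sites), and the per-iteration count of
#' overlapping genes is recorded. Genes whose promoter has no qualifying
#' stretch are excluded from the null with a warning.
#'
#' @param sites data.frame of sites (`gene`, `start`, `width`,
#'   TSS-relative).
#' @param dnase data.frame of intervals (`gene`, `start`, `end`,
#'   TSS-relative half-open).
#' @param promoters list of [promoter_record()] objects.
#' @param gc_floor minimum G/C fraction of null stretches (default 0.79).
#' @param n_rand null iterations (default 1000).
#' @param seed RNG seed.
#' @return list with `n_genes_overlapping`, `expected` (median null count),
#'   `p` (fraction of null iterations with count >= observed), `n_rand`,
#'   `genes_in_null`.
#' @export
dnase_overlap_test <- function(sites, dnase, promoters, gc_floor = 0.79,
                               n_rand = 1000, seed = 1) {
  local_seed_if(seed)
  proms <- stats::setNames(promoters,
                           vapply(promoters, `[[`, "", "gene"))
  genes <- unique(sites$gene)
  overlap_any <- function(starts, widths, iv) {
    if (nrow(iv) == 0L) return(rep(FALSE, length(starts)))
    vapply(seq_along(starts), function(i) {
      any(pmax(starts[i], iv$start) < pmin(starts[i] + widths[i], iv$end))
    }, logical(1))
  }
  obs_flags <- vapply(genes, function(g) {
    ss <- sites[sites$gene == g, , drop = FALSE]
    iv <- dnase[dnase$gene == g, , drop = FALSE]
    any(overlap_any(ss$start, ss$width, iv))
  }, logical(1))
  observed <- sum(obs_flags)
  if (nrow(dnase) == 0L)
    return(list(n_genes_overlapping = 0L, expected = 0, p = 1,
                n_rand = n_rand, genes_in_null = character(0)))
  null_mat <- list()
  for (g in genes) {
    pr <- proms[[g]]
    if (is.null(pr)) stop(sprintf("gene '%s' has sites but no promoter", g))
    w <- sites$width[sites$gene == g][1L]
    chars <- strsplit(pr$sequence, "")[[1]]
    gc <- as.integer(chars %in% c("G", "C"))
    win_gc <- cumsum(gc)
    npos <- length(gc) - w + 1L
    frac <- (win_gc[w:length(gc)] -
               c(0, win_gc)[seq_len(npos)]) / w
    qual <- which(frac >= gc_floor)
    if (length(qual) == 0L) {
      warning(sprintf("gene '%s': no stretch with G/C >= %.2f; excluded",
                      g, gc_floor))
      next
    }
    # uniform draw over qualifying positions == acceptance-rejection on
    # uniform placement with the G/C floor
    starts_local <- qual[sample.int(length(qual), n_rand, replace = TRUE)]
    starts_rel <- starts_local - pr$tss_offset
    iv <- dnase[dnase$gene == g, , drop = FALSE]
    null_mat[[g]] <- overlap_any(starts_rel, rep(w, n_rand), iv)
  }
  if (length(null_mat) == 0L) stop("no gene usable in the null")
  counts <- Reduce(`+`, null_mat)
  list(n_genes_overlapping = observed, expected = stats::median(counts),
       p = mean(counts >= observed), n_rand = n_rand,
       genes_in_null = names(null_mat))
}

#' Compare two per-gene score distributions
#'
#' Rank-sum test on arbitrary per-gene score tables (mean promoter
#' conservation, dN/dS, promoter divergence, ...), with the stated
#' alternative for the foreground relative to the background.
#'
#' @param foreground,background numeric score vectors.
#' @param alternative `"less"`, `"greater"` or `"two.sided"` (foreground vs
#'   background).
#' @return the rank-sum p-value.
#' @export
compare_score_distributions <- function(foreground, background,
                                        alternative = c("two.sided", "less",
                                                        "greater")) {
  alternative <- match.arg(alternative)
  if (length(foreground) == 0L || length(background) == 0L)
    stop("both score sets must be non-empty")
  ranksum_test(foreground, background, alternative = alternative)$p.value
}
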