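# Readers and writers for the plain-text interchange formats the pipeline
# uses: expression/metadata/regulon/annotation/atlas TSVs, promoter FASTA
# (headers "gene|tss_offset") via Biostrings, per-base conservation TSV,
# BED intervals via rtracklayer, and TRANSFAC-format PWMs.

#' Write / read an expression study as TSV
#'
#' The expression table has the gene id in the first column (`gene`) and one
#' column per sample; the metadata table has columns `sample`, `group`,
#' `batch`, `dataset`.
#'
#' @param study an [expression_study()].
#' @param expr_path,meta_path file paths.
#' @return `read_expression_tsv` returns an `ExpressionStudy`.
#' @export
write_expression_tsv <- function(study, expr_path, meta_path) {
  df <- data.frame(gene = study_genes(study), study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample = study_samples(study), group = study$group,
                     batch = study$batch %||% NA,
                     dataset = study$dataset, stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, meta_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(expr_path, meta_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  idx <- match(colnames(v), meta$sample)
  if (anyNA(idx)) stop("metadata missing samples: ",
                       paste(colnames(v)[is.na(idx)], collapse = ", "))
  batch <- meta$batch[idx]
  if (all(is.na(batch))) batch <- NULL
  expression_study(v, group = meta$group[idx], batch = batch,
                   dataset = meta$dataset[idx][1])
}

#' Write / read promoters as FASTA plus a conservation TSV
#'
#' FASTA headers are `gene|tss_offset`; the conservation table has columns
#' `gene`, `pos` (1-based position in the record) and `score`, one row per
#' scored base (bedGraph-like; unscored bases are simply absent).
#'
#' @param promoters list of [promoter_record()] objects.
#' @param fasta_path,cons_path file paths (`cons_path = NULL` skips the
#'   track).
#' @return `read_promoters_fasta` returns a list of `PromoterRecord`.
#' @export
write_promoters_fasta <- function(promoters, fasta_path, cons_path = NULL) {
  seqs <- Biostrings::DNAStringSet(vapply(promoters, `[[`, "", "sequence"))
  names(seqs) <- vapply(promoters, function(p)
    sprintf("%s|%d", p$gene, p$tss_offset), "")
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(cons_path)) {
    rows <- lapply(promoters, function(p) {
      if (is.null(p$conservation)) return(NULL)
      keep <- !is.na(p$conservation)
      data.frame(gene = p$gene, pos = which(keep),
                 score = p$conservation[keep])
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, cons_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta_path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(fasta_path, cons_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  cons_tab <- if (!is.null(cons_path))
    utils::read.delim(cons_path, stringsAsFactors = FALSE) else NULL
  lapply(seq_along(seqs), function(i) {
    hdr <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    if (length(hdr) != 2L)
      stop("FASTA header must be 'gene|tss_offset': ", names(seqs)[i])
    s <- as.character(seqs[[i]])
    cons <- NULL
    if (!is.null(cons_tab)) {
      sub <- cons_tab[cons_tab$gene == hdr[1], , drop = FALSE]
      if (nrow(sub)) {
        cons <- rep(NA_real_, nchar(s))
        cons[sub$pos] <- sub$score
      }
    }
    promoter_record(hdr[1], s, as.integer(hdr[2]), conservation = cons)
  })
}

#' Write / read gene-local intervals as BED
#'
#' BED uses the gene id as the sequence name and promoter-local 0-based
#' half-open coordinates; in memory intervals are TSS-relative, so the
#' promoters' TSS offsets are needed for the conversion.
#'
#' @param intervals data.frame `gene`, `start`, `end` (TSS-relative).
#' @param promoters list of [promoter_record()] supplying `tss_offset` per
#'   gene.
#' @param path BED file path.
#' @return `read_bed_intervals` returns the TSS-relative data.frame.
#' @export
write_bed_intervals <- function(intervals, promoters, path) {
  tss <- stats::setNames(vapply(promoters, `[[`, 1L, "tss_offset"),
                         vapply(promoters, `[[`, "", "gene"))
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$gene,
    ranges = IRanges::IRanges(
      start = intervals$start + tss[intervals$gene], # 1-based inclusive
      end = intervals$end + tss[intervals$gene] - 1L
    )
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed_intervals
#' @export
read_bed_intervals <- function(path, promoters) {
  tss <- stats::setNames(vapply(promoters, `[[`, 1L, "tss_offset"),
                         vapply(promoters, `[[`, "", "gene"))
  gr <- rtracklayer::import(path, format = "BED")
  g <- as.character(GenomicRanges::seqnames(gr))
  data.frame(gene = g,
             start = GenomicRanges::start(gr) - tss[g],
             end = GenomicRanges::end(gr) + 1L - tss[g],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read regulons as TSV
#'
#' One row per (tf, motif, target); site columns are filled when sites are
#' attached.
#'
#' @param regulons list of [tf_regulon()] objects.
#' @param path file path.
#' @return `read_regulon_tsv` returns a list of `TFRegulon`.
#' @export
write_regulon_tsv <- function(regulons, path) {
  rows <- lapply(regulons, function(r) {
    base <- data.frame(tf = r$tf, motif = r$motif, target = r$targets,
                       stringsAsFactors = FALSE)
    if (!is.null(r$sites) && nrow(r$sites)) {
      s <- r$sites
      data.frame(tf = r$tf, motif = r$motif, target = s$gene,
                 site_start = s$start, site_strand = s$strand,
                 site_score = s$score,
                 site_mean_conservation = s$mean_conservation,
                 stringsAsFactors = FALSE)
    } else {
      base$site_start <- NA_integer_
      base$site_strand <- NA_character_
      base$site_score <- NA_real_
      base$site_mean_conservation <- NA_real_
      base
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_regulon_tsv
#' @export
read_regulon_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  keys <- unique(tab[, c("tf", "motif")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$tf == keys$tf[i] & tab$motif == keys$motif[i], ,
               drop = FALSE]
    sites <- NULL
    if ("site_start" %in% names(sub) && any(!is.na(sub$site_start))) {
      sites <- data.frame(gene = sub$target, start = sub$site_start,
                          strand = sub$site_strand, score = sub$site_score,
                          mean_conservation = sub$site_mean_conservation,
                          stringsAsFactors = FALSE)
    }
    tf_regulon(keys$tf[i], keys$motif[i], unique(sub$target), sites = sites)
  })
}

#' Read a TRANSFAC-format position count matrix
#'
#' Parses the classical TRANSFAC matrix layout: an `ID` line, a `P0` header
#' row naming the base columns, numbered count rows, and `//` terminators.
#' An optional `CC core: i-j` comment line sets the core element range.
#'
#' @param path matrix file (may contain several matrices).
#' @return list of [pwm_matrix()] objects.
#' @export
read_transfac_pwm <- function(path) {
  lines <- readLines(path)
  out <- list()
  id <- NULL; rows <- list(); core <- NULL
  flush <- function() {
    if (!is.null(id) && length(rows)) {
      m <- do.call(rbind, rows)
      out[[length(out) + 1L]] <<- pwm_matrix(id, m, core)
    }
    id <<- NULL; rows <<- list(); core <<- NULL
  }
  for (ln in lines) {
    if (grepl("^ID\\s", ln)) {
      flush()
      id <- sub("^ID\\s+", "", ln)
    } else if (grepl("^CC\\s+core:", ln)) {
      core <- as.integer(strsplit(sub(".*core:\\s*", "", ln), "-")[[1]])
    } else if (grepl("^\\d\\d\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(f[2:5])
    } else if (grepl("^//", ln)) {
      flush()
    }
  }
  flush()
  out
}

#' Write / read a tissue atlas as TSV
#' @param atlas a [tissue_atlas()].
#' @param path file path.
#' @param species,focal_tissue identifiers used when reading.
#' @return `read_atlas_tsv` returns a `TissueAtlas`.
#' @export
write_atlas_tsv <- function(atlas, path) {
  df <- data.frame(gene = rownames(atlas$values), atlas$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path, species, focal_tissue) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  tissue_atlas(v, species, focal_tissue)
}

#' Read a flat gene-to-category annotation TSV
#'
#' Columns `gene`, `category`, optional `namespace` (filterable).
#'
#' @param path file path.
#' @param namespace optional namespace to keep (e.g.
#'   `"biological_process"`).
#' @return a [category_annotation()].
#' @export
read_annotation_tsv <- function(path, namespace = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(namespace) && "namespace" %in% names(tab))
    tab <- tab[tab$namespace == namespace, , drop = FALSE]
  category_annotation(tab)
}
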