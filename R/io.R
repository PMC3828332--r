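#' Read isoform models from a GTF file
#'
#' Parses the exon features of a GTF annotation (1-based inclusive
#' coordinates, as written by Cufflinks-style tools) into the isoform-model
#' tables used throughout the package.  All coordinates are converted to
#' 0-based half-open on input.
#'
#' @param path Path to a GTF file whose exon features carry `transcript_id`
#'   and `gene_id` attributes.
#' @return A list of class `isoform_models` with two data frames:
#'   `transcripts` (`isoform_id`, `gene_id`, `chrom`, `strand`, `tss` where
#'   `tss` is the 0-based genomic position of the transcription start base)
#'   and `exons` (`isoform_id`, `start`, `end`, 0-based half-open, sorted by
#'   genomic position within each isoform).
#' @export
read_isoform_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  check_that(length(gr) > 0L, "no exon features found in %s", path)
  df <- data.frame(
    isoform_id = as.character(gr$transcript_id),
    gene_id    = as.character(gr$gene_id),
    chrom      = as.character(GenomicRanges::seqnames(gr)),
    strand     = as.character(GenomicRanges::strand(gr)),
    start      = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end        = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  isoform_models_from_exons(df)
}

# Build an isoform_models object from a 0-based half-open exon table.
isoform_models_from_exons <- function(exons) {
  check_that(all(exons$strand %in% c("+", "-")),
             "isoform strand must be '+' or '-'")
  exons <- exons[order(exons$isoform_id, exons$start), , drop = FALSE]
  check_that(all(exons$start < exons$end), "malformed exon interval")
  first <- !duplicated(exons$isoform_id)
  tx <- exons[first, c("isoform_id", "gene_id", "chrom", "strand")]
  tss_plus  <- tapply(exons$start, exons$isoform_id, min)
  tss_minus <- tapply(exons$end, exons$isoform_id, max) - 1L
  tx$tss <- ifelse(tx$strand == "+",
                   tss_plus[tx$isoform_id], tss_minus[tx$isoform_id])
  rownames(tx) <- NULL
  # overlap within an isoform is malformed input
  by_iso <- split(exons, exons$isoform_id)
  for (e in by_iso) {
    if (nrow(e) > 1L)
      check_that(all(e$end[-nrow(e)] <= e$start[-1L]),
                 "overlapping exons in isoform %s", e$isoform_id[1L])
  }
  ex_out <- exons[, c("isoform_id", "start", "end")]
  rownames(ex_out) <- NULL
  structure(list(transcripts = tx, exons = ex_out),
            class = "isoform_models")
}

#' @export
print.isoform_models <- function(x, ...) {
  cat(sprintf("isoform_models: %d isoforms, %d exons on %d contig(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

# Write isoform models as GTF (exon features, 1-based inclusive).
write_isoform_gtf <- function(models, path) {
  tx <- models$transcripts
  ex <- merge(models$exons, tx, by = "isoform_id", sort = FALSE)
  ex <- ex[order(ex$isoform_id, ex$start), ]
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id, ex$isoform_id)
  lines <- paste(ex$chrom, "tsnet", "exon", ex$start + 1L, ex$end,
                 ".", ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read position weight matrices from a JASPAR-format text file
#'
#' Parses the JASPAR 2016 flat-text format (`>ID NAME` header followed by
#' four bracketed count rows for A, C, G, T).  Counts are normalised to
#' per-position base probabilities.
#'
#' @param path Path to a JASPAR-format PWM file.
#' @param background Background base frequencies (A, C, G, T); must sum to 1.
#' @param pseudocount Probability pseudocount added before log-odds scoring.
#' @return A named list of `tsnet_pwm` objects (named by factor name).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  check_that(length(heads) > 0L, "no JASPAR records in %s", path)
  pwms <- lapply(heads, function(h) {
    fields <- strsplit(sub("^>", "", lines[h]), "[ \t]+")[[1L]]
    name <- if (length(fields) >= 2L) fields[2L] else fields[1L]
    rows <- lines[(h + 1L):(h + 4L)]
    nums <- lapply(rows, function(r) {
      body <- sub("^[ACGTacgt]", "", r)
      as.numeric(regmatches(body, gregexpr("[0-9.]+", body))[[1L]])
    })
    check_that(length(unique(lengths(nums))) == 1L,
               "JASPAR record %s: ragged count rows", name)
    counts <- do.call(rbind, nums)
    bases <- toupper(substr(trimws(rows), 1L, 1L))
    check_that(identical(bases, c("A", "C", "G", "T")),
               "JASPAR record %s: rows must be A, C, G, T", name)
    rownames(counts) <- bases
    pwm(name, counts, background = background, pseudocount = pseudocount)
  })
  names(pwms) <- vapply(pwms, function(p) p$factor, character(1L))
  pwms
}

#' Construct a position weight matrix model
#'
#' @param factor Factor name.
#' @param counts 4 x L matrix of base counts or probabilities with rows
#'   A, C, G, T; each column is normalised to sum to 1.
#' @param background Background base frequencies (length 4, sums to 1).
#' @param pseudocount Probability pseudocount (> 0) added to each entry
#'   (followed by renormalisation) before log-odds scoring, so zero counts
#'   never produce infinite scores.
#' @return A `tsnet_pwm` object with elements `factor`, `prob` (4 x L
#'   probability matrix), `background`, `pseudocount`.
#' @export
pwm <- function(factor, counts, background = rep(0.25, 4), pseudocount = 0.01) {
  counts <- as.matrix(counts)
  check_that(nrow(counts) == 4L, "PWM must have 4 rows (A,C,G,T)")
  check_that(ncol(counts) >= 3L, "PWM must have length >= 3")
  check_that(all(counts >= 0), "PWM counts must be non-negative")
  check_that(abs(sum(background) - 1) < 1e-9, "background must sum to 1")
  check_that(pseudocount > 0, "pseudocount must be > 0")
  prob <- sweep(counts, 2L, colSums(counts), "/")
  rownames(prob) <- c("A", "C", "G", "T")
  structure(list(factor = factor, prob = prob,
                 background = background, pseudocount = pseudocount),
            class = "tsnet_pwm")
}

# Log2-odds score matrix of a PWM after pseudocount regularisation.
pwm_score_matrix <- function(p) {
  pr <- (p$prob + p$pseudocount) / (1 + 4 * p$pseudocount)
  log2(pr / p$background)
}

# Maximum achievable log-odds score.
pwm_max_score <- function(p) sum(apply(pwm_score_matrix(p), 2L, max))

# Consensus sequence (per-position argmax; ties broken A<C<G<T).
pwm_consensus <- function(p) {
  paste(rownames(p$prob)[apply(p$prob, 2L, which.max)], collapse = "")
}

# Write PWMs in JASPAR 2016 text (counts scaled to integers out of 100).
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    counts <- round(p$prob * 100)
    writeLines(sprintf(">M%04d\t%s", i, p$factor), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(counts[b, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Load a base-wise conservation track
#'
#' Reads a bedGraph conservation track (phyloP-scale scores) into per-contig
#' run-length vectors supporting exact per-base queries.  Bases not covered
#' by any interval are distinguished from score-zero bases.
#'
#' @param path Path to a bedGraph file (0-based half-open intervals).
#' @return An object of class `cons_track`.
#' @export
read_conservation <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  check_that(length(gr) > 0L, "empty conservation track %s", path)
  ends <- tapply(GenomicRanges::end(gr),
                 as.character(GenomicRanges::seqnames(gr)), max)
  GenomeInfoDb::seqlengths(gr) <- ends[GenomeInfoDb::seqlevels(gr)]
  structure(list(score = GenomicRanges::coverage(gr, weight = "score"),
                 covered = GenomicRanges::coverage(gr)),
            class = "cons_track")
}

#' Query per-base conservation scores
#'
#' @param track A `cons_track` from [read_conservation()].
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval.
#' @return Numeric vector of length `end - start`, one score per base.
#'   Querying any base outside the track's coverage is an error.
#' @export
conservation_scores <- function(track, chrom, start, end) {
  check_that(start < end, "empty conservation query")
  check_that(chrom %in% names(track$score),
             "contig %s not in conservation track", chrom)
  len <- length(track$score[[chrom]])
  check_that(start >= 0 && end <= len,
             "query [%d,%d) outside conservation coverage of %s", start, end, chrom)
  idx <- (start + 1L):end
  cov <- as.numeric(track$covered[[chrom]][idx])
  check_that(all(cov > 0),
             "query [%d,%d) on %s includes uncovered bases", start, end, chrom)
  as.numeric(track$score[[chrom]][idx]) / cov
}

#' Read a splicing-factor motif table
#'
#' Reads a SpliceAid-style TSV with columns `factor`, `motif`, `score`.
#' Motifs are uppercased and RNA `U` is mapped to `T`.  Positive scores mark
#' enhancer-type elements, negative scores silencer-type; the absolute value
#' measures binding affinity.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `factor`, `motif`, `score`.
#' @export
read_sf_motifs <- function(path) {
  df <- read_tsv(path)
  check_that(all(c("factor", "motif", "score") %in% names(df)),
             "sf motif table must have columns factor, motif, score")
  df$motif <- chartr("Uu", "Tt", toupper(df$motif))
  bad <- grepl("[^ACGT]", df$motif)
  check_that(!any(bad), "motif with non-ACGTU characters: %s",
             paste(df$motif[bad], collapse = ", "))
  df[, c("factor", "motif", "score")]
}

#' Read gene-set collections from a GMT file
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Read a per-sample isoform expression table
#'
#' The table carries one row per isoform with metadata columns
#' `isoform_id`, `gene_id`, `protein_evidence` (0/1), `de_flag` (0/1) and
#' `up_condition`, followed by one numeric column per sample named
#' `<condition>_<replicate>` (FPKM-scale values).
#'
#' @param path Path to the TSV file.
#' @return A list of class `expression_table` with elements `info` (metadata
#'   data frame), `fpkm` (isoforms x samples numeric matrix) and `condition`
#'   (condition label per sample column).
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  meta_cols <- c("isoform_id", "gene_id", "protein_evidence", "de_flag",
                 "up_condition")
  check_that(all(meta_cols %in% names(df)),
             "expression table must carry columns %s",
             paste(meta_cols, collapse = ", "))
  sample_cols <- setdiff(names(df), meta_cols)
  check_that(length(sample_cols) >= 2L, "need at least 2 sample columns")
  fpkm <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(fpkm) <- df$isoform_id
  storage.mode(fpkm) <- "double"
  cond <- sub("_[^_]*$", "", sample_cols)
  info <- df[, meta_cols]
  info$protein_evidence <- as.logical(df$protein_evidence)
  info$de_flag <- as.logical(df$de_flag)
  structure(list(info = info, fpkm = fpkm, condition = cond),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d isoforms x %d samples (%s)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

write_expression <- function(expr, path) {
  df <- cbind(expr$info,
              as.data.frame(expr$fpkm, check.names = FALSE))
  df$protein_evidence <- as.integer(df$protein_evidence)
  df$de_flag <- as.integer(df$de_flag)
  write_tsv(df, path)
}
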