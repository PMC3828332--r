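#' Filter splicing-factor motifs
#'
#' Applies the affinity and length filters used to control false positives
#' in SF motif scanning: motifs are kept when the absolute value of their
#' signed affinity score is at least `min_abs_score` and their length is at
#' most `max_len`.  Both boundaries are inclusive.
#'
#' @param motifs Data frame with columns `factor`, `motif`, `score`
#'   ([read_sf_motifs()]).
#' @param min_abs_score Minimum absolute affinity score (default 5).
#' @param max_len Maximum motif length (default 15).
#' @return The filtered data frame.
#' @export
filter_sf_motifs <- function(motifs, min_abs_score = 5, max_len = 15L) {
  motifs$motif <- chartr("Uu", "Tt", toupper(motifs$motif))
  bad <- grepl("[^ACGT]", motifs$motif)
  check_that(!any(bad), "motif with non-ACGTU characters: %s",
             paste(motifs$motif[bad], collapse = ", "))
  keep <- abs(motifs$score) >= min_abs_score & nchar(motifs$motif) <= max_len
  motifs[keep, , drop = FALSE]
}

#' Extract splice-site windows (EID)
#'
#' For each internal splice site of each multi-exon isoform (each exon end
#' abutting an intron and each exon start following an intron), emits the
#' window `[site - flank, site + flank)`, clipped to contig bounds.
#' Overlapping windows of the same isoform are merged.  Single-exon
#' isoforms contribute no windows.
#'
#' @param models An `isoform_models` object.
#' @param flank Flank size in bp on each side of a splice site (default 200).
#' @param contig_lengths Optional named vector of contig lengths used for
#'   clipping.
#' @return Data frame with columns `isoform`, `chrom`, `start`, `end`
#'   (0-based half-open genomic intervals).
#' @export
extract_splice_windows <- function(models, flank = 200L,
                                   contig_lengths = NULL) {
  out <- list()
  ex_by_iso <- split(models$exons, models$exons$isoform_id)
  tx <- models$transcripts
  for (iso in names(ex_by_iso)) {
    e <- ex_by_iso[[iso]]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) next
    chrom <- tx$chrom[match(iso, tx$isoform_id)]
    sites <- sort(c(e$end[-nrow(e)], e$start[-1L]))  # donor + acceptor
    w <- IRanges::IRanges(start = sites - flank + 1L, end = sites + flank)
    w <- IRanges::reduce(w)
    s <- pmax(IRanges::start(w) - 1L, 0L)
    en <- IRanges::end(w)
    if (!is.null(contig_lengths) && chrom %in% names(contig_lengths))
      en <- pmin(en, contig_lengths[[chrom]])
    out[[length(out) + 1L]] <- data.frame(
      isoform = iso, chrom = chrom, start = s, end = en,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(isoform = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

#' Score splicing-factor motif hits with conservation
#'
#' Finds exact occurrences of each (already filtered) SF motif on the
#' isoform's sense strand within its splice windows, scores each hit by
#' the mean per-base conservation over the spanned nucleotides, deletes
#' hits with conservation below `conservation_min`, and de-duplicates hits
#' at identical coordinates.
#'
#' @param windows Data frame from [extract_splice_windows()].
#' @param motifs Filtered SF motif data frame ([filter_sf_motifs()]).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param track A `cons_track` ([read_conservation()]).
#' @param models The `isoform_models` (for isoform strand).
#' @param conservation_min Minimum mean conservation of a retained hit;
#'   hits exactly at the threshold are kept (default 2).
#' @return Data frame with columns `factor`, `isoform`, `chrom`, `start`,
#'   `end` (genomic, 0-based half-open) and `conservation`.
#' @export
score_sf_hits <- function(windows, motifs, genome, track, models,
                          conservation_min = 2) {
  strand_of <- models$transcripts$strand
  names(strand_of) <- models$transcripts$isoform_id
  out <- list()
  for (w in seq_len(nrow(windows))) {
    chrom <- windows$chrom[w]; ws <- windows$start[w]; we <- windows$end[w]
    iso <- windows$isoform[w]
    seq_w <- Biostrings::subseq(genome[[chrom]], ws + 1L, we)
    sense_minus <- identical(strand_of[[iso]], "-")
    if (sense_minus) seq_w <- Biostrings::reverseComplement(seq_w)
    seq_chr <- toupper(as.character(seq_w))
    wlen <- we - ws
    for (m in seq_len(nrow(motifs))) {
      mot <- motifs$motif[m]
      hits <- gregexpr(mot, seq_chr, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      for (h in hits) {
        # map sense-strand hit back to genomic coordinates
        if (sense_minus) {
          g_end <- we - (h - 1L); g_start <- g_end - nchar(mot)
        } else {
          g_start <- ws + h - 1L; g_end <- g_start + nchar(mot)
        }
        cons <- mean(conservation_scores(track, chrom, g_start, g_end))
        if (cons >= conservation_min)
          out[[length(out) + 1L]] <- data.frame(
            factor = motifs$factor[m], isoform = iso, chrom = chrom,
            start = g_start, end = g_end, conservation = cons,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(factor = character(0), isoform = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), conservation = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[!duplicated(df[, c("factor", "isoform", "chrom", "start", "end")]), ]
  rownames(df) <- NULL
  df[order(df$isoform, df$factor, df$start), , drop = FALSE]
}

#' Build the SF interaction-strength matrix
#'
#' The strength of a splicing factor on an isoform is the mean conservation
#' over its retained hits on that isoform (averaging removes the influence
#' of exon number); pairs with no retained hits have strength 0.
#'
#' @param hits Data frame from [score_sf_hits()] (already
#'   conservation-filtered).
#' @param isoforms Character vector of isoform ids (rows).
#' @param factors Character vector of SF names (columns).
#' @return A `strength_matrix` (isoforms x factors), attribute
#'   `flavor = "SF"`; every nonzero entry carries the conservation floor.
#' @export
sf_strength_matrix <- function(hits, isoforms, factors) {
  if (nrow(hits)) {
    bad_iso <- setdiff(unique(hits$isoform), isoforms)
    bad_fac <- setdiff(unique(hits$factor), factors)
    check_that(length(bad_iso) == 0L, "hit references unknown isoform: %s",
               paste(bad_iso, collapse = ", "))
    check_that(length(bad_fac) == 0L, "hit references unknown factor: %s",
               paste(bad_fac, collapse = ", "))
  }
  m <- matrix(0, length(isoforms), length(factors),
              dimnames = list(isoforms, factors))
  if (nrow(hits)) {
    agg <- tapply(hits$conservation, list(hits$isoform, hits$factor), mean)
    m[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  }
  structure(m, flavor = "SF", class = c("strength_matrix", class(m)))
}

#' Default paralogous hnRNP merge groups
#'
#' Paralogous hnRNP factors produced by alternative splicing share motifs
#' and binding profiles; their strength columns are near-collinear and are
#' merged by element-wise averaging into composite factors.
#'
#' @return Named list: composite factor name -> member factor names.
#' @export
default_paralog_groups <- function() {
  list("hnRNPA1/A2"    = c("hnRNP A1", "hnRNP A2"),
       "hnRNPH1/H2/H3" = c("hnRNP H1", "hnRNP H2", "hnRNP H3"),
       "hnRNPC/C1/C2"  = c("hnRNP C", "hnRNP C1", "hnRNP C2"),
       "hnRNPE1/E2"    = c("hnRNP E1", "hnRNP E2"))
}

#' Merge paralogous factor columns of a strength matrix
#'
#' Each merge group's member columns are replaced by a single column equal
#' to their element-wise mean; other columns are untouched.
#'
#' @param m A `strength_matrix`.
#' @param merge_groups Named list mapping new composite names to member
#'   factor names (see [default_paralog_groups()]).
#' @return The merged `strength_matrix`.
#' @export
merge_paralog_factors <- function(m, merge_groups) {
  flavor <- attr(m, "flavor")
  for (newname in names(merge_groups)) {
    members <- merge_groups[[newname]]
    missing <- setdiff(members, colnames(m))
    check_that(length(missing) == 0L,
               "merge group %s: member(s) missing from matrix: %s",
               newname, paste(missing, collapse = ", "))
    merged <- rowMeans(m[, members, drop = FALSE])
    keep <- setdiff(colnames(m), members)
    m <- cbind(m[, keep, drop = FALSE], merged)
    colnames(m)[ncol(m)] <- newname
  }
  structure(m, flavor = flavor, class = c("strength_matrix", "matrix", "array"))
}

#' Genome-wide single-factor target scan
#'
#' Scans the whole genome for exact occurrences of one SF motif (both
#' orientations), scores each hit by mean conservation, keeps the top
#' `ceiling(keep_fraction * n_hits)` hits by conservation (ties broken by
#' coordinate) and maps them to overlapping gene bodies.
#'
#' @param motif One-row data frame (or list) with `factor` and `motif`.
#' @param models `isoform_models` providing gene bodies (the span of each
#'   gene's exons).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param track A `cons_track`.
#' @param keep_fraction Fraction of hits to keep, in (0, 1] (default 1/3).
#' @return List with `hits` (data frame `chrom`, `start`, `end`, `strand`,
#'   `conservation`, `genes`) and `genes` (deduplicated character vector of
#'   gene ids overlapped by kept hits).
#' @export
genome_scan_targets <- function(motif, models, genome, track,
                                keep_fraction = 1 / 3) {
  check_that(keep_fraction > 0 && keep_fraction <= 1,
             "keep_fraction must lie in (0, 1]")
  mot <- chartr("Uu", "Tt", toupper(motif$motif[[1L]]))
  words <- unique(c(mot, revcomp_chr(mot)))
  strands <- c("+", "-")[seq_along(words)]
  hits <- list()
  for (chrom in names(genome)) {
    seq_chr <- toupper(as.character(genome[[chrom]]))
    for (k in seq_along(words)) {
      occ <- gregexpr(words[k], seq_chr, fixed = TRUE)[[1L]]
      if (occ[1L] == -1L) next
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = as.integer(occ) - 1L,
        end = as.integer(occ) - 1L + nchar(mot), strand = strands[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    warning(sprintf("no genome-wide hits for motif %s", mot))
    return(list(hits = data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  conservation = numeric(0)),
                genes = character(0)))
  }
  df <- do.call(rbind, hits)
  df$conservation <- vapply(seq_len(nrow(df)), function(i)
    mean(conservation_scores(track, df$chrom[i], df$start[i], df$end[i])),
    numeric(1L))
  n_keep <- ceiling(keep_fraction * nrow(df))
  ord <- order(-df$conservation, df$chrom, df$start)
  df <- df[ord[seq_len(n_keep)], , drop = FALSE]
  rownames(df) <- NULL

  # gene bodies: span of each gene's exons
  ex <- merge(models$exons, models$transcripts[, c("isoform_id", "gene_id", "chrom")],
              by = "isoform_id")
  gb <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end))))
  hit_gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start + 1L, df$end))
  gene_gr <- GenomicRanges::GRanges(gb$chrom,
                                    IRanges::IRanges(gb$start + 1L, gb$end))
  ov <- GenomicRanges::findOverlaps(hit_gr, gene_gr)
  df$genes <- vapply(seq_len(nrow(df)), function(i) {
    g <- gb$gene_id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    paste(sort(unique(g)), collapse = ",")
  }, character(1L))
  list(hits = df,
       genes = sort(unique(unlist(strsplit(df$genes[df$genes != ""], ",")))))
}
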