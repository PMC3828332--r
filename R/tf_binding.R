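#' Extract promoter regions (PRD)
#'
#' Builds the promoter-region dataset: for each isoform, the 2000 bp
#' (configurable) upstream of its transcription start site, on the coding
#' strand.  A plus-strand isoform with 0-based TSS `t` yields
#' `genome[t - len, t)`; a minus-strand isoform yields the reverse
#' complement of `genome[t + 1, t + 1 + len)`.  Promoters truncated by a
#' contig edge are returned shorter and reported with a message.
#'
#' @param models An `isoform_models` object ([read_isoform_models()]).
#' @param genome A named [Biostrings::DNAStringSet] covering the isoforms'
#'   contigs.
#' @param promoter_len Promoter length in bp (default 2000).
#' @return A [Biostrings::DNAStringSet] of uppercased promoter sequences
#'   named by isoform id.
#' @export
extract_promoters <- function(models, genome, promoter_len = 2000L) {
  tx <- models$transcripts
  seqs <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    check_that(tx$chrom[i] %in% names(genome),
               "contig %s missing from genome", tx$chrom[i])
    clen <- length(genome[[tx$chrom[i]]])
    t0 <- tx$tss[i]
    if (tx$strand[i] == "+") {
      s <- max(0L, t0 - promoter_len); e <- t0
    } else {
      s <- t0 + 1L; e <- min(clen, t0 + 1L + promoter_len)
    }
    if (e - s < promoter_len)
      message(sprintf("promoter of %s truncated to %d bp by contig edge",
                      tx$isoform_id[i], e - s))
    sub <- Biostrings::subseq(genome[[tx$chrom[i]]], start = s + 1L, end = e)
    if (tx$strand[i] == "-") sub <- Biostrings::reverseComplement(sub)
    seqs[i] <- toupper(as.character(sub))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tx$isoform_id
  out
}

# Score every offset of `sequence` (integer-encoded) against a 4 x L
# log-odds matrix; windows containing N score NA.
score_offsets <- function(codes, score_mat) {
  L <- ncol(score_mat)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  ok <- rep(TRUE, n)
  for (p in seq_len(L)) {
    cp <- codes[p:(p + n - 1L)]
    bad <- is.na(cp)
    ok <- ok & !bad
    cp[bad] <- 1L
    s <- s + score_mat[cbind(cp, p)]
  }
  s[!ok] <- NA_real_
  s
}

encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1L]], c("A", "C", "G", "T"))
}

#' Scan a sequence with a PWM
#'
#' Slides the PWM over both strands of the sequence; at each offset the
#' site score is the sum over positions of `log2(p_base / background)`
#' (with pseudocount regularisation).  A site is emitted when its score
#' reaches `threshold_fraction` of the PWM's maximum achievable score.
#' Windows containing `N` are skipped.
#'
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @param p A `tsnet_pwm`.
#' @param threshold_fraction Fraction of the maximum score in (0, 1]
#'   required to emit a site (default 0.8).
#' @return Data frame of sites with columns `factor`, `start`, `end`
#'   (0-based half-open, sequence-local), `strand`, `score`.
#' @export
scan_pwm <- function(sequence, p, threshold_fraction = 0.8) {
  check_that(threshold_fraction > 0 && threshold_fraction <= 1,
             "threshold_fraction must lie in (0, 1]")
  sm <- pwm_score_matrix(p)
  L <- ncol(sm)
  empty <- data.frame(factor = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0))
  if (nchar(sequence) < L) return(empty)
  thr <- threshold_fraction * pwm_max_score(p)
  codes <- encode_dna(sequence)
  n <- length(codes)
  fwd <- score_offsets(codes, sm)
  rc <- rev(5L - codes)  # reverse complement in integer code (N stays NA)
  rev_scores <- score_offsets(rc, sm)
  hit_f <- which(!is.na(fwd) & fwd >= thr)
  hit_r <- which(!is.na(rev_scores) & rev_scores >= thr)
  sites <- rbind(
    if (length(hit_f)) data.frame(factor = p$factor, start = hit_f - 1L,
                                  end = hit_f - 1L + L, strand = "+",
                                  score = fwd[hit_f]),
    if (length(hit_r)) data.frame(factor = p$factor,
                                  start = n - (hit_r - 1L) - L,
                                  end = n - (hit_r - 1L), strand = "-",
                                  score = rev_scores[hit_r]))
  if (is.null(sites)) return(empty)
  sites[order(sites$start, sites$strand), , drop = FALSE]
}

#' Scan all promoters with all PWMs
#'
#' @param promoters Named [Biostrings::DNAStringSet] (the PRD).
#' @param pwms Named list of `tsnet_pwm` objects.
#' @param threshold_fraction See [scan_pwm()].
#' @return Data frame of binding sites with columns `factor`, `isoform`,
#'   `start`, `end`, `strand`, `score` (coordinates promoter-local).
#' @export
scan_promoters <- function(promoters, pwms, threshold_fraction = 0.8) {
  out <- list()
  for (iso in names(promoters)) {
    seq_i <- as.character(promoters[[iso]])
    for (p in pwms) {
      sites <- scan_pwm(seq_i, p, threshold_fraction)
      if (nrow(sites)) {
        sites$isoform <- iso
        out[[length(out) + 1L]] <- sites
      }
    }
  }
  if (!length(out))
    return(data.frame(factor = character(0), isoform = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  df <- do.call(rbind, out)
  df[, c("factor", "isoform", "start", "end", "strand", "score")]
}

#' Build the TF interaction-strength matrix
#'
#' The strength of a TF on an isoform is the sum of the scores of its
#' binding sites on that isoform's promoter; isoform-factor pairs with no
#' sites have strength 0, and factors with no sites on any promoter are
#' dropped (with a message).
#'
#' @param sites Data frame from [scan_promoters()].
#' @param isoforms Character vector of isoform ids (matrix rows).
#' @param factors Character vector of TF names (candidate columns).
#' @return A `strength_matrix` (isoforms x retained factors) with
#'   attribute `flavor = "TF"`.
#' @export
tf_strength_matrix <- function(sites, isoforms, factors) {
  if (nrow(sites)) {
    bad_iso <- setdiff(unique(sites$isoform), isoforms)
    bad_fac <- setdiff(unique(sites$factor), factors)
    check_that(length(bad_iso) == 0L, "site references unknown isoform: %s",
               paste(bad_iso, collapse = ", "))
    check_that(length(bad_fac) == 0L, "site references unknown factor: %s",
               paste(bad_fac, collapse = ", "))
  }
  m <- matrix(0, length(isoforms), length(factors),
              dimnames = list(isoforms, factors))
  if (nrow(sites)) {
    agg <- tapply(sites$score, list(sites$isoform, sites$factor), sum)
    m[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  }
  empty <- colSums(m != 0) == 0L
  if (any(empty))
    message(sprintf("removing %d TF(s) with no promoter hits: %s",
                    sum(empty), paste(factors[empty], collapse = ", ")))
  m <- m[, !empty, drop = FALSE]
  structure(m, flavor = "TF", class = c("strength_matrix", class(m)))
}

#' @export
print.strength_matrix <- function(x, ...) {
  cat(sprintf("%s strength matrix: %d isoforms x %d factors (%.1f%% nonzero)\n",
              attr(x, "flavor"), nrow(x), ncol(x),
              100 * mean(x != 0)))
  invisible(x)
}
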