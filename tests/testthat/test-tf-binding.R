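# A PWM whose consensus is (effectively) deterministic at every position.
consensus_only_pwm <- function(word, name = "TFX") {
  bases <- strsplit(word, "")[[1L]]
  counts <- matrix(0, 4, length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, rownames(counts)), seq_along(bases))] <- 1
  pwm(name, counts)
}

test_that("promoters follow the strand-aware coordinate convention", {
  chr <- random_dna(8000, seed = 2)
  genome <- make_genome(chr1 = chr)
  mk <- function(strand, tss) {
    ex <- if (strand == "+")
      data.frame(isoform_id = "t1", gene_id = "g1", chrom = "chr1",
                 strand = strand, start = tss, end = tss + 300L)
    else
      data.frame(isoform_id = "t1", gene_id = "g1", chrom = "chr1",
                 strand = strand, start = tss - 300L, end = tss + 1L)
    isoform_models_from_exons(ex)
  }
  p_plus <- extract_promoters(mk("+", 5000L), genome)
  expect_equal(as.character(p_plus[["t1"]]), substr(chr, 3001, 5000))
  p_minus <- extract_promoters(mk("-", 5000L), genome)
  expect_equal(as.character(p_minus[["t1"]]),
               revcomp <- as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr, 5002, 7001)))))
  expect_message(p_short <- extract_promoters(mk("+", 1000L), genome),
                 "truncated")
  expect_equal(as.character(p_short[["t1"]]), substr(chr, 1, 1000))
  expect_equal(nchar(as.character(p_short[["t1"]])), 1000L)
})

test_that("a consensus PWM finds its exact occurrences at the maximum score", {
  p <- consensus_only_pwm("ACGT")
  hits <- scan_pwm("ACGTACGT", p)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, c(0L, 4L))
  expect_equal(plus$score, rep(pwm_max_score <- tsnet:::pwm_max_score(p), 2))
  expect_equal(nrow(scan_pwm("ACG", p)), 0L)  # shorter than the motif
})

test_that("scan scores equal a per-offset hand enumeration on both strands", {
  set.seed(8)
  counts <- matrix(runif(12), 4, 3, dimnames = list(c("A", "C", "G", "T"),
                                                    NULL))
  p <- pwm("TFR", counts)
  seqs <- "ACGTGC"
  thr_frac <- 0.5
  hits <- scan_pwm(seqs, p, threshold_fraction = thr_frac)

  # independent enumeration: log2 odds with pseudocount, every offset
  prob <- sweep(counts, 2, colSums(counts), "/")
  reg <- (prob + 0.01) / (1 + 4 * 0.01)
  lo <- log2(reg / 0.25)
  score_word <- function(w) {
    b <- strsplit(w, "")[[1L]]
    sum(lo[cbind(match(b, c("A", "C", "G", "T")), seq_along(b))])
  }
  rc <- function(w) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(w)))
  exp_rows <- list()
  for (off in 0:3) {
    w <- substr(seqs, off + 1, off + 3)
    exp_rows[[length(exp_rows) + 1]] <-
      data.frame(start = off, strand = "+", score = score_word(w))
    exp_rows[[length(exp_rows) + 1]] <-
      data.frame(start = off, strand = "-", score = score_word(rc(w)))
  }
  expected <- do.call(rbind, exp_rows)
  maxs <- sum(apply(lo, 2, max))
  expected <- expected[expected$score >= thr_frac * maxs, ]
  expected <- expected[order(expected$start, expected$strand), ]
  expect_equal(hits$start, expected$start)
  expect_equal(hits$strand, expected$strand)
  expect_equal(hits$score, expected$score, tolerance = 1e-12)
})

test_that("scanning a sequence and its reverse complement mirrors the sites", {
  set.seed(3)
  counts <- matrix(runif(20, 0.05, 1), 4, 5,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm("TFR", counts)
  s <- random_dna(40, seed = 4)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- scan_pwm(s, p, 0.6)
  h2 <- scan_pwm(rc, p, 0.6)
  # mirrored coordinates: start' = len - end, strand flipped
  mirrored <- data.frame(start = nchar(s) - h2$end,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         score = h2$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(h1$start, mirrored$start)
  expect_equal(h1$strand, mirrored$strand)
  expect_equal(h1$score, mirrored$score, tolerance = 1e-12)
})

test_that("raising the threshold never increases a strength entry", {
  set.seed(5)
  counts <- matrix(runif(24, 0.05, 1), 4, 6,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwms <- list(TFA = pwm("TFA", counts))
  proms <- Biostrings::DNAStringSet(c(i1 = random_dna(300, 6),
                                      i2 = random_dna(300, 7)))
  prev <- NULL
  for (thr in c(0.5, 0.7, 0.9)) {
    sites <- scan_promoters(proms, pwms, threshold_fraction = thr)
    m <- suppressMessages(tf_strength_matrix(sites, c("i1", "i2"), "TFA"))
    v <- if (ncol(m)) m[, "TFA"] else c(i1 = 0, i2 = 0)
    if (!is.null(prev)) expect_true(all(v <= prev + 1e-12))
    prev <- v
  }
})

test_that("TF strengths sum site scores and prune empty factors", {
  sites <- data.frame(factor = c("TFA", "TFA", "TFB"),
                      isoform = c("i1", "i1", "i2"),
                      start = c(0L, 10L, 5L), end = c(4L, 14L, 9L),
                      strand = "+", score = c(2.0, 3.5, 1.25))
  m <- suppressMessages(tf_strength_matrix(sites, c("i1", "i2"),
                                           c("TFA", "TFB", "TFC")))
  expect_equal(m["i1", "TFA"], 5.5)
  expect_equal(m["i2", "TFB"], 1.25)
  expect_false("TFC" %in% colnames(m))
  expect_message(tf_strength_matrix(sites, c("i1", "i2"),
                                    c("TFA", "TFB", "TFC")), "TFC")
  expect_error(tf_strength_matrix(sites, "i1", c("TFA", "TFB")),
               "unknown isoform")

  # additivity: concatenating disjoint site lists sums strengths
  extra <- data.frame(factor = "TFA", isoform = "i1", start = 30L, end = 34L,
                      strand = "-", score = 1.5)
  m2 <- suppressMessages(tf_strength_matrix(rbind(sites, extra),
                                            c("i1", "i2"), c("TFA", "TFB")))
  expect_equal(m2["i1", "TFA"], 5.5 + 1.5)
})

test_that("identical promoter sequences give identical strength rows", {
  word <- "ACGTACGTAC"
  p <- consensus_only_pwm(word)
  s <- plant_motif(random_dna(200, 9), word, 50)
  proms <- Biostrings::DNAStringSet(c(i1 = s, i2 = s))
  sites <- scan_promoters(proms, list(TFX = p))
  m <- tf_strength_matrix(sites, c("i1", "i2"), "TFX")
  expect_equal(m["i1", ], m["i2", ])
})
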