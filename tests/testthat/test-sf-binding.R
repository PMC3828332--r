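two_exon_models <- function(intron_start = 1000L, intron_end = 2000L,
                            chrom = "chr1", iso = "t1") {
  isoform_models_from_exons(data.frame(
    isoform_id = iso, gene_id = paste0("g_", iso), chrom = chrom,
    strand = "+",
    start = c(500L, intron_end), end = c(intron_start, intron_end + 500L)))
}

test_that("SF motif filter applies the affinity and length boundaries inclusively", {
  motifs <- data.frame(
    factor = c("a", "b", "c", "d"),
    motif = c("ACGTACGT", "ACGTACGT", paste(rep("A", 16), collapse = ""),
              paste(rep("ACG", 5), collapse = "")),
    score = c(-6, 4.9, 7, 5))
  kept <- filter_sf_motifs(motifs)
  expect_identical(kept$factor, c("a", "d"))  # |−6|>=5 kept; 4.9 dropped;
  # length 16 dropped; length 15 with score exactly 5 kept
  expect_identical(filter_sf_motifs(kept), kept)  # idempotent
  expect_error(filter_sf_motifs(data.frame(factor = "x", motif = "ACNGT",
                                           score = 9)), "ACNGT")
})

test_that("U is read as T in SF motif tables", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("factor\tmotif\tscore", "SRX\tUUAGGU\t7.5"), f)
  expect_identical(read_sf_motifs(f)$motif, "TTAGGT")
})

test_that("splice windows flank each internal splice site and merge overlaps", {
  w <- extract_splice_windows(two_exon_models())
  expect_equal(w$start, c(800L, 1800L))
  expect_equal(w$end, c(1200L, 2200L))
  # single-exon isoform: no windows
  single <- isoform_models_from_exons(data.frame(
    isoform_id = "s1", gene_id = "gs", chrom = "chr1", strand = "+",
    start = 100L, end = 700L))
  expect_equal(nrow(extract_splice_windows(single)), 0L)
  # sites 150 bp apart merge into one window
  close_by <- isoform_models_from_exons(data.frame(
    isoform_id = "t2", gene_id = "g2", chrom = "chr1", strand = "+",
    start = c(500L, 1150L), end = c(1000L, 1500L)))
  w2 <- extract_splice_windows(close_by)
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(800L, 1350L))
  # clipping at the contig edge
  near_edge <- isoform_models_from_exons(data.frame(
    isoform_id = "t3", gene_id = "g3", chrom = "chr1", strand = "+",
    start = c(0L, 150L), end = c(100L, 400L)))
  w3 <- extract_splice_windows(near_edge, contig_lengths = c(chr1 = 320L))
  expect_true(all(w3$start >= 0L))
  expect_true(all(w3$end <= 320L))
})

test_that("hit conservation is the spanned mean with a strict deletion rule", {
  # genome with a motif planted at known offsets inside the windows
  base <- random_dna(3000, seed = 21)
  motif <- "ACGTTGC"
  g <- plant_motif(base, motif, 900)    # within window [800,1200)
  g <- plant_motif(g, motif, 1850)      # within window [1800,2200)
  genome <- make_genome(chr1 = g)
  models <- two_exon_models()
  windows <- extract_splice_windows(models)
  cons <- rep(0.1, 3000)
  cons[901:907] <- c(1, 2, 3, 2, 2, 2, 2)     # mean 2.0 -> kept (boundary)
  cons[1851:1857] <- c(0, 1, 2, 1, 1, 1, 1)   # mean 1.0 -> deleted
  track <- make_track(cons)
  motifs <- data.frame(factor = "SFX", motif = motif, score = 8)
  hits <- score_sf_hits(windows, motifs, genome, track, models)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 900L)
  expect_equal(hits$conservation, 2.0)
})

test_that("hits equal a brute-force substring search over the window", {
  fx <- shared_fixture()
  d <- fx$design
  genome <- Biostrings::readDNAStringSet(fx$paths$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  models <- read_isoform_models(fx$paths$gtf)
  track <- read_conservation(fx$paths$conservation)
  motifs <- filter_sf_motifs(read_sf_motifs(fx$paths$sf_motifs))
  iso <- d$iso_ids[1L]
  sub <- structure(list(
    transcripts = models$transcripts[models$transcripts$isoform_id == iso, ],
    exons = models$exons[models$exons$isoform_id == iso, ]),
    class = "isoform_models")
  windows <- extract_splice_windows(sub)
  hits <- score_sf_hits(windows, motifs, genome, track, sub)
  chr <- as.character(genome[[1L]])
  for (m in seq_len(nrow(motifs))) {
    found <- integer(0)
    for (w in seq_len(nrow(windows))) {
      seq_w <- substr(chr, windows$start[w] + 1L, windows$end[w])
      occ <- gregexpr(motifs$motif[m], seq_w, fixed = TRUE)[[1L]]
      if (occ[1L] != -1L)
        found <- c(found, windows$start[w] + occ - 1L)
    }
    # brute-force occurrences, conservation-filtered by direct lookup
    keep <- found[vapply(found, function(s)
      mean(conservation_scores(track, windows$chrom[1L], s,
                               s + nchar(motifs$motif[m]))) >= 2,
      logical(1L))]
    got <- sort(hits$start[hits$factor == motifs$factor[m]])
    expect_equal(got, sort(keep), info = motifs$factor[m])
  }
})

test_that("splitting a window into covering pieces does not change the hit set", {
  base <- random_dna(3000, seed = 22)
  motif <- "TTACGCA"
  g <- plant_motif(base, motif, 950)
  genome <- make_genome(chr1 = g)
  models <- two_exon_models()
  cons <- rep(3, 3000)
  track <- make_track(cons)
  motifs <- data.frame(factor = "SFX", motif = motif, score = 8)
  w1 <- data.frame(isoform = "t1", chrom = "chr1", start = 800L, end = 1200L)
  w2 <- data.frame(isoform = "t1", chrom = "chr1",
                   start = c(800L, 900L), end = c(1000L, 1200L))
  h1 <- score_sf_hits(w1, motifs, genome, track, models)
  h2 <- score_sf_hits(w2, motifs, genome, track, models)
  expect_equal(h1, h2)
})

test_that("SF strength is the mean hit conservation, zero without hits", {
  hits <- data.frame(factor = c("SFA", "SFA"), isoform = c("i1", "i1"),
                     chrom = "chr1", start = c(0L, 10L), end = c(7L, 17L),
                     conservation = c(2.5, 3.5))
  m <- sf_strength_matrix(hits, c("i1", "i2"), c("SFA", "SFB"))
  expect_equal(m["i1", "SFA"], 3.0)
  expect_equal(m["i2", "SFA"], 0)
  expect_equal(m["i1", "SFB"], 0)
  expect_true(all(m[m != 0] >= 2))

  # averaging removes the effect of exon number: many hits at c vs one at c
  many <- data.frame(factor = "SFA", isoform = "i1", chrom = "chr1",
                     start = seq(0L, 90L, 10L), end = seq(7L, 97L, 10L),
                     conservation = 2.8)
  one <- data.frame(factor = "SFA", isoform = "i2", chrom = "chr1",
                    start = 0L, end = 7L, conservation = 2.8)
  m2 <- sf_strength_matrix(rbind(many, one), c("i1", "i2"), "SFA")
  expect_equal(m2["i1", "SFA"], m2["i2", "SFA"])
})

test_that("paralogous factor columns merge by element-wise averaging", {
  m <- matrix(c(1, 3, 2, 4, 6, 2, 4, 6), nrow = 2,
              dimnames = list(c("i1", "i2"),
                              c("hnRNP A1", "hnRNP A2", "x1", "x2")))
  m <- structure(m, flavor = "SF", class = c("strength_matrix", "matrix",
                                             "array"))
  merged <- merge_paralog_factors(m, list("hnRNPA1/A2" = c("hnRNP A1",
                                                           "hnRNP A2")))
  expect_equal(unname(merged[, "hnRNPA1/A2"]), c(1.5, 3.5))
  expect_equal(merged[, c("x1", "x2")], m[, c("x1", "x2")])

  # idempotence on identical columns; three-member mean
  m2 <- matrix(c(2, 2, 2, 2, 4, 4, 6, 6), nrow = 2,
               dimnames = list(c("i1", "i2"), c("a", "b", "p", "q")))
  same <- merge_paralog_factors(m2, list(ab = c("a", "b")))
  expect_equal(unname(same[, "ab"]), c(2, 2))
  m3 <- matrix(c(2, 2, 4, 4, 6, 6), nrow = 2,
               dimnames = list(c("i1", "i2"), c("a", "b", "c")))
  expect_equal(unname(merge_paralog_factors(m3, list(abc = c("a", "b", "c")))[, "abc"]),
               c(4, 4))
  expect_error(merge_paralog_factors(m3, list(z = c("a", "nope"))), "nope")
  expect_length(default_paralog_groups(), 4L)
})

test_that("the genome-wide target scan keeps the top conserved fraction", {
  motif <- "GATTACA"
  base <- random_dna(5000, seed = 23)
  base <- gsub(motif, "AAAAAAA", base, fixed = TRUE)
  pos <- seq(100L, 4300L, 520L)[1:9]
  g <- base
  for (p in pos) g <- plant_motif(g, motif, p)
  cons <- rep(0.2, 5000)
  for (k in seq_along(pos)) cons[(pos[k] + 1):(pos[k] + 7)] <- k  # 1..9
  genome <- make_genome(chr1 = g)
  track <- make_track(cons)
  models <- isoform_models_from_exons(data.frame(
    isoform_id = c("t1", "t2"), gene_id = c("gA", "gB"), chrom = "chr1",
    strand = "+", start = c(3000L, 4000L), end = c(3900L, 4700L)))
  res <- genome_scan_targets(list(factor = "SFX", motif = motif),
                             models, genome, track, keep_fraction = 1 / 3)
  expect_equal(nrow(res$hits), 3L)
  expect_equal(sort(res$hits$conservation), c(7, 8, 9))
  all_res <- genome_scan_targets(list(factor = "SFX", motif = motif),
                                 models, genome, track, keep_fraction = 1)
  expect_equal(nrow(all_res$hits), 9L)
  # two kept hits inside one gene -> the gene appears once
  expect_equal(all_res$genes, c("gA", "gB"))
})
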