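#' Configuration for the synthetic fixture generator
#'
#' Defines the study conditions the generator emulates: group sizes of
#' co-expressed differentially expressed isoforms, a panel of TF position
#' weight matrices and SF literal motifs, a sparse linear model with
#' `true_support_per_group` nonzero coefficients per group, additive
#' Gaussian expression noise, and a conservation track whose planted peaks
#' sit exactly on planted SF motif occurrences.
#'
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param n_groups Number of co-expressed groups.
#' @param group_sizes Optional explicit group sizes; otherwise drawn
#'   uniformly from `group_size_range`.
#' @param group_size_range Length-2 integer vector within `[10, 30]`.
#' @param n_isoforms Total isoforms in the expression table; isoforms beyond
#'   the group members are decoys that fail the DEI filters.  Defaults to
#'   the number of members plus 5 decoys.
#' @param n_tfs,n_sfs Number of transcription / splicing factors.
#' @param true_support_per_group Number of factors with nonzero planted
#'   regression coefficients per group.
#' @param coefficient_magnitude_range Range of absolute planted
#'   coefficients; signs are random.
#' @param noise_sd Standard deviation of the additive Gaussian expression
#'   noise (FPKM scale).
#' @param genome_gc GC content of the synthetic genome background.
#' @param conservation_background_mean Mean of the truncated-normal
#'   per-base background conservation (phyloP scale).
#' @param conservation_site_mean Lower bound of planted per-site
#'   conservation values; must be at least 2 so planted SF hits survive the
#'   conservation filter.
#' @param conditions Named integer vector of replicate counts per condition
#'   label (sample columns of the expression table).
#' @param tf_motif_length,sf_motif_length Lengths of TF consensus motifs
#'   and SF literal motifs.
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_groups = 3L,
                           group_sizes = NULL,
                           group_size_range = c(10L, 30L),
                           n_isoforms = NULL,
                           n_tfs = 40L,
                           n_sfs = 20L,
                           true_support_per_group = 5L,
                           coefficient_magnitude_range = c(0.5, 1.5),
                           noise_sd = 0.1,
                           genome_gc = 0.5,
                           conservation_background_mean = 0.5,
                           conservation_site_mean = 3,
                           conditions = c(MDS = 4L, control = 5L),
                           tf_motif_length = 10L,
                           sf_motif_length = 7L) {
  cfg <- list(seed = as.integer(seed), n_groups = as.integer(n_groups),
              group_sizes = group_sizes,
              group_size_range = as.integer(group_size_range),
              n_isoforms = n_isoforms, n_tfs = as.integer(n_tfs),
              n_sfs = as.integer(n_sfs),
              true_support_per_group = as.integer(true_support_per_group),
              coefficient_magnitude_range = coefficient_magnitude_range,
              noise_sd = noise_sd, genome_gc = genome_gc,
              conservation_background_mean = conservation_background_mean,
              conservation_site_mean = conservation_site_mean,
              conditions = conditions,
              tf_motif_length = as.integer(tf_motif_length),
              sf_motif_length = as.integer(sf_motif_length))
  validate_fixture_config(cfg)
}

validate_fixture_config <- function(cfg) {
  check_that(length(cfg$group_size_range) == 2L &&
               cfg$group_size_range[1L] <= cfg$group_size_range[2L] &&
               cfg$group_size_range[1L] >= 10L &&
               cfg$group_size_range[2L] <= 30L,
             "group_size_range must lie within [10, 30]")
  if (!is.null(cfg$group_sizes))
    check_that(length(cfg$group_sizes) == cfg$n_groups &&
                 all(cfg$group_sizes >= cfg$group_size_range[1L]) &&
                 all(cfg$group_sizes <= cfg$group_size_range[2L]),
               "group_sizes must match n_groups and lie in group_size_range")
  check_that(cfg$conservation_site_mean >= 2,
             "conservation_site_mean must be >= 2 (conservation filter)")
  check_that(cfg$conservation_background_mean < 2,
             "conservation_background_mean must be < 2 (conservation filter)")
  check_that(cfg$true_support_per_group <= cfg$n_tfs + cfg$n_sfs,
             "true_support_per_group must be <= n_tfs + n_sfs")
  check_that(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  check_that(cfg$genome_gc > 0 && cfg$genome_gc < 1,
             "genome_gc must lie in (0, 1)")
  check_that(cfg$n_groups <= sum(cfg$conditions) - 1L,
             "n_groups must be < number of samples for separable profiles")
  if (!is.null(cfg$n_isoforms)) {
    sz <- cfg$group_sizes %||% rep(cfg$group_size_range[1L], cfg$n_groups)
    check_that(cfg$n_isoforms >= sum(sz),
               "n_isoforms must cover all group members")
  }
  structure(cfg, class = "fixture_config")
}

# Distinct random DNA words, none palindromic, none equal to (or, when
# with_rc, reverse-complement of / substring of) another.
random_motifs <- function(n, len, with_rc, no_substring = FALSE,
                          avoid = character(0)) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    check_that(guard < 10000L, "motif generation failed; widen settings")
    m <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    pool <- c(out, avoid)
    bad <- m %in% pool || (with_rc && (revcomp_chr(m) %in% c(pool, m)))
    if (!bad && no_substring && length(pool))
      bad <- any(vapply(pool, function(p)
        grepl(m, p, fixed = TRUE) || grepl(p, m, fixed = TRUE), logical(1L)))
    if (!bad) out <- c(out, m)
  }
  out
}

# PWM with high probability on a consensus word (0.91 consensus, 0.03 each
# alternative); planted consensus matches score exactly the PWM maximum and
# any single mismatch falls below 0.8 x maximum.
consensus_pwm <- function(name, consensus) {
  bases <- strsplit(consensus, "")[[1L]]
  counts <- matrix(3, nrow = 4L, ncol = length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, rownames(counts)), seq_along(bases))] <- 91
  pwm(name, counts)
}

# In-memory fixture design: the planted regulatory structure (factors,
# sites, coefficients, strengths, expression) without sequence realisation.
fixture_design_impl <- function(cfg) {
  sizes <- cfg$group_sizes %||%
    sample(seq(cfg$group_size_range[1L], cfg$group_size_range[2L]),
           cfg$n_groups, replace = TRUE)
  sizes <- as.integer(sizes)
  n_members <- sum(sizes)
  n_iso <- cfg$n_isoforms %||% (n_members + 5L)
  n_decoys <- n_iso - n_members

  iso_ids <- sprintf("iso%04d", seq_len(n_iso))
  gene_ids <- sprintf("G%04d", seq_len(n_iso))
  group_of <- c(rep(seq_len(cfg$n_groups), sizes), rep(NA_integer_, n_decoys))

  tf_names <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  sf_names <- sprintf("SF%02d", seq_len(cfg$n_sfs))
  tf_consensus <- random_motifs(cfg$n_tfs, cfg$tf_motif_length, with_rc = TRUE)
  sf_motif_seq <- random_motifs(cfg$n_sfs, cfg$sf_motif_length,
                                with_rc = FALSE, no_substring = TRUE)
  pwms <- mapply(consensus_pwm, tf_names, tf_consensus, SIMPLIFY = FALSE)
  names(pwms) <- tf_names
  max_scores <- vapply(pwms, pwm_max_score, numeric(1L))
  sf_motifs <- data.frame(
    factor = sf_names, motif = sf_motif_seq,
    score = round(sample(c(-1, 1), cfg$n_sfs, replace = TRUE) *
                    runif(cfg$n_sfs, 5, 10), 2),
    stringsAsFactors = FALSE)

  # planted support and coefficients per group
  all_factors <- c(tf_names, sf_names)
  groups <- lapply(seq_len(cfg$n_groups), function(g) {
    support <- sort(sample(all_factors, cfg$true_support_per_group))
    coef <- sample(c(-1, 1), length(support), replace = TRUE) *
      runif(length(support), cfg$coefficient_magnitude_range[1L],
            cfg$coefficient_magnitude_range[2L])
    list(group_id = g, members = iso_ids[which(group_of == g)],
         support = support, coefficients = coef)
  })

  # planted TF site counts and SF site conservation values (0 = no site)
  tf_counts <- matrix(0L, n_iso, cfg$n_tfs,
                      dimnames = list(iso_ids, tf_names))
  sf_cons <- matrix(0, n_iso, cfg$n_sfs, dimnames = list(iso_ids, sf_names))
  member_idx <- which(!is.na(group_of))
  for (i in member_idx) {
    sup <- groups[[group_of[i]]]$support
    for (j in seq_len(cfg$n_tfs)) {
      tf_counts[i, j] <- if (tf_names[j] %in% sup)
        sample(1:3, 1L) else sample(0:2, 1L, prob = c(0.4, 0.4, 0.2))
    }
    for (j in seq_len(cfg$n_sfs)) {
      planted <- sf_names[j] %in% sup || runif(1L) < 0.6
      if (planted)
        sf_cons[i, j] <- runif(1L, max(2.5, cfg$conservation_site_mean - 0.5),
                               cfg$conservation_site_mean + 1.5)
    }
  }

  tf_strength <- sweep(tf_counts, 2L, max_scores, "*")
  sf_strength <- sf_cons

  # group expression: response from the linear model, sample profiles
  # orthogonal across groups so co-expression clusters are separable
  n_samp <- sum(cfg$conditions)
  samp_cond <- rep(names(cfg$conditions), cfg$conditions)
  samp_ids <- unlist(lapply(names(cfg$conditions), function(cn)
    sprintf("%s_%d", cn, seq_len(cfg$conditions[[cn]]))))
  up_cond <- rep_len(names(cfg$conditions), cfg$n_groups)

  raw <- matrix(rnorm(n_samp * cfg$n_groups), n_samp, cfg$n_groups)
  qz <- qr.Q(qr(cbind(1, raw)))[, -1L, drop = FALSE] * sqrt(n_samp)

  response <- numeric(n_iso)
  intercepts <- numeric(cfg$n_groups)
  fpkm <- matrix(0, n_iso, n_samp, dimnames = list(iso_ids, samp_ids))
  X_all <- cbind(tf_strength, sf_strength)
  for (g in seq_len(cfg$n_groups)) {
    idx <- which(group_of == g)
    contrib <- X_all[idx, groups[[g]]$support, drop = FALSE] %*%
      groups[[g]]$coefficients
    intercepts[g] <- 50 + max(0, -min(contrib))
    groups[[g]]$intercept <- intercepts[g]
    e <- as.numeric(intercepts[g] + contrib) +
      rnorm(length(idx), 0, cfg$noise_sd)
    response[idx] <- e
    up <- samp_cond == up_cond[g]
    f <- (1 + 0.35 * qz[, g]) * ifelse(up, 1, 0.8)
    f <- pmax(f, 0.15)
    f <- f / mean(f[up])
    jit <- matrix(rnorm(length(idx) * n_samp, 0, 0.01),
                  length(idx), n_samp)
    jit <- jit - rowMeans(jit[, up, drop = FALSE])
    fpkm[idx, ] <- (e %o% f) * (1 + jit)
  }
  groups <- lapply(groups, function(grp) {
    grp$up_condition <- up_cond[grp$group_id]; grp
  })

  # decoys: one fails each filter in rotation
  decoy_reason <- character(0)
  if (n_decoys > 0L) {
    decoy_reason <- rep_len(c("de_flag", "protein", "fpkm"), n_decoys)
    for (k in seq_len(n_decoys)) {
      i <- n_members + k
      base <- runif(1L, 8, 30)
      vals <- base * (1 + 0.3 * rnorm(n_samp))
      if (decoy_reason[k] == "fpkm") {
        vals <- pmin(pmax(vals, 1), 4.5)   # never above the FPKM floor
      } else vals <- pmax(vals, 6)
      fpkm[i, ] <- vals
      response[i] <- mean(vals[samp_cond == names(cfg$conditions)[1L]])
    }
  }

  info <- data.frame(
    isoform_id = iso_ids, gene_id = gene_ids,
    protein_evidence = TRUE, de_flag = TRUE,
    up_condition = ifelse(is.na(group_of), names(cfg$conditions)[1L],
                          up_cond[ifelse(is.na(group_of), 1L, group_of)]),
    stringsAsFactors = FALSE)
  if (n_decoys > 0L) {
    d <- n_members + seq_len(n_decoys)
    info$de_flag[d][decoy_reason == "de_flag"] <- FALSE
    info$protein_evidence[d][decoy_reason == "protein"] <- FALSE
  }
  expr <- structure(list(info = info, fpkm = fpkm, condition = samp_cond),
                    class = "expression_table")

  list(config = cfg, iso_ids = iso_ids, gene_ids = gene_ids,
       group_of = group_of, sizes = sizes, groups = groups,
       pwms = pwms, tf_consensus = tf_consensus, max_scores = max_scores,
       sf_motifs = sf_motifs,
       tf_site_counts = tf_counts, sf_site_conservation = sf_cons,
       tf_strength_true = tf_strength, sf_strength_true = sf_strength,
       response_true = response, expression = expr)
}

#' Draw the planted regulatory design of a synthetic fixture
#'
#' Returns the in-memory planted structure (PWMs, SF motifs, planted site
#' counts and conservation values, true coefficients and the resulting
#' expression table) without realising genome sequences or files.  Used for
#' strength-level simulation studies; [generate_fixture()] realises the same
#' design as an on-disk input bundle.
#'
#' @param config A [fixture_config()].
#' @return A list with the planted design (see Details in the package
#'   vignette); notably `tf_strength_true`, `sf_strength_true`, `groups`
#'   (support factors, coefficients, intercept per group), and `expression`.
#' @export
fixture_design <- function(config) {
  config <- validate_fixture_config(config)
  with_seed(config$seed, fixture_design_impl(config))
}

#' Replace a window of a sequence with a motif
#'
#' @param sequence Nucleotide string.
#' @param motif Nucleotide string to plant.
#' @param position 0-based offset at which the motif replaces the existing
#'   window.
#' @return The modified sequence; all bases outside the window unchanged.
#' @export
plant_motif <- function(sequence, motif, position) {
  check_that(position >= 0 && position + nchar(motif) <= nchar(sequence),
             "plant position %d out of bounds for motif of length %d",
             position, nchar(motif))
  paste0(substr(sequence, 1L, position), motif,
         substr(sequence, position + nchar(motif) + 1L, nchar(sequence)))
}

#' Simulate expression of one co-expressed group from planted strengths
#'
#' Reads the linear model forward: expression = intercept +
#' strengths[, support] %*% coefficients + Gaussian(0, noise_sd).
#'
#' @param strengths Numeric matrix, group isoforms x factors (columns
#'   named by factor).
#' @param truth List with `support` (factor names), `coefficients` and
#'   `intercept`.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Optional seed for the noise draw.
#' @return Numeric expression vector, one value per row of `strengths`.
#' @export
simulate_group_expression <- function(strengths, truth, noise_sd, seed = NULL) {
  missing <- setdiff(truth$support, colnames(strengths))
  check_that(length(missing) == 0L, "unknown factor(s) in truth: %s",
             paste(missing, collapse = ", "))
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  mu <- truth$intercept +
    as.numeric(strengths[, truth$support, drop = FALSE] %*% truth$coefficients)
  with_seed(seed, mu + rnorm(nrow(strengths), 0, noise_sd))
}

# genome layout constants: per-isoform tile and gene geometry (bp)
.fx_buffer <- 2100L
.fx_stride <- 6500L
.fx_prom_off <- 2500L  # TSS offset within the tile
.fx_exon1 <- 400L
.fx_intron <- 600L
.fx_exon2 <- 400L

fixture_layout <- function(n_iso) {
  tile_start <- .fx_buffer + (seq_len(n_iso) - 1L) * .fx_stride
  tss <- tile_start + .fx_prom_off
  data.frame(tss = tss,
             prom_start = tss - 2000L, prom_end = tss,
             exon1_start = tss, exon1_end = tss + .fx_exon1,
             exon2_start = tss + .fx_exon1 + .fx_intron,
             exon2_end = tss + .fx_exon1 + .fx_intron + .fx_exon2)
}

# Mutate the middle base of accidental motif occurrences inside the given
# regions, leaving planted spans untouched.  regions/planted: 0-based
# half-open data frames with start,end.
scrub_occurrences <- function(genome_chars, motifs, regions, planted) {
  n <- length(genome_chars)
  protected <- rep(FALSE, n)
  if (nrow(planted))
    for (k in seq_len(nrow(planted)))
      protected[(planted$start[k] + 1L):planted$end[k]] <- TRUE
  for (pass in 1:6) {
    dirty <- FALSE
    for (r in seq_len(nrow(regions))) {
      s0 <- regions$start[r]; e0 <- regions$end[r]
      seq_r <- paste(genome_chars[(s0 + 1L):e0], collapse = "")
      for (m in motifs) {
        hits <- gregexpr(m, seq_r, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (h in hits) {
          span <- (s0 + h):(s0 + h + nchar(m) - 1L)  # 1-based genomic
          free <- span[!protected[span]]
          if (!length(free)) next  # identical to a planted site: keep
          # mutate the free base nearest the occurrence's centre
          mid <- free[which.min(abs(free - mean(span)))]
          genome_chars[mid] <- sample(setdiff(c("A", "C", "G", "T"),
                                              genome_chars[mid]), 1L)
          dirty <- TRUE
        }
        if (dirty)  # re-read the mutated region before further motifs
          seq_r <- paste(genome_chars[(s0 + 1L):e0], collapse = "")
      }
    }
    if (!dirty) break
  }
  genome_chars
}

#' Generate a complete synthetic input bundle
#'
#' Realises a [fixture_design()] as files: a synthetic genome with planted
#' TF consensus sites in promoters and SF motif occurrences near splice
#' sites, the matching GTF annotation, JASPAR-format PWMs, the SF motif
#' table, a per-base bedGraph conservation track with peaks exactly on
#' planted SF sites, the per-sample expression table and a `truth.json`
#' with the planted ground truth.  Accidental motif occurrences in
#' promoters and splice windows are removed so measured interaction
#' strengths equal the planted ones.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the design and the written file paths.
#' @export
generate_fixture <- function(config, dir) {
  config <- validate_fixture_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    design <- fixture_design_impl(config)
    realize_fixture(design, dir)
  })
}

realize_fixture <- function(design, dir) {
  cfg <- design$config
  n_iso <- length(design$iso_ids)
  lay <- fixture_layout(n_iso)
  glen <- .fx_buffer * 2L + n_iso * .fx_stride
  gc <- cfg$genome_gc
  genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE,
                         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  # per-isoform splice windows (two per isoform, +/-200 around each site)
  donor <- lay$exon1_end
  acceptor <- lay$exon2_start
  win <- rbind(
    data.frame(iso = seq_len(n_iso), start = donor - 200L, end = donor + 200L),
    data.frame(iso = seq_len(n_iso), start = acceptor - 200L,
               end = acceptor + 200L))
  win <- win[order(win$iso, win$start), ]

  # plant TF consensus sites in promoters
  tf_sites <- list()
  slot_w <- cfg$tf_motif_length + 2L
  n_slots <- 2000L %/% slot_w
  for (i in seq_len(n_iso)) {
    counts <- design$tf_site_counts[i, ]
    total <- sum(counts)
    if (total == 0L) next
    check_that(total <= n_slots, "too many TF sites to place on isoform %d", i)
    slots <- sample(seq_len(n_slots) - 1L, total)
    k <- 0L
    for (j in which(counts > 0L)) {
      for (rep_k in seq_len(counts[j])) {
        k <- k + 1L
        pos <- lay$prom_start[i] + slots[k] * slot_w +
          sample.int(slot_w - cfg$tf_motif_length + 1L, 1L) - 1L
        word <- strsplit(design$tf_consensus[j], "")[[1L]]
        genome_chars[(pos + 1L):(pos + cfg$tf_motif_length)] <- word
        tf_sites[[length(tf_sites) + 1L]] <- data.frame(
          isoform = design$iso_ids[i], factor = names(counts)[j],
          start = pos, end = pos + cfg$tf_motif_length,
          stringsAsFactors = FALSE)
      }
    }
  }
  tf_sites <- if (length(tf_sites)) do.call(rbind, tf_sites) else
    data.frame(isoform = character(0), factor = character(0),
               start = integer(0), end = integer(0))

  # plant SF motif occurrences in splice windows (sense strand)
  sf_sites <- list()
  sf_slot_w <- cfg$sf_motif_length + 2L
  sf_slots_per_win <- 400L %/% sf_slot_w
  for (i in seq_len(n_iso)) {
    cons_i <- design$sf_site_conservation[i, ]
    planted_j <- which(cons_i > 0)
    if (!length(planted_j)) next
    check_that(length(planted_j) <= 2L * sf_slots_per_win,
               "too many SF sites to place on isoform %d", i)
    slots <- sample(seq_len(2L * sf_slots_per_win) - 1L, length(planted_j))
    for (k in seq_along(planted_j)) {
      j <- planted_j[k]
      w <- slots[k] %/% sf_slots_per_win  # 0 = donor window, 1 = acceptor
      off <- (slots[k] %% sf_slots_per_win) * sf_slot_w
      base <- if (w == 0L) donor[i] - 200L else acceptor[i] - 200L
      pos <- base + off
      word <- strsplit(design$sf_motifs$motif[j], "")[[1L]]
      genome_chars[(pos + 1L):(pos + cfg$sf_motif_length)] <- word
      sf_sites[[length(sf_sites) + 1L]] <- data.frame(
        isoform = design$iso_ids[i], factor = design$sf_motifs$factor[j],
        start = pos, end = pos + cfg$sf_motif_length,
        conservation = cons_i[j], stringsAsFactors = FALSE)
    }
  }
  sf_sites <- if (length(sf_sites)) do.call(rbind, sf_sites) else
    data.frame(isoform = character(0), factor = character(0),
               start = integer(0), end = integer(0),
               conservation = numeric(0))

  # remove accidental motif occurrences so measured = planted
  planted_spans <- rbind(tf_sites[, c("start", "end")],
                         sf_sites[, c("start", "end")])
  prom_regions <- data.frame(start = lay$prom_start, end = lay$prom_end)
  tf_words <- c(design$tf_consensus,
                vapply(design$tf_consensus, revcomp_chr, character(1L)))
  genome_chars <- scrub_occurrences(genome_chars, tf_words, prom_regions,
                                    planted_spans)
  genome_chars <- scrub_occurrences(genome_chars, design$sf_motifs$motif,
                                    win[, c("start", "end")], planted_spans)

  # conservation: truncated-normal background, peaks on planted SF sites
  cons <- pmax(rnorm(glen, cfg$conservation_background_mean, 0.5), 0)
  if (nrow(sf_sites))
    for (k in seq_len(nrow(sf_sites)))
      cons[(sf_sites$start[k] + 1L):sf_sites$end[k]] <- sf_sites$conservation[k]

  # write the bundle
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "isoforms.gtf"),
    pwms = file.path(dir, "pwms.jaspar"),
    sf_motifs = file.path(dir, "sf_motifs.tsv"),
    conservation = file.path(dir, "conservation.bedGraph"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"))

  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chrS"
  Biostrings::writeXStringSet(genome, paths$genome)

  exons <- rbind(
    data.frame(isoform_id = design$iso_ids, gene_id = design$gene_ids,
               chrom = "chrS", strand = "+",
               start = lay$exon1_start, end = lay$exon1_end),
    data.frame(isoform_id = design$iso_ids, gene_id = design$gene_ids,
               chrom = "chrS", strand = "+",
               start = lay$exon2_start, end = lay$exon2_end))
  models <- isoform_models_from_exons(exons)
  write_isoform_gtf(models, paths$gtf)

  write_jaspar(design$pwms, paths$pwms)
  write_tsv(design$sf_motifs, paths$sf_motifs)

  bg_lines <- sprintf("chrS\t%d\t%d\t%.4f", 0:(glen - 1L), 1:glen, cons)
  writeLines(bg_lines, paths$conservation)

  write_expression(design$expression, paths$expression)

  truth <- list(
    groups = lapply(design$groups, function(g)
      list(group_id = g$group_id, members = g$members,
           up_condition = g$up_condition, support = g$support,
           coefficients = g$coefficients, intercept = g$intercept)),
    tf_sites = tf_sites, sf_sites = sf_sites,
    tf_strength_true = data.frame(isoform_id = design$iso_ids,
                                  design$tf_strength_true,
                                  check.names = FALSE),
    sf_strength_true = data.frame(isoform_id = design$iso_ids,
                                  design$sf_strength_true,
                                  check.names = FALSE),
    response_true = as.list(stats::setNames(design$response_true,
                                            design$iso_ids)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(design = design, paths = paths, models = models,
                 layout = lay))
}
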