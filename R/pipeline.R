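#' Pipeline run configuration
#'
#' Collects input paths and the method's thresholds.  Defaults are the
#' method's standard operating values: FPKM floor 5, SF motif filter
#' (|score| >= 5, length <= 15), conservation floor 2, 2000-bp promoters,
#' 200-bp splice flanks, group sizes 10-30, GO term sizes 10-100 and FDR
#' alpha 0.05.
#'
#' @param genome,gtf,pwms,sf_motifs,conservation,expression Input paths
#'   (FASTA, GTF, JASPAR text, SF motif TSV, bedGraph, expression TSV).
#' @param gene_sets Optional named character vector of GMT paths; names
#'   are collection labels.  Collections named with a leading `GO` get the
#'   GO-style size filter.
#' @param out_dir Output directory for all stage files.
#' @param fpkm_min,motif_abs_score_min,motif_len_max,conservation_min
#'   Filtering thresholds.
#' @param promoter_len,splice_flank Sequence window sizes (bp).
#' @param group_size_min,group_size_max Co-expression group size bounds.
#' @param threshold_fraction PWM relative score threshold.
#' @param r2_min Keep threshold on adjusted R-squared.
#' @param go_size_min,go_size_max GO-type set size bounds.
#' @param q_alpha FDR threshold.
#' @param response,criterion,k Model options (see [fit_group()]).
#' @param paralog_groups Optional named list of SF paralog merge groups.
#' @param seed Seed used by any stage with randomness (fixture
#'   generation); the inference itself is deterministic.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(genome = NULL, gtf = NULL, pwms = NULL,
                       sf_motifs = NULL, conservation = NULL,
                       expression = NULL, gene_sets = NULL,
                       out_dir = "tsnet_out",
                       fpkm_min = 5, motif_abs_score_min = 5,
                       motif_len_max = 15L, conservation_min = 2,
                       promoter_len = 2000L, splice_flank = 200L,
                       group_size_min = 10L, group_size_max = 30L,
                       threshold_fraction = 0.8, r2_min = 0.5,
                       go_size_min = 10L, go_size_max = 100L,
                       q_alpha = 0.05, response = "condition_mean",
                       criterion = "cp", k = NULL,
                       paralog_groups = NULL, seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("fpkm_min", "motif_abs_score_min", "motif_len_max",
              "conservation_min", "promoter_len", "splice_flank",
              "group_size_min", "group_size_max", "threshold_fraction",
              "go_size_min", "go_size_max", "q_alpha"))
    check_that(cfg[[f]] > 0, "threshold %s must be positive", f)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat key=value file
#'
#' Lines of the form `key = value` (or `key=value`); `#` starts a comment.
#' `gene_sets` takes `label:path` entries separated by commas.
#'
#' @param path Configuration file path.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(lapply(kv, function(x) paste(x[-1L], collapse = "=")),
                          vapply(kv, `[[`, character(1L), 1L))
  num_fields <- c("fpkm_min", "motif_abs_score_min", "motif_len_max",
                  "conservation_min", "promoter_len", "splice_flank",
                  "group_size_min", "group_size_max", "threshold_fraction",
                  "r2_min", "go_size_min", "go_size_max", "q_alpha", "seed",
                  "k")
  for (f in intersect(names(args), num_fields))
    args[[f]] <- as.numeric(args[[f]])
  if ("gene_sets" %in% names(args)) {
    parts <- strsplit(strsplit(args$gene_sets, ",")[[1L]], ":")
    args$gene_sets <- stats::setNames(
      vapply(parts, `[[`, character(1L), 2L),
      vapply(parts, `[[`, character(1L), 1L))
  }
  do.call(run_config, modifyList(args, list(...)))
}

out_path <- function(config, name) file.path(config$out_dir, name)

stage_preprocess <- function(config) {
  expr <- read_expression(config$expression)
  deis <- filter_deis(expr, fpkm_min = config$fpkm_min)
  groups <- cluster_coexpressed(deis, min_size = config$group_size_min,
                                max_size = config$group_size_max)
  write_groups(groups, out_path(config, "groups.tsv"),
               out_path(config, "clustering_report.json"))
  list(expr = expr, deis = deis, groups = groups)
}

write_strength_tsv <- function(m, path) {
  df <- data.frame(isoform_id = rownames(m),
                   as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

read_strength_tsv <- function(path, flavor) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$isoform_id
  structure(m, flavor = flavor, class = c("strength_matrix", "matrix", "array"))
}

stage_score_tf <- function(config, models, genome, isoforms) {
  pwms <- read_jaspar(config$pwms)
  keep <- models$transcripts$isoform_id %in% isoforms
  sub <- list(transcripts = models$transcripts[keep, , drop = FALSE],
              exons = models$exons[models$exons$isoform_id %in% isoforms, ,
                                   drop = FALSE])
  class(sub) <- "isoform_models"
  prd <- extract_promoters(sub, genome, promoter_len = config$promoter_len)
  Biostrings::writeXStringSet(prd, out_path(config, "prd.fa"))
  sites <- scan_promoters(prd, pwms,
                          threshold_fraction = config$threshold_fraction)
  write_tsv(sites, out_path(config, "tf_sites.tsv"))
  m <- tf_strength_matrix(sites, isoforms, names(pwms))
  write_strength_tsv(m, out_path(config, "tf_strength.tsv"))
  m
}

stage_score_sf <- function(config, models, genome, isoforms) {
  motifs <- read_sf_motifs(config$sf_motifs)
  motifs <- filter_sf_motifs(motifs,
                             min_abs_score = config$motif_abs_score_min,
                             max_len = config$motif_len_max)
  track <- read_conservation(config$conservation)
  keep <- models$transcripts$isoform_id %in% isoforms
  sub <- list(transcripts = models$transcripts[keep, , drop = FALSE],
              exons = models$exons[models$exons$isoform_id %in% isoforms, ,
                                   drop = FALSE])
  class(sub) <- "isoform_models"
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  windows <- extract_splice_windows(sub, flank = config$splice_flank,
                                    contig_lengths = clen)
  eid <- Biostrings::DNAStringSet(vapply(seq_len(nrow(windows)), function(i)
    as.character(Biostrings::subseq(genome[[windows$chrom[i]]],
                                    windows$start[i] + 1L, windows$end[i])),
    character(1L)))
  names(eid) <- sprintf("%s:%d-%d", windows$isoform, windows$start,
                        windows$end)
  Biostrings::writeXStringSet(eid, out_path(config, "eid.fa"))
  hits <- score_sf_hits(windows, motifs, genome, track, sub,
                        conservation_min = config$conservation_min)
  write_tsv(hits, out_path(config, "sf_hits.tsv"))
  m <- sf_strength_matrix(hits, isoforms, unique(motifs$factor))
  if (!is.null(config$paralog_groups))
    m <- merge_paralog_factors(m, config$paralog_groups)
  write_strength_tsv(m, out_path(config, "sf_strength.tsv"))
  m
}

stage_fit <- function(config, groups, tf_strength, sf_strength, expr) {
  fits <- lapply(groups, function(g) {
    fit <- fit_group(g, tf_strength, sf_strength, expr,
                     response = config$response,
                     criterion = config$criterion, k = config$k,
                     r2_min = config$r2_min)
    write_fit_json(fit, out_path(config, sprintf("fit_group_%03d.json",
                                                 g$group_id)))
    fit
  })
  fits
}

stage_networks <- function(config, fits, groups, tf_strength, sf_strength,
                           gene_of) {
  kept <- which(vapply(fits, function(f) isTRUE(f$kept), logical(1L)))
  networks <- lapply(kept, function(i)
    assemble_network(fits[[i]], groups[[i]], tf_strength, sf_strength,
                     gene_of = gene_of))
  write_networks_tsv(networks, out_path(config, "networks.tsv"))
  for (nw in networks)
    write_network_graphml(nw, out_path(config,
                                       sprintf("network_%03d.graphml",
                                               nw$group_id)))
  networks
}

stage_enrich <- function(config, networks, universe) {
  if (is.null(config$gene_sets) || !length(networks)) return(NULL)
  collections <- lapply(names(config$gene_sets), function(label) {
    sets <- read_gmt(config$gene_sets[[label]])
    if (grepl("^GO", label, ignore.case = TRUE))
      sets <- filter_gene_sets(sets, universe,
                               min_size = config$go_size_min,
                               max_size = config$go_size_max)
    sets
  })
  names(collections) <- names(config$gene_sets)
  res <- enrich_networks(networks, collections, universe,
                         alpha = config$q_alpha)
  write_tsv(res, out_path(config, "enrichment.tsv"))
  res
}

#' Run the full inference pipeline
#'
#' Executes all stages in order: DEI filtering and co-expression
#' clustering; promoter extraction and PWM scanning into the TF strength
#' matrix; splice-window extraction, conservation-filtered SF motif
#' scanning into the SF strength matrix; per-group LARS fits; network
#' assembly for well-fitting groups; and optional gene-set enrichment.
#' All intermediates are written to `config$out_dir`; the run is fully
#' deterministic given the inputs.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: stage counts, per-group adjusted
#'   R-squared, configuration echo, package version and elapsed seconds
#'   (the persisted `report.json` omits the elapsed time so repeated runs
#'   are byte-identical).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("genome", "gtf", "pwms", "sf_motifs", "conservation",
              "expression")) {
    check_that(!is.null(config[[f]]) && file.exists(config[[f]]),
               "input '%s' missing or not found", f)
  }
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  models <- read_isoform_models(config$gtf)

  pre <- stage_preprocess(config)
  groups <- pre$groups
  isoforms <- sort(unique(unlist(lapply(groups, `[[`, "members"))))
  if (!length(isoforms)) {
    warning("no co-expressed groups; pipeline produced empty outputs")
    report <- build_report(config, pre, groups, list(), list(), NULL, t0)
    return(report)
  }
  tf_m <- stage_score_tf(config, models, genome, isoforms)
  sf_m <- stage_score_sf(config, models, genome, isoforms)
  fits <- stage_fit(config, groups, tf_m, sf_m, pre$deis)
  gene_of <- stats::setNames(models$transcripts$gene_id,
                             models$transcripts$isoform_id)
  networks <- stage_networks(config, fits, groups, tf_m, sf_m, gene_of)
  universe <- sort(unique(models$transcripts$gene_id))
  enr <- stage_enrich(config, networks, universe)
  build_report(config, pre, groups, fits, networks, enr, t0)
}

build_report <- function(config, pre, groups, fits, networks, enr, t0) {
  counts <- list(
    isoforms_in = nrow(pre$expr$info),
    deis = nrow(pre$deis$info),
    groups = length(groups),
    fits = length(fits),
    kept_networks = length(networks))
  per_group <- lapply(fits, function(f)
    list(group_id = f$group_id, n = f$n, step = f$step,
         adjusted_r_squared = f$adjusted_r_squared, kept = f$kept))
  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL  # the report already lives there
  cfg_echo <- cfg_echo[!vapply(cfg_echo, is.null, logical(1L))]
  report <- list(counts = counts, per_group = per_group,
                 n_enrichment_tests = if (is.null(enr)) 0L else nrow(enr),
                 config = cfg_echo,
                 version = as.character(utils::packageVersion("tsnet")))
  jsonlite::write_json(report, out_path(config, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf(
    "run_report: %d isoforms -> %d DEIs -> %d groups -> %d kept networks (%.1f s)\n",
    c0$isoforms_in, c0$deis, c0$groups, c0$kept_networks,
    x$elapsed_sec %||% NA_real_))
  invisible(x)
}
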