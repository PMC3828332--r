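#' Filter differentially expressed isoforms
#'
#' Keeps the isoforms suitable for network modelling: those called
#' differentially expressed upstream (`de_flag`), validated at the protein
#' level, and with every FPKM value in their up-regulated condition
#' strictly greater than `fpkm_min`.
#'
#' @param expr An `expression_table` (see [read_expression()]).
#' @param fpkm_min FPKM floor; a value exactly equal to `fpkm_min` fails
#'   (the rule is strictly greater). Default 5.
#' @return An `expression_table` restricted to the retained isoforms.
#' @export
filter_deis <- function(expr, fpkm_min = 5) {
  info <- expr$info
  keep <- logical(nrow(info))
  for (i in seq_len(nrow(info))) {
    up <- info$up_condition[i]
    cols <- which(expr$condition == up)
    check_that(length(cols) > 0L,
               "isoform %s: no sample for up_condition '%s'",
               info$isoform_id[i], up)
    keep[i] <- isTRUE(info$de_flag[i]) &&
      isTRUE(info$protein_evidence[i]) &&
      all(expr$fpkm[i, cols] > fpkm_min)
  }
  structure(list(info = info[keep, , drop = FALSE],
                 fpkm = expr$fpkm[keep, , drop = FALSE],
                 condition = expr$condition),
            class = "expression_table")
}

# Recursively re-cut an oversized cluster at its own merge heights until
# every part has at most max_size members.  If average-linkage bisection
# degenerates (a shard below min_size out of a splittable cluster), fall
# back to chunking the dendrogram leaf order into near-equal parts, which
# keeps co-expressed neighbours together and guarantees legal sizes.
cut_to_size <- function(ids, dmat, min_size, max_size) {
  n <- length(ids)
  if (n <= max_size) {
    if (n >= min_size) return(list(ids))
    return(list())
  }
  hc <- hclust(stats::as.dist(dmat[ids, ids, drop = FALSE]),
               method = "average")
  parts <- cutree(hc, k = 2L)
  sizes <- tabulate(parts, 2L)
  if (n >= 2L * min_size && any(sizes < min_size)) {
    k <- ceiling(n / max_size)
    chunk <- ceiling(n / k)
    ord <- ids[hc$order]
    return(split(ord, ceiling(seq_along(ord) / chunk)))
  }
  out <- list()
  for (k in 1:2)
    out <- c(out, cut_to_size(ids[parts == k], dmat, min_size, max_size))
  out
}

#' Cluster DEIs into co-expressed groups
#'
#' Hierarchical (average-linkage) clustering on Pearson correlation
#' distance `1 - r` of per-sample expression profiles.  The dendrogram is
#' cut top-down at correlation distance `h_cut` (so members of a cluster
#' are positively co-expressed); clusters larger than `max_size` are
#' recursively re-cut at their own merge heights, and clusters smaller
#' than `min_size` are dropped (with a message).  Every emitted group
#' therefore has between `min_size` and `max_size` members.  Processing
#' order is fixed by isoform id, so results do not depend on input row
#' order.
#'
#' @param expr An `expression_table` of DEIs (output of [filter_deis()]).
#' @param min_size,max_size Allowed group sizes (defaults 10 and 30).
#' @param h_cut Dendrogram cut height on the `1 - r` scale (default 0.3,
#'   i.e. clusters are joined while average correlation exceeds 0.7).
#' @return A list of `coexpression_group` objects, each with `group_id`,
#'   `members` (isoform ids), `expression` (members x samples matrix) and
#'   `mean_pairwise_r`.
#' @export
cluster_coexpressed <- function(expr, min_size = 10L, max_size = 30L,
                                h_cut = 0.3) {
  mat <- expr$fpkm
  check_that(ncol(mat) >= 2L, "need at least 2 samples to correlate")
  if (nrow(mat) < min_size) {
    warning("fewer DEIs than the minimum group size; no groups emitted")
    return(list())
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  constant <- apply(mat, 1L, function(v) sd(v) == 0 || !is.finite(sd(v)))
  if (any(constant)) {
    warning(sprintf("dropping %d constant-expression isoform(s) before clustering",
                    sum(constant)))
    mat <- mat[!constant, , drop = FALSE]
  }
  if (nrow(mat) < min_size) {
    warning("fewer DEIs than the minimum group size; no groups emitted")
    return(list())
  }
  r <- cor(t(mat))
  dmat <- 1 - r
  dimnames(dmat) <- list(rownames(mat), rownames(mat))
  hc <- hclust(stats::as.dist(dmat), method = "average")
  top <- cutree(hc, h = h_cut)
  clusters <- list()
  for (cl in sort(unique(top)))
    clusters <- c(clusters,
                  cut_to_size(rownames(mat)[top == cl], dmat,
                              min_size, max_size))
  dropped <- setdiff(rownames(mat), unlist(clusters))
  if (length(dropped))
    message(sprintf("%d isoform(s) in undersized clusters dropped", length(dropped)))
  # deterministic group numbering by first member id
  clusters <- clusters[order(vapply(clusters, min, character(1L)))]
  lapply(seq_along(clusters), function(g) {
    ids <- sort(clusters[[g]])
    rsub <- r[ids, ids]
    structure(list(group_id = g, members = ids,
                   expression = mat[ids, , drop = FALSE],
                   mean_pairwise_r = mean(rsub[upper.tri(rsub)])),
              class = "coexpression_group")
  })
}

#' @export
print.coexpression_group <- function(x, ...) {
  cat(sprintf("coexpression_group %d: %d isoforms, mean pairwise r = %.3f\n",
              x$group_id, length(x$members), x$mean_pairwise_r))
  invisible(x)
}

# Persist group membership as TSV and the clustering report as JSON.
write_groups <- function(groups, tsv_path, report_path = NULL) {
  df <- do.call(rbind, lapply(groups, function(g)
    data.frame(group_id = g$group_id, isoform_id = g$members,
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(group_id = integer(0), isoform_id = character(0))
  write_tsv(df, tsv_path)
  if (!is.null(report_path)) {
    rep <- lapply(groups, function(g)
      list(group_id = g$group_id, size = length(g$members),
           mean_pairwise_r = g$mean_pairwise_r))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
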