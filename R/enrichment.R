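#' Filter gene sets by size
#'
#' Restricts each set to the universe and keeps sets whose resulting size
#' lies within `[min_size, max_size]` (both inclusive; a set of exactly
#' `min_size` or `max_size` genes is kept).  Used for GO-type collections,
#' where very small and very large terms are uninformative for networks of
#' this size.
#'
#' @param sets Named list of character vectors (gene sets).
#' @param universe Character vector of gene ids; set sizes are computed
#'   after intersecting with it.
#' @param min_size,max_size Inclusive size bounds (defaults 10 and 100).
#' @return The filtered, universe-intersected named list.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 10L,
                             max_size = 100L) {
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sizes <- lengths(sets)
  sets[sizes >= min_size & sizes <= max_size]
}

#' One-sided Fisher's exact test for over-representation
#'
#' Exact hypergeometric upper-tail probability of observing at least the
#' given overlap between a network's gene list and a gene set, within the
#' universe.
#'
#' @param network_genes,gene_set Character vectors, subsets of `universe`.
#' @param universe Character vector of all considered gene ids.
#' @return A list with the 2x2 counts (`overlap`, `network_only`,
#'   `set_only`, `neither`) and `p`.
#' @export
fisher_test <- function(network_genes, gene_set, universe) {
  universe <- unique(universe)
  check_that(length(universe) > 0L, "empty universe")
  ng <- intersect(unique(network_genes), universe)
  gs <- intersect(unique(gene_set), universe)
  ov <- length(intersect(ng, gs))
  n_net <- length(ng); n_set <- length(gs); n_u <- length(universe)
  # upper tail P(K >= ov) for K ~ Hypergeom(n_u, n_set, n_net)
  p <- phyper(ov - 1L, n_set, n_u - n_set, n_net, lower.tail = FALSE)
  list(overlap = ov, network_only = n_net - ov, set_only = n_set - ov,
       neither = n_u - n_net - n_set + ov, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values, monotone in p-rank and capped at 1,
#' returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  check_that(all(is.finite(pvalues)) && all(pvalues >= 0) &&
               all(pvalues <= 1), "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Enrichment of networks in gene-set collections
#'
#' For each collection, computes the one-sided Fisher p-value of every
#' (network, set) pair, applies Benjamini-Hochberg FDR control within the
#' collection, and flags pairs with `q < alpha` and, separately, pairs
#' with raw `p < p_report` (the raw-p reporting convention used for
#' GO-style collections).
#'
#' @param networks List of `tsn_network` objects.
#' @param collections Named list of collections; each collection is a named
#'   list of gene sets (e.g. from [read_gmt()]), already size-filtered
#'   where appropriate.
#' @param universe Character vector of gene ids.
#' @param alpha FDR threshold (default 0.05).
#' @param p_report Raw-p reporting threshold (default 1e-4).
#' @param factor_gene Optional factor-to-gene map (see [network_genes()]).
#' @return Data frame with columns `collection`, `network_id`, `set`,
#'   `overlap`, `network_size`, `set_size`, `p`, `q`, `flagged_fdr`,
#'   `flagged_raw`.
#' @export
enrich_networks <- function(networks, collections, universe, alpha = 0.05,
                            p_report = 1e-4, factor_gene = NULL) {
  universe <- unique(universe)
  out <- list()
  for (cname in names(collections)) {
    coll <- collections[[cname]]
    rows <- list()
    for (nw in networks) {
      genes <- intersect(network_genes(nw, factor_gene), universe)
      if (!length(genes)) {
        warning(sprintf("network %d shares no genes with the universe; skipped",
                        nw$group_id))
        next
      }
      for (sname in names(coll)) {
        ft <- fisher_test(genes, coll[[sname]], universe)
        rows[[length(rows) + 1L]] <- data.frame(
          collection = cname, network_id = nw$group_id, set = sname,
          overlap = ft$overlap, network_size = ft$overlap + ft$network_only,
          set_size = ft$overlap + ft$set_only, p = ft$p,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df$q <- bh_fdr(df$p)
    df$flagged_fdr <- df$q < alpha
    df$flagged_raw <- df$p < p_report
    out[[length(out) + 1L]] <- df
  }
  if (!length(out))
    return(data.frame(collection = character(0), network_id = integer(0),
                      set = character(0), overlap = integer(0),
                      network_size = integer(0), set_size = integer(0),
                      p = numeric(0), q = numeric(0),
                      flagged_fdr = logical(0), flagged_raw = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
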