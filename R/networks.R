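#' Assemble a transcription-and-splicing network for one group
#'
#' Builds the bipartite factor-to-target network of a kept fit: an edge
#' runs from a selected factor to a group member iff the factor's
#' interaction strength on that isoform is positive.  The edge weight is
#' the strength value and the edge sign is the sign of the factor's
#' regression coefficient (negative coefficients mark putative
#' inhibition).
#'
#' @param fit A kept `group_fit` (refused when `fit$kept` is `FALSE`).
#' @param group The matching `coexpression_group`.
#' @param tf_strength,sf_strength The `strength_matrix` pair.
#' @param gene_of Optional named character vector mapping isoform ids to
#'   gene names for display.
#' @return A list of class `tsn_network` with `group_id`,
#'   `adjusted_r_squared`, `factors` (data frame: factor, type,
#'   coefficient), `targets` (data frame: isoform, gene) and `edges`
#'   (data frame: factor, factor_type, coefficient, sign, isoform, gene,
#'   strength).
#' @export
assemble_network <- function(fit, group, tf_strength, sf_strength,
                             gene_of = NULL) {
  check_that(isTRUE(fit$kept), "fit was not kept (ill-fitting group)")
  check_that(fit$group_id == group$group_id,
             "fit/group id mismatch (%s vs %s)", fit$group_id, group$group_id)
  members <- group$members
  gene <- if (is.null(gene_of)) stats::setNames(members, members) else gene_of
  edges <- list()
  isolated <- character(0)
  for (f in fit$selected) {
    m <- if (fit$factor_type[[f]] == "TF") tf_strength else sf_strength
    str_f <- if (f %in% colnames(m)) m[members, f] else
      stats::setNames(numeric(length(members)), members)
    hit <- members[str_f > 0]
    if (!length(hit)) {
      isolated <- c(isolated, f)
      next
    }
    edges[[length(edges) + 1L]] <- data.frame(
      factor = f, factor_type = unname(fit$factor_type[[f]]),
      coefficient = unname(fit$coefficients[[f]]),
      sign = if (fit$coefficients[[f]] >= 0) "+" else "-",
      isoform = hit, gene = unname(gene[hit]), strength = unname(str_f[hit]),
      stringsAsFactors = FALSE)
  }
  if (length(isolated))
    warning(sprintf("selected factor(s) with no positive strength on any member: %s",
                    paste(isolated, collapse = ", ")))
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(factor = character(0), factor_type = character(0),
               coefficient = numeric(0), sign = character(0),
               isoform = character(0), gene = character(0),
               strength = numeric(0))
  structure(list(
    group_id = group$group_id,
    adjusted_r_squared = fit$adjusted_r_squared,
    factors = data.frame(factor = fit$selected,
                         type = unname(fit$factor_type[fit$selected]),
                         coefficient = unname(fit$coefficients[fit$selected]),
                         stringsAsFactors = FALSE),
    targets = data.frame(isoform = members, gene = unname(gene[members]),
                         stringsAsFactors = FALSE),
    edges = edges), class = "tsn_network")
}

#' @export
print.tsn_network <- function(x, ...) {
  cat(sprintf(
    "tsn_network (group %d): %d factors -> %d targets, %d edges, adj R^2 = %.3f\n",
    x$group_id, nrow(x$factors), nrow(x$targets), nrow(x$edges),
    x$adjusted_r_squared))
  invisible(x)
}

#' Gene list of a network
#'
#' The deduplicated union of target genes and factor genes, used for
#' enrichment testing.
#'
#' @param network A `tsn_network`.
#' @param factor_gene Optional named vector mapping factor names to gene
#'   ids; factors absent from the map keep their own name.
#' @return Character vector of gene ids.
#' @export
network_genes <- function(network, factor_gene = NULL) {
  fg <- network$factors$factor
  if (!is.null(factor_gene)) {
    mapped <- factor_gene[fg]
    fg <- ifelse(is.na(mapped), fg, mapped)
  }
  sort(unique(c(network$targets$gene, fg)))
}

#' Serialize networks to a single TSV edge table
#'
#' @param networks List of `tsn_network` objects.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_networks_tsv <- function(networks, path) {
  rows <- lapply(networks, function(nw) {
    if (!nrow(nw$edges)) return(NULL)
    cbind(group_id = nw$group_id,
          nw$edges[, c("factor", "factor_type", "coefficient", "isoform",
                       "gene", "strength")])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(group_id = integer(0), factor = character(0),
                     factor_type = character(0), coefficient = numeric(0),
                     isoform = character(0), gene = character(0),
                     strength = numeric(0))
  write_tsv(df, path)
}

#' Convert a network to an igraph bipartite graph
#'
#' Factor nodes carry `type` (TF/SF) and `coefficient`; target nodes carry
#' `gene`; edges carry `strength` and `sign`.
#'
#' @param network A `tsn_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  nodes <- rbind(
    data.frame(name = network$factors$factor, kind = network$factors$type,
               stringsAsFactors = FALSE),
    data.frame(name = network$targets$isoform, kind = "target",
               stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("factor", "isoform", "strength", "sign")],
    directed = TRUE, vertices = nodes)
  g
}

#' Write a network as GraphML
#'
#' @param network A `tsn_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
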