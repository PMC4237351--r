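# Projection of gene-level selections onto the PPI network and extraction
# of connected components among the selected proteins.

#' Select genes at a -log10 p-value cutoff
#'
#' Returns the genes whose corrected gene-wise p-value satisfies
#' `-log10(p) >= cutoff` (equivalently `p <= 10^-cutoff`). Selection is
#' monotone: a higher cutoff always yields a subset.
#'
#' @param scores gene score table from [gene_scores()].
#' @param cutoff_neglogp positive cutoff on `-log10(corrected_p)`.
#' @return character vector of selected gene ids (sorted).
#' @export
select_genes <- function(scores, cutoff_neglogp) {
  stopifnot(cutoff_neglogp > 0)
  scores <- as.data.table(scores)
  sort(scores[neg_log10_p >= cutoff_neglogp, gene_id])
}

#' Map selected genes onto PPI network proteins
#'
#' Selection is propagated through the gene-protein map with union
#' semantics: every protein mapped by any selected gene and present in the
#' network is selected once. Genes mapping to no network protein are
#' recorded as unmapped.
#'
#' @param genes character vector of selected gene ids.
#' @param map gene-protein map from [read_gene_map()].
#' @param net PPI network (`igraph`).
#' @param cutoff_neglogp optional cutoff recorded in the result.
#' @return object of class `selected_set`: list with `cutoff_neglogp`,
#'   `genes`, `proteins` (sorted, subset of network nodes), `unmapped_genes`.
#' @export
map_to_network <- function(genes, map, net, cutoff_neglogp = NA_real_) {
  map <- as.data.table(map)
  nodes <- igraph::V(net)$name
  hit <- map[gene_id %in% genes & protein_id %in% nodes]
  proteins <- sort(unique(hit$protein_id))
  mapped_genes <- unique(hit$gene_id)
  structure(list(cutoff_neglogp = cutoff_neglogp,
                 genes = sort(unique(genes)),
                 proteins = proteins,
                 unmapped_genes = sort(setdiff(genes, mapped_genes))),
            class = "selected_set")
}

#' @export
print.selected_set <- function(x, ...) {
  cat(sprintf("selected_set: %d genes -> %d network proteins (%d unmapped genes)",
              length(x$genes), length(x$proteins), length(x$unmapped_genes)))
  if (!is.na(x$cutoff_neglogp))
    cat(sprintf(" at -log10P >= %g", x$cutoff_neglogp))
  cat("\n")
  invisible(x)
}

#' Connected components of the selected-protein subgraph
#'
#' Components are computed on the subgraph induced by the selected
#' proteins: two selected proteins belong to the same component only when
#' they are connected through edges whose endpoints are both selected.
#' Paths that detour through unselected proteins do not merge components
#' (no bridging); this matches the definition of the isolated-node metric,
#' under which a selected protein with neighbours only outside the
#' selection counts as isolated.
#'
#' @param net PPI network (`igraph`).
#' @param subset character vector of selected protein ids (must be network
#'   nodes).
#' @return list of character vectors (each sorted), ordered by decreasing
#'   size with ties broken by the lexicographically smallest member.
#' @export
subgraph_components <- function(net, subset) {
  subset <- unique(as.character(subset))
  stopifnot(all(subset %in% igraph::V(net)$name))
  if (!length(subset)) return(list())
  sub <- igraph::induced_subgraph(net, subset)
  comp <- igraph::components(sub)
  groups <- split(igraph::V(sub)$name, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, `[`, character(1), 1L))
  unname(groups[ord])
}

#' Largest connected component of a selection
#'
#' @inheritParams subgraph_components
#' @return character vector of the proteins in the LCC (empty if `subset`
#'   is empty).
#' @export
lcc_proteins <- function(net, subset) {
  comps <- subgraph_components(net, subset)
  if (!length(comps)) character() else comps[[1L]]
}

#' Genes encoding a set of proteins
#'
#' Inverse lookup through the gene-protein map, used to translate an LCC
#' protein set back to gene identifiers for benchmarking.
#'
#' @param proteins character vector of protein ids.
#' @param map gene-protein map.
#' @return sorted character vector of gene ids mapping to any of `proteins`.
#' @export
genes_for_proteins <- function(proteins, map) {
  map <- as.data.table(map)
  sort(unique(map[protein_id %in% proteins, gene_id]))
}
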