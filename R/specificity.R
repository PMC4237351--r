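# Replication/specificity scoring of primary-LCC proteins across a
# replication dataset and a panel of unrelated-disease datasets.

#' Score primary-LCC proteins for reproducibility and disease specificity
#'
#' Every protein of the primary-dataset LCC starts at 0.5. Presence in the
#' replication-dataset LCC adds 0.5; presence in each of the K
#' unrelated-disease LCCs subtracts 0.5/K. Scores therefore live on the
#' lattice `(K(1 + replication) - n_unrelated) / (2K)` in [0, 1]: 1 means
#' replicated and absent from every unrelated disease, 0 means not
#' replicated and present in all of them. The arithmetic is carried out on
#' the integer numerator so equality tests on scores are exact.
#'
#' @param primary_lcc character vector of primary-LCC protein ids
#'   (non-empty).
#' @param replication_lcc character vector (possibly empty) of
#'   replication-LCC protein ids.
#' @param unrelated_lccs list of K >= 1 character vectors, one per
#'   unrelated-disease LCC.
#' @return `data.table` with one row per primary-LCC protein:
#'   `protein_id`, `in_replication_lcc`, `n_unrelated_lccs`, `score`;
#'   sorted by decreasing score then protein id.
#' @export
score_proteins <- function(primary_lcc, replication_lcc, unrelated_lccs) {
  primary_lcc <- unique(as.character(primary_lcc))
  if (!length(primary_lcc)) stop("primary LCC is empty", call. = FALSE)
  if (!is.list(unrelated_lccs) || length(unrelated_lccs) < 1L)
    stop("unrelated_lccs must be a list of at least one protein set",
         call. = FALSE)
  K <- length(unrelated_lccs)
  in_rep <- primary_lcc %in% unique(as.character(replication_lcc))
  n_unrel <- Reduce(`+`, lapply(unrelated_lccs, function(s)
    as.integer(primary_lcc %in% unique(as.character(s)))),
    accumulate = FALSE, init = integer(length(primary_lcc)))
  numerator <- K * (1L + as.integer(in_rep)) - as.integer(n_unrel)
  out <- data.table(protein_id = primary_lcc,
                    in_replication_lcc = in_rep,
                    n_unrelated_lccs = as.integer(n_unrel),
                    score = numerator / (2 * K))
  out[order(-score, protein_id)]
}

#' Summarize a specificity score table
#'
#' Tabulates proteins by (replication presence, number of unrelated LCCs)
#' stratum and by score value, so any marginal of interest (e.g. the
#' fraction replicated but non-specific) can be read off directly.
#'
#' @param scores table from [score_proteins()].
#' @return list with `by_stratum` and `by_score` `data.table`s (counts and
#'   fractions; fractions sum to 1 in each table).
#' @export
score_summary <- function(scores) {
  scores <- as.data.table(scores)
  if (!nrow(scores)) stop("empty score table", call. = FALSE)
  n <- nrow(scores)
  by_stratum <- scores[, .(n = .N, fraction = .N / n),
                       by = .(in_replication_lcc, n_unrelated_lccs)][
                         order(-in_replication_lcc, n_unrelated_lccs)]
  by_score <- scores[, .(n = .N, fraction = .N / n), by = score][order(-score)]
  list(by_stratum = by_stratum[], by_score = by_score[])
}

#' Top-scoring genes and their first neighbours within the LCC
#'
#' Extracts, from the induced primary-LCC subgraph, the proteins whose
#' specificity score reaches `score_threshold` together with their direct
#' neighbours in the LCC, as an induced subgraph annotated with per-node
#' scores (for plotting, the score is the natural colour scale).
#'
#' @param primary_lcc_graph `igraph` induced subgraph on the primary LCC
#'   (e.g. `igraph::induced_subgraph(net, lcc_proteins(net, sel$proteins))`).
#' @param scores table from [score_proteins()] covering the LCC proteins.
#' @param score_threshold minimum score for a "top" protein (default 1,
#'   i.e. replicated and fully disease-specific).
#' @return `igraph` subgraph with vertex attributes `score` and `is_top`.
#' @export
top_gene_network <- function(primary_lcc_graph, scores, score_threshold = 1.0) {
  scores <- as.data.table(scores)
  nodes <- igraph::V(primary_lcc_graph)$name
  sc <- setNames(scores$score, scores$protein_id)[nodes]
  top <- nodes[!is.na(sc) & sc >= score_threshold]
  if (!length(top))
    stop(sprintf(paste0("no protein reaches score threshold %g; ",
                        "try a lower threshold"), score_threshold),
         call. = FALSE)
  nbr_idx <- unique(unlist(igraph::adjacent_vertices(primary_lcc_graph, top)))
  nbrs <- igraph::V(primary_lcc_graph)$name[nbr_idx]
  keep <- union(top, intersect(nbrs, nodes))
  g <- igraph::induced_subgraph(primary_lcc_graph, keep)
  igraph::V(g)$score <- unname(sc[igraph::V(g)$name])
  igraph::V(g)$is_top <- igraph::V(g)$name %in% top
  g
}
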