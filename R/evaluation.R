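# Benchmarking of gene selections against a candidate list and
# quantification of cross-dataset overlap.

#' Precision and recall of a gene selection against a candidate list
#'
#' Precision (positive predictive value) is the percentage of selected
#' genes that are known candidates; recall (sensitivity) is the percentage
#' of known candidates retrieved. Matching is by exact gene id after case
#' normalization; duplicates in either input are ignored.
#'
#' @param selected character vector of selected gene ids (non-empty).
#' @param candidates character vector of candidate gene ids (non-empty).
#' @param label optional label describing the selection.
#' @return one-row `data.frame`: `selection_label`, `n_selected`, `n_hits`,
#'   `precision_pct`, `recall_pct`.
#' @export
precision_recall <- function(selected, candidates, label = "selection") {
  selected <- unique(toupper(as.character(selected)))
  candidates <- unique(toupper(as.character(candidates)))
  if (!length(selected)) stop("empty selection: precision undefined", call. = FALSE)
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  hits <- length(intersect(selected, candidates))
  data.frame(selection_label = label,
             n_selected = length(selected),
             n_hits = hits,
             precision_pct = 100 * hits / length(selected),
             recall_pct = 100 * hits / length(candidates),
             stringsAsFactors = FALSE)
}

#' Build the three benchmark gene selections
#'
#' Given the LCC gene set at a cutoff, returns the three selections that
#' are compared against the candidate list: the LCC genes themselves, the
#' same number of top-ranked genes (ascending corrected p, ties broken by
#' gene id), and all genes selected at the cutoff.
#'
#' @param scores gene score table from [gene_scores()].
#' @param lcc_genes character vector, must be a subset of the genes
#'   selected at `cutoff`.
#' @param cutoff `-log10 P` cutoff used to derive the LCC.
#' @return named list of character vectors: `lcc_genes`, `top_genes`,
#'   `all_at_cutoff`.
#' @export
build_selections <- function(scores, lcc_genes, cutoff) {
  scores <- as.data.table(scores)
  all_at_cutoff <- select_genes(scores, cutoff)
  lcc_genes <- sort(unique(as.character(lcc_genes)))
  if (!all(lcc_genes %in% all_at_cutoff))
    stop("lcc_genes must be a subset of the genes selected at the cutoff",
         call. = FALSE)
  n <- length(lcc_genes)
  if (n > nrow(scores))
    stop("more LCC genes than scored genes", call. = FALSE)
  top <- scores[order(corrected_p, gene_id), gene_id][seq_len(n)]
  list(lcc_genes = lcc_genes, top_genes = sort(top),
       all_at_cutoff = all_at_cutoff)
}

#' Jaccard overlap of two sets
#'
#' @param a,b character vectors (at least one non-empty).
#' @param level optional label (`"snp"`, `"gene"`, `"lcc"`, ...).
#' @return one-row `data.frame`: `level`, `jaccard`, `n_intersection`,
#'   `n_union`.
#' @export
jaccard <- function(a, b, level = NA_character_) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  n_union <- length(union(a, b))
  if (n_union == 0L) stop("Jaccard undefined for two empty sets", call. = FALSE)
  n_int <- length(intersect(a, b))
  data.frame(level = level, jaccard = n_int / n_union,
             n_intersection = n_int, n_union = n_union,
             stringsAsFactors = FALSE)
}

#' Cross-dataset overlap at SNP, gene and LCC level
#'
#' Quantifies reproducibility between two independently analysed datasets.
#' To compare like with like, the LCC size of each dataset fixes the
#' number of top SNPs (ranked by SNP p-value) and top genes (ranked by
#' corrected gene-wise p-value) taken from that dataset; the Jaccard index
#' is then computed at all three levels, together with the fold gain of
#' network-level overlap over SNP- and gene-level overlap.
#'
#' @param ds1,ds2 lists with components `snps` (SNP table), `scores` (gene
#'   score table) and `lcc_genes` (character vector, non-empty).
#' @return `data.frame` of three [jaccard()] rows (levels snp/gene/lcc)
#'   with attribute `fold_change` (named vector `lcc_vs_snp`,
#'   `lcc_vs_gene`; `NA` when the denominator overlap is zero).
#' @export
cross_dataset_overlap <- function(ds1, ds2) {
  for (ds in list(ds1, ds2))
    if (!length(ds$lcc_genes))
      stop("both datasets need a non-empty LCC gene set", call. = FALSE)
  top_snps <- function(ds, n) {
    s <- as.data.table(ds$snps)
    s[order(pvalue, snp_id), snp_id][seq_len(min(n, nrow(s)))]
  }
  top_genes <- function(ds, n) {
    s <- as.data.table(ds$scores)
    s[order(corrected_p, gene_id), gene_id][seq_len(min(n, nrow(s)))]
  }
  n1 <- length(ds1$lcc_genes); n2 <- length(ds2$lcc_genes)
  res <- rbind(
    jaccard(top_snps(ds1, n1), top_snps(ds2, n2), level = "snp"),
    jaccard(top_genes(ds1, n1), top_genes(ds2, n2), level = "gene"),
    jaccard(ds1$lcc_genes, ds2$lcc_genes, level = "lcc"))
  j <- setNames(res$jaccard, res$level)
  attr(res, "fold_change") <- c(
    lcc_vs_snp = if (j[["snp"]] > 0) j[["lcc"]] / j[["snp"]] else NA_real_,
    lcc_vs_gene = if (j[["gene"]] > 0) j[["lcc"]] / j[["gene"]] else NA_real_)
  res
}

#' Precision/recall table for the three benchmark selections
#'
#' Convenience wrapper producing the standard three-row benchmark table
#' (LCC genes, equal-count top genes, all genes at the cutoff).
#'
#' @inheritParams build_selections
#' @param candidates candidate gene list.
#' @return `data.frame` with one [precision_recall()] row per selection.
#' @export
evaluate_selections <- function(scores, lcc_genes, cutoff, candidates) {
  sels <- build_selections(scores, lcc_genes, cutoff)
  do.call(rbind, Map(function(s, lab) precision_recall(s, candidates, lab),
                     sels, names(sels)))
}
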