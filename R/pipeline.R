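# End-to-end orchestration: score -> project -> coherence scan -> LCC ->
# evaluation (-> optional cross-dataset overlap and specificity), with a
# reproducibility manifest.

#' Default pipeline configuration
#'
#' @param window_bp SNP-to-gene assignment window (bp).
#' @param cutoffs `-log10 P` grid for the coherence scan.
#' @param lcc_cutoff cutoff at which the LCC is extracted, or `"auto"` to
#'   pick the smallest scanned cutoff where all three coherence metrics
#'   (direct interactions, isolates, LCC size) have empirical p < 0.05.
#' @param n_perm random sets per cutoff.
#' @param seed integer seed.
#' @param null_universe `"all"` or `"mapped"` (see [coherence_scan()]).
#' @return named list of settings.
#' @export
pipeline_config <- function(window_bp = 10000L, cutoffs = seq(0.5, 5, 0.5),
                            lcc_cutoff = 1.0, n_perm = 1000L, seed = 1L,
                            null_universe = "all") {
  list(window_bp = window_bp, cutoffs = cutoffs, lcc_cutoff = lcc_cutoff,
       n_perm = n_perm, seed = seed, null_universe = null_universe)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_io("config file not found", path = config)
    config <- yaml::read_yaml(config)
  }
  cfg <- pipeline_config()
  cfg[names(config)] <- config
  if (is.character(cfg$cutoffs))
    cfg$cutoffs <- eval(parse(text = cfg$cutoffs))
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full network-GWAS pipeline on one dataset
#'
#' Executes gene scoring, network projection, the coherence scan, LCC
#' extraction at the configured cutoff and candidate-list evaluation, and
#' writes every stage output plus a JSON manifest (config snapshot, input
#' checksums, seed, package version, per-stage counts) to `out_dir`. Given
#' the same inputs and manifest, a re-run reproduces all outputs.
#'
#' @param snps SNP table ([read_association_table()]) or path to one.
#' @param genes gene annotation ([read_gene_annotation()]) or path.
#' @param map gene-protein map ([read_gene_map()]) or path.
#' @param net PPI network (`igraph`) or path to an edge list.
#' @param candidates candidate gene list (character) or path; optional.
#' @param config list from [pipeline_config()], partial list, or path to a
#'   YAML file with those fields.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing files.
#' @return list of class `netnoise_run`: `scores`, `scan`, `lcc_cutoff`,
#'   `selected` (selected_set at the LCC cutoff), `lcc_proteins`,
#'   `lcc_genes`, `evaluation` (or NULL), `manifest`.
#' @export
run_pipeline <- function(snps, genes, map, net, candidates = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  cfg <- .load_config(config)
  inputs <- list(snps = snps, genes = genes, map = map, net = net,
                 candidates = candidates)
  checksums <- lapply(inputs, function(x)
    if (is.character(x) && length(x) == 1L && file.exists(x))
      unname(tools::md5sum(x)) else NA_character_)
  snps <- .stage("read_snps", if (is.character(snps))
    read_association_table(snps) else as.data.table(snps))
  genes <- .stage("read_genes", if (is.character(genes))
    read_gene_annotation(genes) else as.data.table(genes))
  map <- .stage("read_map", if (is.character(map))
    read_gene_map(map) else as.data.table(map))
  net <- .stage("read_net", if (is.character(net)) read_edge_list(net) else net)
  if (is.character(candidates) && length(candidates) == 1L &&
      file.exists(candidates))
    candidates <- .stage("read_candidates", read_gene_list(candidates))

  scores <- .stage("gene_scoring",
                   gene_scores(snps, genes, window_bp = cfg$window_bp))
  scan <- .stage("coherence_scan",
                 coherence_scan(scores, map, net, cutoffs = cfg$cutoffs,
                                n_perm = cfg$n_perm, seed = cfg$seed,
                                null_universe = cfg$null_universe))
  lcc_cutoff <- cfg$lcc_cutoff
  if (identical(lcc_cutoff, "auto")) {
    ok <- scan$p_pct_direct < 0.05 & scan$p_pct_isolated < 0.05 &
      scan$p_lcc_size < 0.05
    if (!any(ok))
      stop("auto cutoff selection: no scanned cutoff has all three metrics ",
           "at empirical p < 0.05", call. = FALSE)
    lcc_cutoff <- scan$cutoff[which(ok)[1L]]
  }
  selected <- .stage("projection", {
    sel_genes <- select_genes(scores, lcc_cutoff)
    map_to_network(sel_genes, map, net, cutoff_neglogp = lcc_cutoff)
  })
  lcc <- .stage("lcc", lcc_proteins(net, selected$proteins))
  lcc_genes <- intersect(genes_for_proteins(lcc, map), selected$genes)
  evaluation <- NULL
  if (!is.null(candidates) && length(lcc_genes))
    evaluation <- .stage("evaluation",
                         evaluate_selections(scores, lcc_genes, lcc_cutoff,
                                             candidates))
  manifest <- list(
    package_version = as.character(utils::packageVersion("netnoise")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    config = cfg[c("window_bp", "lcc_cutoff", "n_perm", "null_universe")],
    cutoffs = cfg$cutoffs,
    input_md5 = checksums,
    counts = list(n_snps = nrow(snps), n_genes_annotated = nrow(genes),
                  n_genes_scored = nrow(scores),
                  n_network_proteins = igraph::vcount(net),
                  n_network_edges = igraph::ecount(net),
                  lcc_cutoff_used = lcc_cutoff,
                  n_selected_genes = length(selected$genes),
                  n_selected_proteins = length(selected$proteins),
                  lcc_size = length(lcc)))
  res <- structure(list(scores = scores, scan = scan,
                        lcc_cutoff = lcc_cutoff, selected = selected,
                        lcc_proteins = lcc, lcc_genes = lcc_genes,
                        evaluation = evaluation, manifest = manifest),
                   class = "netnoise_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(scores, file.path(out_dir, "gene_scores.tsv"))
    write_tsv(as.data.frame(scan), file.path(out_dir, "coherence_scan.tsv"))
    write_tsv(lcc, file.path(out_dir, "lcc_proteins.txt"))
    write_tsv(lcc_genes, file.path(out_dir, "lcc_genes.txt"))
    if (!is.null(evaluation))
      write_tsv(evaluation, file.path(out_dir, "evaluation.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.netnoise_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("netnoise pipeline run\n")
  cat(sprintf("  SNPs: %d   genes scored: %d   network: %d proteins / %d edges\n",
              cnt$n_snps, cnt$n_genes_scored, cnt$n_network_proteins,
              cnt$n_network_edges))
  cat(sprintf("  LCC at -log10P >= %g: %d proteins (%d genes) of %d selected\n",
              x$lcc_cutoff, cnt$lcc_size, length(x$lcc_genes),
              cnt$n_selected_proteins))
  if (!is.null(x$evaluation)) {
    cat("  evaluation vs candidate list:\n")
    print(x$evaluation, row.names = FALSE)
  }
  invisible(x)
}
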