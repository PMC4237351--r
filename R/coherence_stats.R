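# Functional-coherence statistics of a selected protein set on the PPI
# network, with empirical significance against equal-size random node sets.

#' Topology metrics of a selected protein set
#'
#' Computes, on the subgraph induced by the selected proteins:
#' * `pct_direct` — percentage of selected proteins with at least one edge
#'   to another selected protein;
#' * `pct_isolated` — percentage with no such edge (complement, the two
#'   always sum to 100);
#' * `edge_density` — within-set edge count divided by `choose(n, 2)`, a
#'   diagnostic pair-level variant of the direct-interaction reading;
#' * `lcc_size` — size of the largest connected component of the induced
#'   subgraph.
#'
#' @param net PPI network (`igraph`).
#' @param subset character vector of selected protein ids.
#' @return named list: `n_selected`, `pct_direct`, `pct_isolated`,
#'   `edge_density`, `lcc_size`.
#' @export
topology_metrics <- function(net, subset) {
  subset <- unique(as.character(subset))
  if (!length(subset)) {
    warning("empty protein subset: all topology metrics are 0")
    return(list(n_selected = 0L, pct_direct = 0, pct_isolated = 0,
                edge_density = 0, lcc_size = 0L))
  }
  stopifnot(all(subset %in% igraph::V(net)$name))
  sub <- igraph::induced_subgraph(net, subset)
  .metrics_from_subgraph(sub)
}

.metrics_from_subgraph <- function(sub) {
  n <- igraph::vcount(sub)
  deg <- igraph::degree(sub)
  n_isolated <- sum(deg == 0L)
  comp <- igraph::components(sub)
  list(n_selected = n,
       pct_direct = 100 * (n - n_isolated) / n,
       pct_isolated = 100 * n_isolated / n,
       edge_density = if (n >= 2L) igraph::ecount(sub) / choose(n, 2) else 0,
       lcc_size = as.integer(max(comp$csize)))
}

.metric_names <- c("pct_direct", "pct_isolated", "edge_density", "lcc_size")

# direction in which each metric is "more coherent than random"
.metric_directions <- c(pct_direct = "greater", pct_isolated = "smaller",
                        edge_density = "greater", lcc_size = "greater")

#' Null distribution of topology metrics from random protein sets
#'
#' Draws `n_perm` sets of `set_size` proteins (without replacement within
#' each set) and computes the topology metrics of each. Uniform sampling
#' over the chosen node universe is the default; degree-matched mode bins
#' the universe by degree decile and draws, within each bin, as many nodes
#' as the reference set contains — a robustness check against hub bias.
#'
#' @param net PPI network (`igraph`).
#' @param set_size size of each random set.
#' @param n_perm number of random sets (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param mode `"uniform"` (default) or `"degree_matched"`.
#' @param reference character vector of protein ids whose degree profile is
#'   matched (required for `degree_matched`).
#' @param universe optional character vector restricting the sampling
#'   universe (default: all network nodes).
#' @param keep_sets logical; retain the drawn node sets in attribute
#'   `sets` (default FALSE, they are large).
#' @return `data.frame` with `n_perm` rows and columns `pct_direct`,
#'   `pct_isolated`, `edge_density`, `lcc_size`.
#' @export
random_null <- function(net, set_size, n_perm = 1000L, seed = NULL,
                        mode = c("uniform", "degree_matched"),
                        reference = NULL, universe = NULL,
                        keep_sets = FALSE) {
  mode <- match.arg(mode)
  nodes <- universe %||% igraph::V(net)$name
  stopifnot(n_perm >= 1L, set_size >= 1L)
  if (set_size > length(nodes))
    stop("set_size exceeds the sampling universe", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "degree_matched") {
    if (is.null(reference))
      stop("degree_matched mode needs a reference protein set", call. = FALSE)
    deg <- igraph::degree(net, v = nodes)
    brk <- unique(quantile(deg, probs = seq(0, 1, 0.1)))
    bin <- cut(deg, breaks = brk, include.lowest = TRUE)
    ref_bin <- cut(igraph::degree(net, v = reference), breaks = brk,
                   include.lowest = TRUE)
    need <- table(ref_bin)
    pool <- split(nodes, bin)
    draw <- function() {
      unlist(lapply(names(need), function(b) {
        k <- need[[b]]
        if (k == 0L) return(character())
        sample(pool[[b]], k)
      }), use.names = FALSE)
    }
  } else {
    draw <- function() sample(nodes, set_size)
  }
  rows <- vector("list", n_perm)
  sets <- if (keep_sets) vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    s <- draw()
    if (keep_sets) sets[[i]] <- s
    m <- topology_metrics(net, s)
    rows[[i]] <- m[.metric_names]
  }
  out <- as.data.frame(do.call(rbind, lapply(rows, unlist)))
  names(out) <- .metric_names
  if (keep_sets) attr(out, "sets") <- sets
  out
}

#' Empirical p-value of an observed statistic against a null sample
#'
#' Uses the add-one estimator `p = (1 + r) / (n + 1)` where `r` counts null
#' values at least as extreme as the observed one (`>=` for
#' `direction = "greater"`, `<=` for `"smaller"`). Ties count as extreme,
#' the estimate is never zero, and its floor is `1/(n_perm + 1)`.
#'
#' @param observed observed metric value (scalar).
#' @param null numeric vector of null samples (non-empty).
#' @param direction `"greater"` when large values mean coherence,
#'   `"smaller"` for the isolated-node metric.
#' @return empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, null, direction = c("greater", "smaller")) {
  direction <- match.arg(direction)
  stopifnot(length(null) >= 1L, length(observed) == 1L)
  r <- if (direction == "greater") sum(null >= observed) else sum(null <= observed)
  (1 + r) / (length(null) + 1)
}

#' Coherence scan over gene-wise significance cutoffs
#'
#' For each cutoff (ascending), selects genes at that `-log10 P`, maps them
#' to network proteins, computes the observed topology metrics, draws
#' `n_perm` equal-size random protein sets and reports the empirical
#' p-value of every metric. The scan stops at the first cutoff with an
#' empty protein selection. The default grid 0.5–5.0 in steps of 0.5
#' covers the sub-threshold range where statistical "noise" may still
#' carry functionally coherent signal.
#'
#' @param scores gene score table from [gene_scores()].
#' @param map gene-protein map.
#' @param net PPI network (`igraph`).
#' @param cutoffs ascending numeric vector of `-log10 P` cutoffs.
#' @param n_perm random sets per cutoff (default 1000).
#' @param seed optional integer seed.
#' @param mode null sampling mode, see [random_null()].
#' @param null_universe `"all"` (default; all network proteins) or
#'   `"mapped"` (only proteins mapped by any scored gene).
#' @return object of class `coherence_scan`: a `data.frame` with one row
#'   per evaluated cutoff (columns: cutoff, n_genes, n_selected, each
#'   observed metric, null mean/sd/quartiles of each metric, and
#'   `p_<metric>` empirical p-values), with the per-cutoff null samples in
#'   attribute `null_samples`.
#' @export
coherence_scan <- function(scores, map, net, cutoffs = seq(0.5, 5, by = 0.5),
                           n_perm = 1000L, seed = NULL,
                           mode = c("uniform", "degree_matched"),
                           null_universe = c("all", "mapped")) {
  mode <- match.arg(mode)
  null_universe <- match.arg(null_universe)
  stopifnot(!is.unsorted(cutoffs))
  if (!is.null(seed)) set.seed(seed)
  map <- as.data.table(map)
  universe <- if (null_universe == "mapped")
    intersect(unique(map[gene_id %in% scores$gene_id, protein_id]),
              igraph::V(net)$name)
  else igraph::V(net)$name
  rows <- list()
  nulls <- list()
  for (ct in cutoffs) {
    sel <- select_genes(scores, ct)
    ss <- map_to_network(sel, map, net, cutoff_neglogp = ct)
    if (!length(ss$proteins)) break
    obs <- topology_metrics(net, ss$proteins)
    nul <- random_null(net, set_size = length(ss$proteins), n_perm = n_perm,
                       mode = mode, reference = ss$proteins,
                       universe = universe)
    ps <- vapply(.metric_names, function(m)
      empirical_p(obs[[m]], nul[[m]], .metric_directions[[m]]), numeric(1))
    summ <- unlist(lapply(.metric_names, function(m) {
      q <- quantile(nul[[m]], c(0.25, 0.5, 0.75), names = FALSE)
      setNames(c(mean(nul[[m]]), stats::sd(nul[[m]]), q),
               paste0("null_", m, c("_mean", "_sd", "_q25", "_q50", "_q75")))
    }))
    rows[[length(rows) + 1L]] <- data.frame(
      cutoff = ct, n_genes = length(sel), n_selected = obs$n_selected,
      as.data.frame(obs[.metric_names]),
      as.data.frame(as.list(summ)),
      as.data.frame(as.list(setNames(ps, paste0("p_", .metric_names)))))
    nulls[[as.character(ct)]] <- nul
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cutoff = numeric(0))
  attr(out, "null_samples") <- nulls
  class(out) <- c("coherence_scan", class(out))
  out
}
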