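# Independent brute-force oracles used to cross-check the igraph-backed
# implementation. Deliberately naive: adjacency lists + BFS, hand tallies.

# adjacency list from a 2-column character edge matrix, restricted to `nodes`
bf_adjacency <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    keep <- edges[, 1] %in% nodes & edges[, 2] %in% nodes &
      edges[, 1] != edges[, 2]
    for (i in which(keep)) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# connected components by breadth-first search over the induced subgraph
bf_components <- function(edges, subset) {
  adj <- bf_adjacency(edges, subset)
  unvisited <- subset
  comps <- list()
  while (length(unvisited)) {
    queue <- unvisited[1]
    comp <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unvisited <- setdiff(unvisited, comp)
  }
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, `[`, character(1), 1))
  comps[ord]
}

# hand-tallied topology metrics on the induced subgraph
bf_metrics <- function(edges, subset) {
  adj <- bf_adjacency(edges, subset)
  n <- length(subset)
  deg <- vapply(subset, function(v) length(adj[[v]]), integer(1))
  n_edges <- sum(deg) / 2
  comps <- bf_components(edges, subset)
  list(n_selected = n,
       pct_direct = 100 * sum(deg > 0) / n,
       pct_isolated = 100 * sum(deg == 0) / n,
       edge_density = if (n >= 2) n_edges / choose(n, 2) else 0,
       lcc_size = if (length(comps)) length(comps[[1]]) else 0L)
}

# random simple graph as an edge matrix + node vector (for oracle tests)
random_test_graph <- function(n, p = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

graph_from_edge_matrix <- function(edges, nodes) {
  ppi_from_edges(edges[, 1], edges[, 2], nodes = nodes)
}
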