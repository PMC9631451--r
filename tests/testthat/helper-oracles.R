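# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by enumeration rather than calling package internals.

# All simple paths between u and t in an adjacency list with edge costs
# (list keyed by node, each a named numeric vector of neighbour costs).
enumerate_simple_paths <- function(adj, u, t) {
  paths <- list()
  walk <- function(path, cost) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1L]] <<- list(path = path, cost = cost)
      return()
    }
    for (nb in names(adj[[last]])) {
      if (!nb %in% path) walk(c(path, nb), cost + adj[[last]][[nb]])
    }
  }
  if (u %in% names(adj)) walk(u, 0)
  paths
}

brute_min_cost <- function(adj, u, t) {
  p <- enumerate_simple_paths(adj, u, t)
  if (!length(p)) return(list(cost = Inf, paths = list()))
  costs <- vapply(p, `[[`, numeric(1), "cost")
  best <- min(costs)
  list(cost = best,
       paths = lapply(p[abs(costs - best) < 1e-9], `[[`, "path"))
}

# Random undirected weighted graph as an adjacency list + edge data frame.
random_weighted_graph <- function(n_nodes, p_edge = 0.45, costs = NULL) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (is.null(costs)) costs <- round(runif(nrow(pairs), 0.05, 1), 3)
  adj <- setNames(lapply(nodes, function(x) numeric(0)), nodes)
  for (k in seq_len(nrow(pairs))) {
    adj[[pairs[k, 1]]][pairs[k, 2]] <- costs[k]
    adj[[pairs[k, 2]]][pairs[k, 1]] <- costs[k]
  }
  list(nodes = nodes,
       edges = data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                          cost = costs, stringsAsFactors = FALSE),
       adj = adj)
}

# Exhaustive normalized betweenness on an unweighted undirected graph:
# fraction of shortest s-t paths through each interior node, summed over
# pairs, normalized by (n-1)(n-2)/2.
brute_betweenness <- function(edges, nodes) {
  adj <- setNames(lapply(nodes, function(x) numeric(0)), nodes)
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]][edges[k, 2]] <- 1
    adj[[edges[k, 2]]][edges[k, 1]] <- 1
  }
  b <- setNames(rep(0, length(nodes)), nodes)
  prs <- t(combn(nodes, 2))
  for (k in seq_len(nrow(prs))) {
    res <- brute_min_cost(adj, prs[k, 1], prs[k, 2])
    if (!is.finite(res$cost) || !length(res$paths)) next
    # unit costs: minimal cost = minimal hop count
    through <- table(unlist(lapply(res$paths, function(p) p[-c(1, length(p))])))
    if (length(through)) {
      b[names(through)] <- b[names(through)] + through / length(res$paths)
    }
  }
  n <- length(nodes)
  b / ((n - 1) * (n - 2) / 2)
}

# Random bipartite component-target edge list.
random_bipartite <- function(n_comp, n_tgt, p = 0.3) {
  comps <- sprintf("C%02d", seq_len(n_comp))
  tgts <- sprintf("T%02d", seq_len(n_tgt))
  grid <- expand.grid(component = comps, target = tgts,
                      stringsAsFactors = FALSE)
  grid[runif(nrow(grid)) < p, , drop = FALSE]
}

# Symbolic expansion of the chain score for prescribed step correlations,
# a shortcut-correlation lookup, and label positions (independent of
# score_chain's partial-product bookkeeping).
expand_chain_score <- function(v0, s, shortcut_cor, tox_pos = NA, jqc_pos = NA) {
  n <- length(s) + 1
  v1 <- v0 * prod(s)
  seg <- function(pos) v0 * prod(s[seq_len(pos - 1)])
  v2 <- if (is.na(tox_pos)) 0 else {
    seg(tox_pos) * (if (tox_pos == n) 1 else shortcut_cor(tox_pos))
  }
  v3 <- if (is.na(jqc_pos)) 0 else {
    seg(jqc_pos) * (if (jqc_pos == n) 1 else shortcut_cor(jqc_pos))
  }
  list(v1 = v1, v2 = v2, v3 = v3, v = v1 - v2 + v3)
}
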