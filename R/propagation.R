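#' Gene-gene correlation store
#'
#' Precomputes the symmetric correlation matrix of a gene x sample
#' expression matrix (Pearson by default, pairwise-complete samples).
#' Genes whose expression is constant get correlation 0 to every other
#' gene, with a warning (the correlation is undefined). Lookups for genes
#' absent from the store return 0.
#'
#' @param expr numeric gene x sample matrix with gene row names.
#' @param method correlation method passed to [stats::cor()].
#' @param transform `"log2"` (log2(x+1)) or `"none"`.
#' @return An object of class `cor_store`.
#' @export
correlation_store <- function(expr, method = c("pearson", "spearman", "kendall"),
                              transform = c("log2", "none")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs gene row names")
  if (ncol(expr) < 3) stop("need at least 3 samples to estimate correlations")
  if (transform == "log2") {
    if (any(expr < 0, na.rm = TRUE)) stop("log2 transform requires nonnegative expression")
    expr <- log2(expr + 1)
  }
  sds <- apply(expr, 1, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const)) {
    warning(sum(const), " gene(s) have constant expression; their correlations are set to 0")
  }
  suppressWarnings(
    m <- stats::cor(t(expr), method = method, use = "pairwise.complete.obs")
  )
  m[is.na(m)] <- 0
  diag(m) <- 1
  structure(list(cor = m, method = method), class = "cor_store")
}

#' @export
print.cor_store <- function(x, ...) {
  cat(sprintf("Correlation store: %d genes (%s)\n", nrow(x$cor), x$method))
  invisible(x)
}

#' Look up a pairwise correlation
#'
#' @param store a `cor_store`.
#' @param i,j gene symbols (vectorized; recycled to common length).
#' @return Numeric vector of correlations in [-1, 1]; 0 for unknown pairs.
#' @export
get_cor <- function(store, i, j) {
  stopifnot(inherits(store, "cor_store"))
  n <- max(length(i), length(j))
  i <- rep_len(as.character(i), n)
  j <- rep_len(as.character(j), n)
  out <- numeric(n)
  known <- i %in% rownames(store$cor) & j %in% rownames(store$cor)
  if (any(known)) out[known] <- store$cor[cbind(i[known], j[known])]
  out[i == j] <- 1
  out
}

#' Build the weighted propagation graph over a PPI network
#'
#' Converts an undirected protein-protein interaction edge list into the
#' weighted graph the chain search runs on. In `"correlation"` mode the
#' cost of edge (u, x) is `max(1 - |s_ux|, eps)` where `s_ux` is the genes'
#' expression correlation: strongly co-expressed neighbours are cheap to
#' traverse, and the clamp keeps all costs strictly positive as Dijkstra
#' requires. Unknown correlations give cost 1. In `"hop"` mode every edge
#' costs 1 and shortest paths reduce to breadth-first (fewest-hop) paths.
#' Self-loops are dropped with a warning; duplicate edges keep the minimum
#' cost.
#'
#' @param ppi data frame or 2-column matrix of gene symbol pairs (an
#'   optional third column is ignored in cost construction).
#' @param cor a [correlation_store()]; may be `NULL` in hop mode.
#' @param mode `"correlation"` (default) or `"hop"`.
#' @param eps positive clamp for correlation-mode costs.
#' @return An object of class `gene_graph`: adjacency list keyed by gene
#'   with per-neighbour costs, plus `nodes` and `mode`.
#' @export
build_weighted_graph <- function(ppi, cor = NULL,
                                 mode = c("correlation", "hop"), eps = 1e-6) {
  mode <- match.arg(mode)
  if (is.matrix(ppi)) ppi <- as.data.frame(ppi, stringsAsFactors = FALSE)
  u <- as.character(ppi[[1]])
  v <- as.character(ppi[[2]])
  loops <- u == v
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    u <- u[!loops]; v <- v[!loops]
  }
  if (mode == "correlation") {
    if (is.null(cor)) stop("correlation mode needs a correlation store")
    s <- get_cor(cor, u, v)
    cost <- pmax(1 - abs(s), eps)
  } else {
    cost <- rep(1, length(u))
  }
  # canonical undirected key; duplicates keep minimum cost
  a <- pmin(u, v); b <- pmax(u, v)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  if (any(!keep)) {
    cost <- as.numeric(tapply(cost, key, min)[key[keep]])
    a <- a[keep]; b <- b[keep]
  } else {
    cost <- unname(cost[keep])
  }
  nodes <- sort(unique(c(a, b)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(a)) {
    adj[[a[k]]][[b[k]]] <- cost[k]
    adj[[b[k]]][[a[k]]] <- cost[k]
  }
  adj <- lapply(adj, function(x) {
    if (is.null(x)) numeric(0) else unlist(x)[order(names(unlist(x)))]
  })
  structure(list(adj = adj, nodes = nodes, mode = mode, eps = eps),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$adj)) / 2
  cat(sprintf("Weighted gene graph: %d nodes, %d edges (mode: %s)\n",
              length(x$nodes), n_edges, x$mode))
  invisible(x)
}

# Dijkstra from a single source with deterministic tie-breaking:
# equal-distance frontier nodes are settled in lexicographic order, and an
# equal-cost predecessor is replaced only by a lexicographically smaller
# one. Returns distances and predecessor labels.
.dijkstra <- function(graph, source) {
  nodes <- graph$nodes
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  pred <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  settled <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  dist[source] <- 0
  repeat {
    open <- !settled & is.finite(dist)
    if (!any(open)) break
    cand <- names(dist)[open]
    dmin <- min(dist[cand])
    t <- min(cand[dist[cand] == dmin])   # lexicographic tie-break
    settled[t] <- TRUE
    nb <- graph$adj[[t]]
    for (x in names(nb)) {
      if (settled[x]) next
      alt <- dist[t] + nb[[x]]
      if (alt < dist[x] || (alt == dist[x] && !is.na(pred[x]) && t < pred[x])) {
        dist[x] <- alt
        pred[x] <- t
      }
    }
  }
  list(dist = dist, pred = pred)
}

.trace_path <- function(pred, source, sink) {
  path <- sink
  while (path[1] != source) {
    p <- pred[path[1]]
    if (is.na(p)) return(NULL)
    path <- c(p, path)
  }
  path
}

#' Enumerate shortest gene transmission chains
#'
#' For every (source, sink) pair with finite shortest-path distance,
#' returns exactly one minimal-cost simple path through the weighted gene
#' graph, found by Dijkstra's algorithm with deterministic lexicographic
#' tie-breaking (both in the order equal-distance nodes are settled and in
#' predecessor choice), reconstructed by predecessor tracking. Sources are
#' component targets of the primary herb; sinks are pathogenic genes.
#' Unreachable pairs are omitted; source/sink genes absent from the graph
#' are skipped with a warning.
#'
#' @param graph a [build_weighted_graph()] result.
#' @param sources,sinks character vectors of gene symbols.
#' @return List of `gene_chain` objects (see [gene_chain()]); each carries
#'   attributes `cost` (total path cost) and unlabeled nodes.
#' @export
shortest_chains <- function(graph, sources, sinks) {
  stopifnot(inherits(graph, "gene_graph"))
  sources <- unique(as.character(sources))
  sinks <- unique(as.character(sinks))
  miss <- setdiff(c(sources, sinks), graph$nodes)
  if (length(miss)) {
    warning(length(miss), " source/sink gene(s) not in graph, skipped: ",
            paste(utils::head(sort(miss), 5), collapse = ", "),
            if (length(miss) > 5) ", ..." else "")
  }
  sources <- sort(intersect(sources, graph$nodes))
  sinks <- sort(intersect(sinks, graph$nodes))
  chains <- list()
  for (u in sources) {
    dj <- .dijkstra(graph, u)
    for (t in sinks) {
      if (t == u || !is.finite(dj$dist[t])) next
      path <- .trace_path(dj$pred, u, t)
      if (is.null(path)) next
      ch <- gene_chain(path)
      attr(ch, "cost") <- unname(dj$dist[t])
      chains[[length(chains) + 1L]] <- ch
    }
  }
  chains
}

#' All-pairs shortest distances from a set of sources
#'
#' Convenience wrapper exposing the distances (not the paths) computed by
#' the same deterministic Dijkstra used by [shortest_chains()].
#'
#' @param graph a `gene_graph`.
#' @param sources character vector of source genes (must be in the graph).
#' @return Numeric matrix, one row per source, one column per graph node.
#' @export
chain_distances <- function(graph, sources) {
  stopifnot(inherits(graph, "gene_graph"))
  sources <- as.character(sources)
  stopifnot(all(sources %in% graph$nodes))
  out <- t(vapply(sources, function(u) .dijkstra(graph, u)$dist,
                  numeric(length(graph$nodes))))
  rownames(out) <- sources
  out
}

#' Read a PPI edge list
#'
#' Accepts a TSV (`geneA`, `geneB`, optional `weight`) or a SIF file
#' (`geneA <relation> geneB`).
#'
#' @param path input file.
#' @param format `"tsv"` or `"sif"`.
#' @return Data frame with columns `geneA`, `geneB` (and `weight` if
#'   present).
#' @export
read_ppi <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(x)[1:2] <- c("geneA", "geneB")
    x
  } else {
    lines <- readLines(path)
    parts <- strsplit(lines[nzchar(lines)], "\t")
    keep <- lengths(parts) >= 3
    data.frame(geneA = vapply(parts[keep], `[`, character(1), 1),
               geneB = vapply(parts[keep], `[`, character(1), 3),
               stringsAsFactors = FALSE)
  }
}
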