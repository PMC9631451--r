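#' Build a bipartite component-target network
#'
#' Constructs the component-target (C-T) network linking herb constituents
#' to the genes/proteins they act on. Edges are deduplicated; every edge
#' component must appear in the supplied component list. Edges may carry an
#' initial influence coefficient `a >= 0` (see [influence_coefficients()]),
#' stored as an edge attribute.
#'
#' @param edges data frame (or 2/3-column matrix) with columns
#'   `component`, `target` and optionally `a`.
#' @param components component data frame or character vector of component
#'   ids; used to validate edge endpoints and to record isolated components.
#' @return An object of class `ct_network`: a list with `components`,
#'   `targets` (sorted character vectors), `edges` (data frame
#'   `component, target, a`), and `summary`.
#' @export
ct_network <- function(edges, components) {
  comp_ids <- if (is.data.frame(components)) as.character(components$id) else as.character(components)
  comp_ids <- unique(comp_ids)
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(component = character(0), target = character(0),
                        a = numeric(0), stringsAsFactors = FALSE)
  } else {
    if (!all(c("component", "target") %in% names(edges))) {
      names(edges)[1:2] <- c("component", "target")
    }
    edges$component <- as.character(edges$component)
    edges$target <- as.character(edges$target)
    if (is.null(edges$a)) edges$a <- NA_real_ else edges$a <- as.numeric(edges$a)
    unknown <- setdiff(edges$component, comp_ids)
    if (length(unknown)) {
      stop("edge references unknown component(s): ",
           paste(unknown, collapse = ", "))
    }
    edges <- edges[!duplicated(edges[c("component", "target")]),
                   c("component", "target", "a")]
    edges <- edges[order(edges$component, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  targets <- sort(unique(edges$target))
  comp_deg <- table(factor(edges$component, levels = sort(comp_ids)))
  tgt_deg <- table(factor(edges$target, levels = targets))
  net <- list(
    components = sort(comp_ids),
    targets = targets,
    edges = edges,
    summary = list(
      n_components = length(comp_ids),
      n_targets = length(targets),
      n_edges = nrow(edges),
      mean_targets_per_component = if (length(comp_ids)) nrow(edges) / length(comp_ids) else 0,
      mean_components_per_target = if (length(targets)) nrow(edges) / length(targets) else 0,
      component_degree = as.integer(comp_deg),
      target_degree = as.integer(tgt_deg)
    )
  )
  structure(net, class = "ct_network")
}

#' @export
print.ct_network <- function(x, ...) {
  s <- x$summary
  cat("Component-target network\n")
  cat(sprintf("  components: %d   targets: %d   edges: %d\n",
              s$n_components, s$n_targets, s$n_edges))
  cat(sprintf("  mean targets/component: %.2f   mean components/target: %.2f\n",
              s$mean_targets_per_component, s$mean_components_per_target))
  if (any(!is.na(x$edges$a))) cat("  influence coefficients: attached\n")
  invisible(x)
}

#' Targets of a component
#'
#' @param net a `ct_network`.
#' @param component component id.
#' @return Character vector of target gene symbols.
#' @export
ct_targets <- function(net, component) {
  stopifnot(inherits(net, "ct_network"))
  net$edges$target[net$edges$component == component]
}

.ct_igraph <- function(net) {
  nodes <- c(net$components, net$targets)
  g <- igraph::graph_from_data_frame(
    net$edges[c("component", "target")], directed = FALSE,
    vertices = data.frame(name = nodes,
                          type = c(rep(TRUE, length(net$components)),
                                   rep(FALSE, length(net$targets))),
                          stringsAsFactors = FALSE))
  if (nrow(net$edges)) igraph::E(g)$a <- net$edges$a
  g
}

#' Normalized betweenness centrality on the C-T network
#'
#' Shortest-path betweenness computed on the full undirected bipartite
#' graph with unit edge lengths, normalized by (n-1)(n-2)/2 for n total
#' nodes, so values lie in [0, 1]. Degree-1 nodes (and all nodes of a
#' singleton network) have betweenness 0.
#'
#' @param net a `ct_network`.
#' @param nodes `"components"` (default), `"targets"` or `"all"`.
#' @return Named numeric vector of betweenness values.
#' @export
component_betweenness <- function(net, nodes = c("components", "targets", "all")) {
  stopifnot(inherits(net, "ct_network"))
  nodes <- match.arg(nodes)
  all_nodes <- c(net$components, net$targets)
  if (length(all_nodes) == 0) stop("empty network")
  b <- stats::setNames(rep(0, length(all_nodes)), all_nodes)
  if (length(all_nodes) > 2 && nrow(net$edges) > 0) {
    g <- .ct_igraph(net)
    raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    n <- length(all_nodes)
    b[names(raw)] <- raw / ((n - 1) * (n - 2) / 2)
  }
  switch(nodes,
         components = b[net$components],
         targets = b[net$targets],
         all = b)
}

#' Export a C-T network to SIF, GraphML or TSV
#'
#' TSV and GraphML carry the influence coefficient `a`; SIF is the plain
#' Cytoscape interaction format `component ct target` and records edges
#' only.
#'
#' @param net a `ct_network`.
#' @param path output file.
#' @param format `"tsv"`, `"sif"` or `"graphml"` (case-insensitive).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "ct_network"))
  format <- tolower(format[1])
  if (!format %in% c("tsv", "sif", "graphml")) {
    stop("unknown format '", format, "'; supported: tsv, sif, graphml")
  }
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    lines <- sprintf("%s\tct\t%s", net$edges$component, net$edges$target)
    iso_c <- setdiff(net$components, net$edges$component)
    iso_t <- setdiff(net$targets, net$edges$target)
    writeLines(c(lines, iso_c, iso_t), path)
  } else {
    igraph::write_graph(.ct_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a C-T network written by [export_network()]
#'
#' @param path input file.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return A `ct_network`.
#' @export
read_network <- function(path, format = c("tsv", "sif", "graphml")) {
  format <- tolower(format[1])
  if (format == "tsv") {
    e <- utils::read.delim(path, stringsAsFactors = FALSE)
    ct_network(e, unique(e$component))
  } else if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t")
    is_edge <- lengths(parts) == 3
    comp <- vapply(parts[is_edge], `[`, character(1), 1)
    tgt <- vapply(parts[is_edge], `[`, character(1), 3)
    iso <- unlist(parts[!is_edge])
    edges <- data.frame(component = comp, target = tgt,
                        stringsAsFactors = FALSE)
    comps <- unique(c(comp, setdiff(iso, tgt)))
    ct_network(edges, comps)
  } else if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vt <- igraph::V(g)$type
    vn <- igraph::V(g)$name
    el <- igraph::as_edgelist(g)
    # orient each edge component -> target using the bipartite type flag
    comp_first <- vt[match(el[, 1], vn)]
    edges <- data.frame(component = ifelse(comp_first, el[, 1], el[, 2]),
                        target = ifelse(comp_first, el[, 2], el[, 1]),
                        stringsAsFactors = FALSE)
    ea <- igraph::edge_attr(g, "a")
    if (!is.null(ea)) edges$a <- as.numeric(ea)
    ct_network(edges, vn[vt])
  } else {
    stop("unknown format '", format, "'; supported: tsv, sif, graphml")
  }
}
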