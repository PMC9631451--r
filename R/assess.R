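#' Coverage of a reference gene set by a query set
#'
#' `coverage = |query ∩ reference| / |reference|`: the fraction of the
#' reference genes recovered by the query.
#'
#' @param query,reference character vectors of gene symbols (reference must
#'   be non-empty).
#' @param query_name,reference_name labels for reporting.
#' @return An object of class `coverage_report`: list with set sizes,
#'   `intersection` and `coverage` in [0, 1].
#' @export
coverage <- function(query, reference, query_name = "query",
                     reference_name = "reference") {
  query <- unique(as.character(query))
  reference <- unique(as.character(reference))
  if (length(reference) == 0) stop("reference gene set is empty")
  inter <- length(intersect(query, reference))
  structure(list(query_name = query_name, query_size = length(query),
                 reference_name = reference_name,
                 reference_size = length(reference),
                 intersection = inter,
                 coverage = inter / length(reference)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage of %s (%d genes) by %s (%d genes): %d/%d = %.1f%%\n",
              x$reference_name, x$reference_size, x$query_name, x$query_size,
              x$intersection, x$reference_size, 100 * x$coverage))
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' One-sided tail test of gene-set overlap: given a query of size q drawn
#' from a universe of size N containing a gene set of size m, the p-value
#' is P(X >= overlap) for X hypergeometric(m, N - m, q). With a list of
#' gene sets, p-values are Benjamini-Hochberg adjusted across the list.
#'
#' @param query character vector (must be a subset of `universe`).
#' @param genesets a character vector (one set) or named list of character
#'   vectors; each must be a subset of `universe`.
#' @param universe character vector of all considered genes.
#' @return Data frame `geneset, set_size, overlap, expected, p, p_adj`.
#' @export
ora_hypergeometric <- function(query, genesets, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  bad <- setdiff(query, universe)
  if (length(bad)) {
    stop("query genes outside the universe: ", paste(bad, collapse = ", "))
  }
  if (!is.list(genesets)) genesets <- list(geneset = genesets)
  if (is.null(names(genesets))) {
    names(genesets) <- paste0("set", seq_along(genesets))
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(genesets), function(nm) {
    gs <- unique(as.character(genesets[[nm]]))
    bad <- setdiff(gs, universe)
    if (length(bad)) {
      stop("gene set '", nm, "' has genes outside the universe: ",
           paste(bad, collapse = ", "))
    }
    m <- length(gs)
    k <- length(intersect(query, gs))
    # P(X >= k); phyper's upper tail is strict, hence k - 1
    p <- stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(geneset = nm, set_size = m, overlap = k,
               expected = q * m / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Read gene sets from GMT or newline-delimited text
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Plain text: one gene per line, returned as a single unnamed set.
#'
#' @param path input file.
#' @param format `"gmt"` or `"txt"`.
#' @return Named list of character vectors (`"txt"`: list of length 1).
#' @export
read_gene_sets <- function(path, format = c("gmt", "txt")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "txt") {
    return(stats::setNames(list(trimws(lines)),
                           tools::file_path_sans_ext(basename(path))))
  }
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, character(1), 1))
}
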