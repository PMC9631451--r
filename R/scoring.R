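#' Construct a gene transmission chain
#'
#' An ordered simple path of gene symbols from a component target of the
#' primary herb, through PPI intermediates, to a pathogenic gene. Each node
#' may carry labels: `"JQC"` marks a target of the helper herb, `"TOX"` a
#' toxic target of the primary herb.
#'
#' @param genes character vector of gene symbols (no repeats).
#' @param labels optional list of character vectors (subsets of
#'   `c("JQC", "TOX")`), one per gene; default no labels.
#' @return An object of class `gene_chain`.
#' @export
gene_chain <- function(genes, labels = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("a gene transmission chain must be a simple path")
  if (is.null(labels)) labels <- rep(list(character(0)), length(genes))
  if (length(labels) != length(genes)) stop("one label set per gene required")
  labels <- lapply(labels, function(l) {
    l <- unique(as.character(l))
    bad <- setdiff(l, c("JQC", "TOX"))
    if (length(bad)) stop("unknown chain label(s): ", paste(bad, collapse = ", "))
    # canonical order matches the worked-example notation [TOX][JQC]
    intersect(c("TOX", "JQC"), l)
  })
  structure(list(genes = genes, labels = labels), class = "gene_chain")
}

#' Annotate a chain with helper-herb and toxic-target labels
#'
#' Every node found in `jqc_targets` gains the `JQC` label, every node in
#' `tox_targets` the `TOX` label; the sets may overlap, in which case a
#' node carries both.
#'
#' @param chain a `gene_chain`.
#' @param jqc_targets,tox_targets character vectors of gene symbols.
#' @return The labeled `gene_chain`.
#' @export
annotate_labels <- function(chain, jqc_targets = character(0),
                            tox_targets = character(0)) {
  stopifnot(inherits(chain, "gene_chain"))
  labels <- lapply(seq_along(chain$genes), function(i) {
    l <- chain$labels[[i]]
    g <- chain$genes[i]
    if (g %in% tox_targets) l <- c(l, "TOX")
    if (g %in% jqc_targets) l <- c(l, "JQC")
    unique(l)
  })
  gene_chain(chain$genes, labels)
}

#' Format a chain in the bracketed-label notation
#'
#' @param chain a `gene_chain`.
#' @param space put a space before the first label bracket (the notation
#'   used in the packaged worked-example table), default `TRUE`.
#' @return A string such as `"DHCR24 [JQC]-UBC-CFL1"`.
#' @export
format_chain <- function(chain, space = TRUE) {
  stopifnot(inherits(chain, "gene_chain"))
  sep <- if (space) " " else ""
  toks <- vapply(seq_along(chain$genes), function(i) {
    l <- chain$labels[[i]]
    if (length(l)) paste0(chain$genes[i], sep, paste0("[", l, "]", collapse = ""))
    else chain$genes[i]
  }, character(1))
  paste(toks, collapse = "-")
}

#' @export
print.gene_chain <- function(x, ...) {
  cat(format_chain(x), "\n")
  invisible(x)
}

#' Parse a bracketed-label chain string
#'
#' Inverse of [format_chain()]: accepts node tokens separated by `-`, each
#' a gene symbol optionally followed by label brackets, with or without a
#' space before them (e.g. `"DHCR24 [JQC]-MDM2 [TOX][JQC]-MTOR"`).
#'
#' @param text chain string.
#' @return A `gene_chain`.
#' @export
parse_chain <- function(text) {
  toks <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  genes <- character(length(toks))
  labels <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    m <- regmatches(toks[i], gregexpr("\\[[A-Z]+\\]", toks[i]))[[1]]
    labels[[i]] <- gsub("\\[|\\]", "", m)
    genes[i] <- trimws(gsub("\\[[A-Z]+\\]", "", toks[i]))
  }
  gene_chain(genes, labels)
}

.first_label_pos <- function(chain, label) {
  hit <- vapply(chain$labels, function(l) label %in% l, logical(1))
  if (any(hit)) which(hit)[1] else NA_integer_
}

#' Score a gene transmission chain
#'
#' Implements the multiplicative propagation score. Writing s_k for the
#' correlation between consecutive chain genes k and k+1:
#' \itemize{
#' \item `v0`: initial value, the sum of initial influence coefficients `a`
#'   over all component edges onto the first gene (or supplied directly);
#' \item `v1 = v0 * prod(s_k)`: fully propagated ("spread") value;
#'   `loss = v0 - v1`;
#' \item `v2`: toxicity-truncated value. With X the FIRST `TOX`-labeled
#'   node, `tox_begin` is the partial product of v0 and the step
#'   correlations up to X, and `v2 = tox_fin = tox_begin * s(X, terminal)`
#'   where the shortcut correlation from a terminal labeled node to itself
#'   is 1. No `TOX` label: `v2 = tox_begin = tox_fin = 0`;
#' \item `v3`: helper-shortcut value, identically with the FIRST
#'   `JQC`-labeled node J: `jqc_begin` up to J,
#'   `v3 = jqc_fin = jqc_begin * s(J, terminal)`;
#' \item `v = v1 - v2 + v3`: final score. Later toxic nodes are penalized
#'   less; earlier helper nodes reward more.
#' }
#' Correlations are signed; set `abs_cor = TRUE` to propagate absolute
#' values instead.
#'
#' @param chain an annotated `gene_chain` of length >= 2.
#' @param influence data frame `component, target, a` (see
#'   [influence_coefficients()]); used to compute v0. Ignored when `v0` is
#'   given.
#' @param cor a [correlation_store()] supplying both step correlations and
#'   the shortcut correlations to the terminal gene.
#' @param v0 optionally, the initial value directly.
#' @param abs_cor propagate `|s|` instead of signed s.
#' @return An object of class `chain_score`: list with the chain and the
#'   numeric fields `v0, v1, v2, v3, v, loss, tox_begin, tox_fin,
#'   jqc_begin, jqc_fin`.
#' @export
score_chain <- function(chain, influence = NULL, cor = NULL, v0 = NULL,
                        abs_cor = FALSE) {
  stopifnot(inherits(chain, "gene_chain"))
  n <- length(chain$genes)
  if (n < 2) stop("chain must have at least 2 nodes")
  if (is.null(v0)) {
    if (is.null(influence)) stop("supply either v0 or an influence table")
    v0 <- sum(influence$a[influence$target == chain$genes[1]])
  }
  if (v0 == 0) warning("chain has zero initial value; all scores are 0")
  s <- if (is.null(cor)) rep(1, n - 1) else
    get_cor(cor, chain$genes[-n], chain$genes[-1])
  if (abs_cor) s <- abs(s)
  shortcut <- function(pos) {
    if (pos == n) 1 else {
      sc <- if (is.null(cor)) 1 else get_cor(cor, chain$genes[pos], chain$genes[n])
      if (abs_cor) abs(sc) else sc
    }
  }
  partial <- v0 * cumprod(c(1, s))   # partial[k] = v0 * prod(s_1..s_{k-1})
  v1 <- partial[n]
  ptox <- .first_label_pos(chain, "TOX")
  if (is.na(ptox)) {
    tox_begin <- tox_fin <- v2 <- 0
  } else {
    tox_begin <- partial[ptox]
    v2 <- tox_fin <- tox_begin * shortcut(ptox)
  }
  pjqc <- .first_label_pos(chain, "JQC")
  if (is.na(pjqc)) {
    jqc_begin <- jqc_fin <- v3 <- 0
  } else {
    jqc_begin <- partial[pjqc]
    v3 <- jqc_fin <- jqc_begin * shortcut(pjqc)
  }
  structure(list(chain = chain, v0 = v0, v1 = v1, v2 = v2, v3 = v3,
                 v = v1 - v2 + v3, loss = v0 - v1,
                 tox_begin = tox_begin, tox_fin = tox_fin,
                 jqc_begin = jqc_begin, jqc_fin = jqc_fin),
            class = "chain_score")
}

#' Combine chain score parts into the final score
#'
#' The final-score rule `v = v1 - v2 + v3`: the fully propagated value,
#' minus the toxicity-truncated value, plus the helper-shortcut value.
#'
#' @param v1 spread (fully propagated) value.
#' @param v2 toxicity-truncated value (`tox_fin`; 0 when no toxic node).
#' @param v3 helper-shortcut value (`JQC_fin`; 0 when no helper node).
#' @return The final score.
#' @export
combine_chain_score <- function(v1, v2, v3) v1 - v2 + v3

#' @export
print.chain_score <- function(x, ...) {
  cat(format_chain(x$chain), "\n")
  cat(sprintf("  v0 = %.4g  v1 = %.4g  v2 = %.4g  v3 = %.4g  v = %.4g\n",
              x$v0, x$v1, x$v2, x$v3, x$v))
  invisible(x)
}

#' Score a list of chains
#'
#' @param chains list of annotated `gene_chain`s.
#' @param influence influence coefficient table.
#' @param cor a `cor_store`.
#' @param abs_cor see [score_chain()].
#' @return List of `chain_score` objects.
#' @export
score_chains <- function(chains, influence, cor, abs_cor = FALSE) {
  lapply(chains, score_chain, influence = influence, cor = cor,
         abs_cor = abs_cor)
}

#' Retain chains scoring strictly above the cohort median
#'
#' The median final score of all chains is the retention threshold; only
#' chains with `v > median(v)` (strict) are kept, so an all-equal cohort
#' retains nothing. The even-count median is the usual midpoint.
#'
#' @param scored list of `chain_score` objects.
#' @return List with `retained` (the surviving `chain_score`s), `median`
#'   (the threshold) and `n_input`.
#' @export
filter_by_median <- function(scored) {
  if (length(scored) == 0) stop("no scored chains to filter")
  v <- vapply(scored, function(x) x$v, numeric(1))
  med <- stats::median(v)
  list(retained = scored[v > med], median = med, n_input = length(scored))
}

#' Tabulate chain scores in the worked-example column layout
#'
#' @param scored list of `chain_score` objects.
#' @param space space before label brackets in the chain string.
#' @return Data frame with columns `inital_value, chain, Spread value,
#'   Loss value, tox_begin value, tox_fin value, JQC_begin value,
#'   JQC_fin value, fin_value` (the layout of the packaged worked-example
#'   fixture, including its historical spelling of "inital").
#' @export
chain_score_table <- function(scored, space = TRUE) {
  df <- data.frame(
    inital_value = vapply(scored, function(x) x$v0, numeric(1)),
    chain = vapply(scored, function(x) format_chain(x$chain, space), character(1)),
    spread = vapply(scored, function(x) x$v1, numeric(1)),
    loss = vapply(scored, function(x) x$loss, numeric(1)),
    tox_begin = vapply(scored, function(x) x$tox_begin, numeric(1)),
    tox_fin = vapply(scored, function(x) x$tox_fin, numeric(1)),
    jqc_begin = vapply(scored, function(x) x$jqc_begin, numeric(1)),
    jqc_fin = vapply(scored, function(x) x$jqc_fin, numeric(1)),
    fin_value = vapply(scored, function(x) x$v, numeric(1)),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("inital_value", "chain", "Spread value", "Loss value",
                 "tox_begin value", "tox_fin value", "JQC_begin value",
                 "JQC_fin value", "fin_value")
  df
}
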