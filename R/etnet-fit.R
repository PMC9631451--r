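#' Fit the efficacy-toxicity network model for a herb pair
#'
#' One-call driver running the full quantitative compatibility analysis in
#' memory: (1) ADMET screen of both herbs' components and shared/unique
#' partition; (2) common component-target network with degree and
#' betweenness statistics; (3) influence decomposition of target-gene
#' expression for the primary herb's components, yielding per-edge initial
#' influence coefficients; (4) toxic-target selection from the
#' adverse-reaction annotations (or a supplied gene set); (5) weighted
#' propagation graph over the PPI network and deterministic shortest gene
#' transmission chains from primary-herb targets to pathogenic genes;
#' (6) chain labeling, scoring (v = v1 - v2 + v3) and median retention;
#' (7) synergy ranking of all cross-herb component pairs; (8) coverage of
#' the pathogenic genes by the retained chains.
#'
#' @param components component data frame for both herbs (column `herb`
#'   distinguishes them).
#' @param ct_edges component-target edge data frame (`component, target`).
#' @param ppi PPI edge data frame (`geneA, geneB`).
#' @param expression gene x sample numeric matrix.
#' @param disease_genes pathogenic gene symbols (chain sinks).
#' @param tox_annotations adverse-reaction annotation data frame (see
#'   [select_toxic_targets()]); alternatively pass `tox_genes` directly.
#' @param tox_genes toxic target genes (overrides `tox_annotations`).
#' @param helper_targets extra helper-herb target genes; the helper herb's
#'   own network targets are always included.
#' @param primary_herb,helper_herb values of `components$herb` naming the
#'   efficacious-but-toxic herb and the helper herb.
#' @param criteria [admet_criteria()] to screen with.
#' @param min_systems,min_reports toxic-target selection thresholds.
#' @param cost_mode edge-cost mode of the propagation graph
#'   (`"correlation"` or `"hop"`).
#' @param cor_method correlation method (default Pearson).
#' @param transform,center expression preprocessing for both the influence
#'   decomposition and the correlation store (see [influence_model()]).
#' @param abs_cor propagate absolute correlations in chain scoring.
#' @param L decomposition rank (default: number of primary components).
#' @return An object of class `etnet` with elements `screen`, `partition`,
#'   `network` (common C-T network with coefficients on primary edges),
#'   `influence` (the fitted `influence_model`), `tox_genes`,
#'   `helper_targets`, `graph`, `chains`, `scores`, `retained`, `median`,
#'   `synergy`, `coverage` and `settings`.
#' @seealso [run_pipeline()] for the file-based staged equivalent.
#' @export
etnet <- function(components, ct_edges, ppi, expression, disease_genes,
                  tox_annotations = NULL, tox_genes = NULL,
                  helper_targets = character(0),
                  primary_herb = "LGT", helper_herb = "JQC",
                  criteria = admet_criteria(),
                  min_systems = 2, min_reports = 10,
                  cost_mode = c("correlation", "hop"),
                  cor_method = "pearson",
                  transform = c("log2", "none"), center = TRUE,
                  abs_cor = FALSE, L = NULL) {
  cost_mode <- match.arg(cost_mode)
  transform <- match.arg(transform)

  ## 1. screen + partition
  scr <- admet_screen(components, criteria)
  passing <- scr$passing
  herbs <- unique(components$herb)
  if (!all(c(primary_herb, helper_herb) %in% herbs)) {
    stop("component table must contain both '", primary_herb, "' and '",
         helper_herb, "' rows")
  }
  primA <- passing[passing$herb == primary_herb, , drop = FALSE]
  helpB <- passing[passing$herb == helper_herb, , drop = FALSE]
  if (nrow(primA) == 0 || nrow(helpB) == 0) {
    stop("ADMET screen left no components for one of the herbs")
  }
  part <- partition_components(primA, helpB)

  ## 2. common C-T network (edges of screened components only)
  keep_ids <- unique(c(primA$id, helpB$id))
  edges <- ct_edges[as.character(ct_edges$component) %in% keep_ids, , drop = FALSE]
  net <- ct_network(edges, keep_ids)

  ## 3. influence decomposition on the primary herb's sub-network
  prim_net <- ct_network(edges[edges$component %in% primA$id, , drop = FALSE],
                         primA$id)
  infl <- influence_model(expression, prim_net, L = L,
                          transform = transform, center = center)
  coefs <- coef(infl)
  # carry coefficients onto the common network's primary edges
  key <- paste(net$edges$component, net$edges$target)
  ckey <- paste(coefs$component, coefs$target)
  net$edges$a <- coefs$a[match(key, ckey)]

  ## 4. toxic targets
  if (is.null(tox_genes)) {
    tox_genes <- if (is.null(tox_annotations)) character(0) else
      select_toxic_targets(tox_annotations, min_systems, min_reports)
  }
  tox_genes <- as.character(tox_genes)
  helper_targets <- sort(unique(c(as.character(helper_targets),
                                  unlist(lapply(helpB$id, ct_targets, net = net)))))

  ## 5. propagation graph + chains
  cor <- correlation_store(expression, method = cor_method,
                           transform = transform)
  graph <- build_weighted_graph(ppi, cor, mode = cost_mode)
  sources <- sort(unique(unlist(lapply(primA$id, ct_targets, net = prim_net))))
  chains <- shortest_chains(graph, sources, as.character(disease_genes))

  ## 6. label + score + median retention
  chains <- lapply(chains, annotate_labels, jqc_targets = helper_targets,
                   tox_targets = tox_genes)
  scores <- score_chains(chains, coefs, cor, abs_cor = abs_cor)
  filt <- if (length(scores)) filter_by_median(scores) else
    list(retained = list(), median = NA_real_, n_input = 0L)

  ## 7. synergy ranking over all cross pairs
  syn <- rank_pairs(net, tox = tox_genes,
                    herbA_ids = primA$id, herbB_ids = helpB$id)

  ## 8. coverage of the pathogenic genes by retained-chain genes
  chain_genes <- unique(unlist(lapply(filt$retained,
                                      function(s) s$chain$genes)))
  cov <- if (length(disease_genes)) {
    coverage(chain_genes, disease_genes, "retained chain genes",
             "pathogenic genes")
  } else NULL

  structure(list(screen = scr, partition = part, network = net,
                 influence = infl, tox_genes = tox_genes,
                 helper_targets = helper_targets, graph = graph,
                 chains = chains, scores = scores,
                 retained = filt$retained, median = filt$median,
                 synergy = syn, coverage = cov,
                 settings = list(primary_herb = primary_herb,
                                 helper_herb = helper_herb,
                                 cost_mode = cost_mode,
                                 cor_method = cor_method,
                                 transform = transform, center = center,
                                 abs_cor = abs_cor,
                                 min_systems = min_systems,
                                 min_reports = min_reports)),
            class = "etnet")
}

#' @export
print.etnet <- function(x, ...) {
  s <- x$settings
  cat("Efficacy-toxicity network model (", s$primary_herb, " + ",
      s$helper_herb, ")\n", sep = "")
  cat(sprintf("  screened components: %d passing / %d rejected\n",
              nrow(x$screen$passing), nrow(x$screen$rejected)))
  cat(sprintf("  C-T network: %d components, %d targets, %d edges\n",
              x$network$summary$n_components, x$network$summary$n_targets,
              x$network$summary$n_edges))
  cat(sprintf("  toxic targets: %d   helper targets: %d\n",
              length(x$tox_genes), length(x$helper_targets)))
  cat(sprintf("  chains: %d scored, %d retained above median %.4g\n",
              length(x$scores), length(x$retained), x$median))
  cat(sprintf("  component pairs ranked: %d\n", nrow(x$synergy)))
  invisible(x)
}

#' @export
summary.etnet <- function(object, n_top = 5, ...) {
  v <- vapply(object$scores, function(s) s$v, numeric(1))
  out <- list(
    n_passing = nrow(object$screen$passing),
    n_rejected = nrow(object$screen$rejected),
    partition = object$partition$summary,
    network = object$network$summary[c("n_components", "n_targets", "n_edges")],
    n_chains = length(object$scores),
    n_retained = length(object$retained),
    median_score = object$median,
    score_range = if (length(v)) range(v) else c(NA_real_, NA_real_),
    top_chains = utils::head(
      chain_score_table(object$scores[order(-v)]), n_top),
    top_pairs = utils::head(object$synergy, n_top),
    coverage = object$coverage)
  class(out) <- "summary.etnet"
  out
}

#' @export
print.summary.etnet <- function(x, ...) {
  cat("Components passing ADMET screen:", x$n_passing,
      "(rejected:", x$n_rejected, ")\n")
  cat(sprintf("Shared components: %d   unique: %d + %d (entities: %d)\n",
              x$partition$n_shared,
              x$partition$n_A - x$partition$n_shared,
              x$partition$n_B - x$partition$n_shared,
              x$partition$n_entities))
  cat(sprintf("Chains: %d scored, %d retained above median %.4g\n",
              x$n_chains, x$n_retained, x$median_score))
  cat("\nTop chains by final score:\n")
  print(x$top_chains, digits = 4)
  cat("\nTop component pairs by synergy score:\n")
  print(x$top_pairs, digits = 4)
  if (!is.null(x$coverage)) print(x$coverage)
  invisible(x)
}

#' @export
coef.etnet <- function(object, ...) coef(object$influence)

#' Plot the chain score distribution of a fitted model
#'
#' Histogram of final chain scores with the median retention threshold
#' marked; chains to the right of the line are retained.
#'
#' @param x an `etnet` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.etnet <- function(x, ...) {
  v <- vapply(x$scores, function(s) s$v, numeric(1))
  if (!length(v)) stop("no scored chains to plot")
  graphics::hist(v, main = "Gene transmission chain scores",
                 xlab = "final score v", ...)
  graphics::abline(v = x$median, lty = 2)
  graphics::mtext(sprintf("median = %.3g (retained: %d/%d)",
                          x$median, length(x$retained), length(v)),
                  side = 3, cex = 0.8)
  invisible(x)
}
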