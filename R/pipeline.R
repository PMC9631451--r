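#' Assemble (or load) a pipeline run configuration
#'
#' A run configuration names every input file, the output directory, and
#' the analysis parameters. It can be given as an R list or a YAML file
#' with the same field names. Unset parameters take the defaults below.
#' The resolved configuration is serialized next to the outputs of every
#' run.
#'
#' @param config list or path to a YAML file. Recognized fields:
#'   `inputs` (named list: `components`, `ct_edges`, `ppi`, `expression`,
#'   `tox_annotations` and/or `tox_genes`, `disease_genes`,
#'   `helper_targets`), `out_dir`, and `params` (`primary_herb`,
#'   `helper_herb`, `cost_mode`, `cor_method`, `transform`, `center`,
#'   `abs_cor`, `min_systems`, `min_reports`, `seed`, `log_level`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(primary_herb = "LGT", helper_herb = "JQC",
                   cost_mode = "correlation", cor_method = "pearson",
                   transform = "log2", center = TRUE, abs_cor = FALSE,
                   min_systems = 2, min_reports = 10, seed = 1,
                   log_level = "info")
  params <- utils::modifyList(defaults, config$params %||% list())
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  inputs <- config$inputs %||% list()
  need <- c("components", "ct_edges", "ppi", "expression", "disease_genes")
  missing_in <- setdiff(need, names(inputs))
  if (length(missing_in)) {
    stop("config inputs missing: ", paste(missing_in, collapse = ", "))
  }
  structure(list(inputs = inputs, out_dir = config$out_dir, params = params),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(cfg, ...) {
  if (identical(cfg$params$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " [etnet] ", ...)
}

.outfile <- function(cfg, name) file.path(cfg$out_dir, name)

.read_gene_list <- function(path) {
  if (is.null(path)) character(0) else trimws(readLines(path))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.pipeline_stages <- c("screen", "ctnet", "influence", "propagate",
                      "score", "synergy", "assess")

#' Run the analysis pipeline over files
#'
#' Executes the staged pipeline `screen -> ctnet -> influence -> propagate
#' -> score -> synergy -> assess`, with every stage reading its inputs
#' from, and writing its outputs to, files under `out_dir` — so any
#' contiguous suffix of stages can be re-run standalone against the
#' artifacts of a previous run. Outputs: `screened_components.tsv` (+
#' `rejected_components.tsv`), `ct_network.tsv` + `ct_network.graphml`,
#' `influence_coefficients.tsv`, `chains.tsv`, `scored_chains.tsv` (the
#' worked-example column layout), `retained_chains.tsv`,
#' `ranked_pairs.tsv`, `coverage.tsv`, and `manifest.json` recording the
#' resolved configuration, seed, package version and per-stage outputs.
#' On failure a `FAILED` marker naming the stage is left in `out_dir` and
#' the error is re-raised with the stage name.
#'
#' @param config a [run_config()], list, or YAML path.
#' @param stages character vector of stages to run (default all, in
#'   order).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, stages = .pipeline_stages) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(.outfile(cfg, "FAILED"))
  manifest <- list(package = "etnet",
                   version = as.character(utils::packageVersion("etnet")),
                   seed = cfg$params$seed,
                   config = list(inputs = cfg$inputs, out_dir = cfg$out_dir,
                                 params = cfg$params),
                   stages = list())
  for (stage in .pipeline_stages[.pipeline_stages %in% stages]) {
    .log(cfg, "stage: ", stage)
    res <- tryCatch(
      do.call(paste0(".stage_", stage), list(cfg)),
      error = function(e) {
        writeLines(c(stage, conditionMessage(e)), .outfile(cfg, "FAILED"))
        stop("pipeline stage '", stage, "' failed [ETNET_STAGE_ERROR]: ",
             conditionMessage(e), call. = FALSE)
      })
    manifest$stages[[stage]] <- res
  }
  jsonlite::write_json(manifest, .outfile(cfg, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(list(inputs = cfg$inputs, out_dir = cfg$out_dir,
                        params = cfg$params),
                   .outfile(cfg, "resolved_config.yaml"))
  invisible(cfg$out_dir)
}

.stage_screen <- function(cfg) {
  comp <- read_components(cfg$inputs$components)
  scr <- admet_screen(comp)
  .write_tsv(scr$passing, .outfile(cfg, "screened_components.tsv"))
  .write_tsv(scr$rejected, .outfile(cfg, "rejected_components.tsv"))
  list(outputs = c("screened_components.tsv", "rejected_components.tsv"),
       n_passing = nrow(scr$passing), n_rejected = nrow(scr$rejected))
}

.stage_ctnet <- function(cfg) {
  passing <- utils::read.delim(.outfile(cfg, "screened_components.tsv"),
                               stringsAsFactors = FALSE)
  edges <- utils::read.delim(cfg$inputs$ct_edges, stringsAsFactors = FALSE)
  edges <- edges[as.character(edges$component) %in% passing$id, , drop = FALSE]
  net <- ct_network(edges, passing$id)
  export_network(net, .outfile(cfg, "ct_network.tsv"), "tsv")
  export_network(net, .outfile(cfg, "ct_network.graphml"), "graphml")
  list(outputs = c("ct_network.tsv", "ct_network.graphml"),
       n_components = net$summary$n_components,
       n_targets = net$summary$n_targets, n_edges = net$summary$n_edges)
}

.stage_influence <- function(cfg) {
  passing <- utils::read.delim(.outfile(cfg, "screened_components.tsv"),
                               stringsAsFactors = FALSE)
  prim <- passing[passing$herb == cfg$params$primary_herb, , drop = FALSE]
  net <- read_network(.outfile(cfg, "ct_network.tsv"), "tsv")
  pedges <- net$edges[net$edges$component %in% prim$id, , drop = FALSE]
  pnet <- ct_network(pedges, prim$id)
  expr <- read_expression(cfg$inputs$expression)
  infl <- influence_model(expr, pnet, transform = cfg$params$transform,
                          center = cfg$params$center)
  .write_tsv(coef(infl), .outfile(cfg, "influence_coefficients.tsv"))
  list(outputs = "influence_coefficients.tsv",
       n_coefficients = nrow(coef(infl)), L = infl$L, M = infl$M,
       residual = infl$residual)
}

.stage_propagate <- function(cfg) {
  coefs <- utils::read.delim(.outfile(cfg, "influence_coefficients.tsv"),
                             stringsAsFactors = FALSE)
  ppi <- read_ppi(cfg$inputs$ppi)
  expr <- read_expression(cfg$inputs$expression)
  cor <- correlation_store(expr, method = cfg$params$cor_method,
                           transform = cfg$params$transform)
  graph <- build_weighted_graph(ppi, cor, mode = cfg$params$cost_mode)
  sinks <- .read_gene_list(cfg$inputs$disease_genes)
  chains <- shortest_chains(graph, unique(coefs$target), sinks)
  df <- data.frame(
    chain = vapply(chains, format_chain, character(1)),
    cost = vapply(chains, function(ch) attr(ch, "cost"), numeric(1)),
    stringsAsFactors = FALSE)
  .write_tsv(df, .outfile(cfg, "chains.tsv"))
  list(outputs = "chains.tsv", n_chains = nrow(df),
       cost_mode = cfg$params$cost_mode)
}

.stage_score <- function(cfg) {
  chain_df <- utils::read.delim(.outfile(cfg, "chains.tsv"),
                                stringsAsFactors = FALSE)
  coefs <- utils::read.delim(.outfile(cfg, "influence_coefficients.tsv"),
                             stringsAsFactors = FALSE)
  expr <- read_expression(cfg$inputs$expression)
  cor <- correlation_store(expr, method = cfg$params$cor_method,
                           transform = cfg$params$transform)
  tox <- if (!is.null(cfg$inputs$tox_genes)) {
    .read_gene_list(cfg$inputs$tox_genes)
  } else if (!is.null(cfg$inputs$tox_annotations)) {
    select_toxic_targets(read_tox_annotations(cfg$inputs$tox_annotations),
                         cfg$params$min_systems, cfg$params$min_reports)
  } else character(0)
  helper <- .read_gene_list(cfg$inputs$helper_targets)
  chains <- lapply(chain_df$chain, parse_chain)
  chains <- lapply(chains, annotate_labels, jqc_targets = helper,
                   tox_targets = tox)
  scored <- score_chains(chains, coefs, cor, abs_cor = cfg$params$abs_cor)
  tab <- chain_score_table(scored)
  .write_tsv(tab, .outfile(cfg, "scored_chains.tsv"))
  filt <- if (length(scored)) filter_by_median(scored) else
    list(retained = list(), median = NA_real_)
  .write_tsv(chain_score_table(filt$retained),
             .outfile(cfg, "retained_chains.tsv"))
  list(outputs = c("scored_chains.tsv", "retained_chains.tsv"),
       n_scored = length(scored), n_retained = length(filt$retained),
       median = filt$median)
}

.stage_synergy <- function(cfg) {
  passing <- utils::read.delim(.outfile(cfg, "screened_components.tsv"),
                               stringsAsFactors = FALSE)
  net <- read_network(.outfile(cfg, "ct_network.tsv"), "tsv")
  tox <- if (!is.null(cfg$inputs$tox_genes)) {
    .read_gene_list(cfg$inputs$tox_genes)
  } else if (!is.null(cfg$inputs$tox_annotations)) {
    select_toxic_targets(read_tox_annotations(cfg$inputs$tox_annotations),
                         cfg$params$min_systems, cfg$params$min_reports)
  } else character(0)
  prim <- passing$id[passing$herb == cfg$params$primary_herb]
  help <- passing$id[passing$herb == cfg$params$helper_herb]
  ranked <- rank_pairs(net, tox = tox, herbA_ids = prim, herbB_ids = help)
  .write_tsv(ranked, .outfile(cfg, "ranked_pairs.tsv"))
  list(outputs = "ranked_pairs.tsv", n_pairs = nrow(ranked))
}

.stage_assess <- function(cfg) {
  retained <- utils::read.delim(.outfile(cfg, "retained_chains.tsv"),
                                stringsAsFactors = FALSE, check.names = FALSE)
  sinks <- .read_gene_list(cfg$inputs$disease_genes)
  chain_genes <- unique(unlist(lapply(retained$chain,
                                      function(s) parse_chain(s)$genes)))
  cov <- coverage(chain_genes, sinks, "retained chain genes",
                  "pathogenic genes")
  df <- data.frame(query = cov$query_name, query_size = cov$query_size,
                   reference = cov$reference_name,
                   reference_size = cov$reference_size,
                   intersection = cov$intersection,
                   coverage = cov$coverage, stringsAsFactors = FALSE)
  .write_tsv(df, .outfile(cfg, "coverage.tsv"))
  list(outputs = "coverage.tsv", coverage = cov$coverage)
}

#' Write a synthetic study and a matching run configuration
#'
#' Convenience for smoke runs and the command-line `simulate` subcommand:
#' generates a [make_synthetic_study()], writes its input files under
#' `dir/inputs`, and returns a [run_config()] pointing at them with
#' outputs under `dir/out`.
#'
#' @param seed generator seed.
#' @param dir directory for inputs and outputs.
#' @param ... passed to [make_synthetic_study()].
#' @return A `run_config`, with the study attached as attribute
#'   `"study"`.
#' @export
simulate_run_config <- function(seed, dir, ...) {
  study <- make_synthetic_study(seed, ...)
  paths <- write_study(study, file.path(dir, "inputs"))
  cfg <- run_config(list(
    inputs = list(components = paths[["components"]],
                  ct_edges = paths[["ct_edges"]],
                  ppi = paths[["ppi"]],
                  expression = paths[["expression"]],
                  tox_genes = paths[["tox_genes"]],
                  disease_genes = paths[["disease_genes"]],
                  helper_targets = paths[["helper_targets"]]),
    out_dir = file.path(dir, "out"),
    params = list(seed = seed, transform = "none", center = FALSE,
                  log_level = "quiet")))
  attr(cfg, "study") <- study
  cfg
}
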