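# All generator randomness flows from the single `seed` argument through
# the local RNG scope below; the caller's RNG state is untouched.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rand_components <- function(ids, herb) {
  n <- length(ids)
  data.frame(
    id = ids, herb = herb,
    name = paste0("cmp_", ids),
    mw = round(stats::runif(n, 150, 540), 2),     # a few exceed the 500 Da rule
    hdon = stats::rbinom(n, 6, 0.35),
    hacc = stats::rbinom(n, 11, 0.4),
    rbn = stats::rbinom(n, 11, 0.3),
    fsp3 = round(stats::runif(n), 2),
    gi = sample(c("High", "Low"), n, replace = TRUE, prob = c(0.9, 0.1)),
    herg = sample(c("low_risk", "medium_risk", "high_risk", "ambiguous"),
                  n, replace = TRUE, prob = c(0.6, 0.25, 0.08, 0.07)),
    stringsAsFactors = FALSE)
}

# Compound-symmetric Gaussian blocks: genes within a block share pairwise
# correlation rho, blocks are independent.
.block_mvn <- function(n_genes, n_samples, block_size, rho) {
  out <- matrix(0, n_genes, n_samples)
  i <- 1
  while (i <= n_genes) {
    b <- min(block_size, n_genes - i + 1)
    z <- stats::rnorm(n_samples)                  # shared block factor
    e <- matrix(stats::rnorm(b * n_samples), b)
    out[i:(i + b - 1), ] <- sqrt(rho) * matrix(z, b, n_samples, byrow = TRUE) +
      sqrt(1 - rho) * e
    i <- i + b
  }
  out
}

#' Generate a complete synthetic two-herb study
#'
#' Seeded generator producing every input the pipeline consumes, plus the
#' ground truth needed to validate the influence decomposition: components
#' with ADMET properties for a primary (LGT-like) and helper (JQC-like)
#' herb sharing `n_shared` components; a component-target edge list whose
#' primary-herb blocks are target-disjoint by default (the well-posed
#' setting for mixing-matrix recovery); a preferential-attachment PPI
#' graph; a gene x sample expression matrix whose target-gene rows follow
#' the factor model `A = Y_true S_true + noise` and whose remaining rows
#' are block-structured Gaussians with within-block correlation `rho`;
#' toxic-gene annotations constructed so the multi-system/report-count
#' selection rule recovers the planted toxic set; disease genes; and the
#' helper-herb target list.
#'
#' @param seed integer seed; identical seeds give identical studies.
#' @param n_components_per_herb components per herb (default 6).
#' @param n_targets number of target genes (default 60).
#' @param n_ppi_nodes total genes in the PPI graph (>= n_targets;
#'   default 150).
#' @param n_samples expression samples (default 200).
#' @param rho within-block correlation of non-target genes in [0, 1)
#'   (default 0.6).
#' @param tox_fraction fraction of target genes planted as toxic targets
#'   (default 0.1).
#' @param disease_fraction fraction of PPI genes marked pathogenic
#'   (default 0.1).
#' @param noise_sd Gaussian noise s.d. on the factor-model rows
#'   (default 0.1).
#' @param n_shared components present in both herbs (default 1).
#' @param disjoint_targets give each primary-herb component a disjoint
#'   target block (default `TRUE`).
#' @param block_size block size of the non-target correlation structure.
#' @return An object of class `synthetic_study`: list with `seed`,
#'   `components`, `ct_edges`, `ppi`, `expression`, `tox_annotations`,
#'   `tox_genes`, `disease_genes`, `helper_targets`, `genes`, `targets`
#'   and `ground_truth` (`Y_true`, `S_true`, `a_true`).
#' @export
make_synthetic_study <- function(seed, n_components_per_herb = 6,
                                 n_targets = 60, n_ppi_nodes = 150,
                                 n_samples = 200, rho = 0.6,
                                 tox_fraction = 0.1, disease_fraction = 0.1,
                                 noise_sd = 0.1, n_shared = 1,
                                 disjoint_targets = TRUE, block_size = 5) {
  stopifnot(n_components_per_herb >= 1, n_targets >= 1,
            n_ppi_nodes >= n_targets, n_samples >= 3,
            rho >= 0, rho < 1, tox_fraction >= 0, tox_fraction <= 1,
            disease_fraction >= 0, disease_fraction <= 1,
            n_shared >= 0, n_shared <= n_components_per_herb)
  n_tox <- ceiling(tox_fraction * n_targets)
  if (n_tox > n_targets) stop("more toxic genes requested than target genes")
  .with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_ppi_nodes))
    targets <- genes[seq_len(n_targets)]

    nA <- n_components_per_herb
    nB <- n_components_per_herb
    shared_ids <- if (n_shared) sprintf("SHD%03d", seq_len(n_shared)) else character(0)
    idsA <- c(sprintf("LGT%03d", seq_len(nA - n_shared)), shared_ids)
    idsB <- c(sprintf("JQC%03d", seq_len(nB - n_shared)), shared_ids)
    components <- rbind(.rand_components(idsA, "LGT"),
                        .rand_components(idsB, "JQC"))
    components <- validate_components(components)

    # primary-herb target blocks (M sources for the decomposition)
    M <- length(idsA)
    if (disjoint_targets) {
      if (n_targets < M) stop("need at least one target per primary component")
      split_idx <- sort(seq_len(n_targets) %% M)
      blocksA <- split(sample(targets), split_idx)
    } else {
      blocksA <- lapply(seq_len(M), function(i) {
        sample(targets, max(2, stats::rbinom(1, n_targets, 0.15)))
      })
    }
    names(blocksA) <- idsA
    # helper-herb components hit random targets (may overlap anything);
    # a shared component is the same compound in both herbs and keeps its
    # primary-herb target block
    blocksB <- lapply(idsB, function(i) {
      if (i %in% idsA) blocksA[[i]] else
        sample(targets, max(2, stats::rbinom(1, n_targets, 0.12)))
    })
    names(blocksB) <- idsB
    edge_rows <- c(
      lapply(idsA, function(i) data.frame(component = i, target = blocksA[[i]],
                                          stringsAsFactors = FALSE)),
      lapply(setdiff(idsB, idsA),
             function(i) data.frame(component = i, target = blocksB[[i]],
                                    stringsAsFactors = FALSE)))
    ct_edges <- do.call(rbind, edge_rows)

    # ground-truth factors on the primary-herb blocks
    Y_true <- matrix(0, n_targets, M, dimnames = list(targets, idsA))
    for (i in seq_len(M)) {
      Y_true[blocksA[[i]], i] <- stats::runif(length(blocksA[[i]]), 0.5, 1.5)
    }
    S_true <- matrix(stats::rnorm(M * n_samples), M, n_samples,
                     dimnames = list(idsA, NULL))
    expr <- matrix(0, n_ppi_nodes, n_samples,
                   dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
    expr[targets, ] <- Y_true %*% S_true +
      noise_sd * matrix(stats::rnorm(n_targets * n_samples), n_targets)
    n_rest <- n_ppi_nodes - n_targets
    if (n_rest > 0) {
      expr[genes[(n_targets + 1):n_ppi_nodes], ] <-
        .block_mvn(n_rest, n_samples, block_size, rho)
    }

    # scale-free-ish PPI by preferential attachment
    g <- igraph::sample_pa(n_ppi_nodes, power = 1, m = 2, directed = FALSE)
    igraph::V(g)$name <- sample(genes)  # detach hub identity from gene index
    el <- igraph::as_edgelist(g)
    ppi <- data.frame(geneA = el[, 1], geneB = el[, 2],
                      stringsAsFactors = FALSE)

    tox_genes <- sort(sample(targets, n_tox))
    n_dis <- ceiling(disease_fraction * n_ppi_nodes)
    disease_genes <- sort(sample(genes, n_dis))
    helper_targets <- sort(unique(unlist(blocksB)))

    systems <- c("hepatic", "renal", "cardiovascular", "hematologic",
                 "digestive", "reproductive")
    ann_tox <- do.call(rbind, lapply(tox_genes, function(gn) {
      k <- sample(2:4, 1)
      data.frame(gene = gn, effect = paste0("adverse_", seq_len(k)),
                 system = sample(systems, k),
                 n_reports = stats::rpois(k, 8) + 4,  # totals comfortably > 10
                 stringsAsFactors = FALSE)
    }))
    decoys <- setdiff(sample(targets, min(n_targets, 2 * n_tox + 3)), tox_genes)
    ann_decoy <- if (length(decoys)) do.call(rbind, lapply(decoys, function(gn) {
      single_system <- stats::runif(1) < 0.5
      k <- if (single_system) 1 else 2
      data.frame(gene = gn, effect = paste0("adverse_", seq_len(k)),
                 system = sample(systems, k),
                 # multi-system decoys stay at or below the report threshold
                 n_reports = if (single_system) stats::rpois(k, 20) + 11
                             else sample(0:5, k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })) else NULL
    tox_annotations <- rbind(ann_tox, ann_decoy)
    rownames(tox_annotations) <- NULL

    a_true <- .extract_true_coefficients(Y_true, ct_edges, idsA)

    structure(list(seed = seed, components = components, ct_edges = ct_edges,
                   ppi = ppi, expression = expr,
                   tox_annotations = tox_annotations, tox_genes = tox_genes,
                   disease_genes = disease_genes,
                   helper_targets = helper_targets,
                   genes = genes, targets = targets,
                   primary_ids = idsA, helper_ids = idsB,
                   ground_truth = list(Y_true = Y_true, S_true = S_true,
                                       a_true = a_true)),
              class = "synthetic_study")
  })
}

# Ground-truth coefficients by the same extraction rule the influence
# module applies to its estimated Y: clip at 0, max-normalize per component.
.extract_true_coefficients <- function(Y_true, ct_edges, primary_ids) {
  e <- ct_edges[ct_edges$component %in% primary_ids, , drop = FALSE]
  a <- vapply(seq_len(nrow(e)), function(k) {
    max(Y_true[e$target[k], e$component[k]], 0)
  }, numeric(1))
  for (cid in unique(e$component)) {
    sel <- e$component == cid
    m <- max(a[sel])
    if (m > 0) a[sel] <- a[sel] / m
  }
  data.frame(component = e$component, target = e$target, a = a,
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic two-herb study (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  components: %d   targets: %d   PPI genes: %d   samples: %d\n",
              nrow(x$components), length(x$targets), length(x$genes),
              ncol(x$expression)))
  cat(sprintf("  toxic genes: %d   disease genes: %d   helper targets: %d\n",
              length(x$tox_genes), length(x$disease_genes),
              length(x$helper_targets)))
  invisible(x)
}

#' Misspecified expression generator (no factor structure)
#'
#' Pure block-covariance Gaussian expression with within-block correlation
#' `rho` and no component factor model; used to probe robustness of the
#' decomposition when its generative assumption does not hold.
#'
#' @param seed integer seed.
#' @param n_genes,n_samples matrix dimensions.
#' @param block_size genes per correlated block.
#' @param rho within-block correlation in [0, 1).
#' @return Gene x sample matrix with `G0001`-style row names.
#' @export
make_block_expression <- function(seed, n_genes = 100, n_samples = 200,
                                  block_size = 5, rho = 0.6) {
  stopifnot(rho >= 0, rho < 1, n_genes >= 1, n_samples >= 1)
  .with_seed(seed, {
    m <- .block_mvn(n_genes, n_samples, block_size, rho)
    dimnames(m) <- list(sprintf("G%04d", seq_len(n_genes)),
                        sprintf("S%03d", seq_len(n_samples)))
    m
  })
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits the same TSV/SIF files the pipeline readers consume, so a written
#' synthetic study is indistinguishable from real inputs: components,
#' component-target edges, PPI edges (TSV and SIF), expression,
#' toxicity annotations, and the three gene lists.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  paths <- c(
    components = w(study$components, "components.tsv"),
    ct_edges = w(study$ct_edges, "ct_edges.tsv"),
    ppi = w(study$ppi, "ppi.tsv"),
    tox_annotations = w(study$tox_annotations, "tox_annotations.tsv"))
  expr <- data.frame(gene = rownames(study$expression), study$expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
  paths["expression"] <- w(expr, "expression.tsv")
  wl <- function(x, f) { writeLines(x, file.path(dir, f)); file.path(dir, f) }
  paths["ppi_sif"] <- wl(sprintf("%s\tpp\t%s", study$ppi$geneA, study$ppi$geneB),
                         "ppi.sif")
  paths["tox_genes"] <- wl(study$tox_genes, "tox_genes.txt")
  paths["disease_genes"] <- wl(study$disease_genes, "disease_genes.txt")
  paths["helper_targets"] <- wl(study$helper_targets, "helper_targets.txt")
  invisible(paths)
}

#' Read a gene x sample expression TSV
#'
#' First column `gene` (row names), remaining columns samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene row names.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- x[[1]]
  m
}
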