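# correlation store with hand-prescribed entries, built from exact
# 3-sample vectors is fiddly; instead fabricate the store directly.
fake_cor <- function(genes, mat) {
  dimnames(mat) <- list(genes, genes)
  structure(list(cor = mat, method = "pearson"), class = "cor_store")
}

prescribed_cor <- function(genes, pairs) {
  m <- diag(length(genes))
  dimnames(m) <- list(genes, genes)
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  }
  fake_cor(genes, m)
}

test_that("label annotation attaches all applicable labels", {
  ch <- gene_chain(c("A", "B", "C"))
  out <- annotate_labels(ch, jqc_targets = "B")
  expect_equal(format_chain(out, space = FALSE), "A-B[JQC]-C")

  both <- annotate_labels(ch, jqc_targets = "B", tox_targets = "B")
  expect_equal(both$labels[[2]], c("TOX", "JQC"))
  expect_equal(format_chain(both), "A-B [TOX][JQC]-C")

  expect_equal(format_chain(annotate_labels(ch)), "A-B-C")
})

test_that("chain strings round-trip through parser and formatter", {
  s <- "DHCR24 [JQC]-MDM2 [TOX][JQC]-EEF1A1 [JQC]"
  ch <- parse_chain(s)
  expect_equal(ch$genes, c("DHCR24", "MDM2", "EEF1A1"))
  expect_equal(ch$labels, list("JQC", c("TOX", "JQC"), "JQC"))
  expect_equal(format_chain(ch), s)

  plain <- "PGC-ULK2-CREB1"
  expect_equal(format_chain(parse_chain(plain)), plain)
  expect_error(gene_chain(c("A", "A")), "simple path")
  expect_error(gene_chain("A", list("BAD")), "unknown chain label")
})

test_that("unit propagation: all correlations 1, no labels", {
  genes <- c("A", "B", "C", "D")
  cs <- fake_cor(genes, matrix(1, 4, 4))
  sc <- score_chain(gene_chain(genes), v0 = 1, cor = cs)
  expect_equal(sc$v1, 1)
  expect_equal(sc$v2, 0)
  expect_equal(sc$v3, 0)
  expect_equal(sc$v, 1)
  expect_equal(sc$loss, 0)
})

test_that("scores match an independent symbolic expansion with prescribed correlations", {
  genes <- c("A", "B", "C", "D", "E")
  s_steps <- c(0.9, 0.7, -0.5, 0.6)
  shortcuts <- c(B = 0.35, C = -0.8)
  pairs <- list(list("A", "B", 0.9), list("B", "C", 0.7),
                list("C", "D", -0.5), list("D", "E", 0.6),
                list("B", "E", 0.35), list("C", "E", -0.8))
  cs <- prescribed_cor(genes, pairs)
  ch <- gene_chain(genes, list(character(0), "JQC", "TOX",
                               character(0), character(0)))
  sc <- score_chain(ch, v0 = 12.5, cor = cs)
  oracle <- expand_chain_score(12.5, s_steps,
                               shortcut_cor = function(pos) shortcuts[[genes[pos]]],
                               tox_pos = 3, jqc_pos = 2)
  expect_equal(sc$v1, oracle$v1, tolerance = 1e-12)
  expect_equal(sc$v2, oracle$v2, tolerance = 1e-12)
  expect_equal(sc$v3, oracle$v3, tolerance = 1e-12)
  expect_equal(sc$v, oracle$v, tolerance = 1e-12)
  expect_equal(sc$v, sc$v1 - sc$v2 + sc$v3, tolerance = 1e-12)
  expect_equal(sc$tox_begin, 12.5 * 0.9 * 0.7, tolerance = 1e-12)
  expect_equal(sc$jqc_begin, 12.5 * 0.9, tolerance = 1e-12)
})

test_that("terminal-label convention: shortcut correlation 1 at the last node", {
  genes <- c("A", "B", "C")
  cs <- prescribed_cor(genes, list(list("A", "B", 0.8), list("B", "C", 0.5),
                                   list("A", "C", 0.3)))
  # TOX at terminal node: v2 equals the full spread value
  ch <- gene_chain(genes, list(character(0), character(0), "TOX"))
  sc <- score_chain(ch, v0 = 10, cor = cs)
  expect_equal(sc$v2, sc$v1, tolerance = 1e-12)
  expect_equal(sc$tox_begin, sc$tox_fin, tolerance = 1e-12)

  # JQC at terminal node: v3 = v1, so v = v1 - 0 + v1 = 2 v1
  ch <- gene_chain(genes, list(character(0), character(0), "JQC"))
  sc <- score_chain(ch, v0 = 10, cor = cs)
  expect_equal(sc$v, 2 * sc$v1, tolerance = 1e-12)
})

test_that("a 3-node chain with JQC at the middle node has v3 = v1 and v = 2 v1", {
  genes <- c("P", "Q", "R")
  cs <- prescribed_cor(genes, list(list("P", "Q", 0.77), list("Q", "R", 0.41)))
  ch <- gene_chain(genes, list(character(0), "JQC", character(0)))
  sc <- score_chain(ch, v0 = 270.12, cor = cs)
  # shortcut from Q to terminal R is the same correlation as the last step
  expect_equal(sc$v3, sc$v1, tolerance = 1e-12)
  expect_equal(sc$v, 2 * sc$v1, tolerance = 1e-12)
})

test_that("dual-labeled nodes contribute to both the penalty and the bonus", {
  genes <- c("A", "M", "E")
  cs <- prescribed_cor(genes, list(list("A", "M", 0.4), list("M", "E", 0.9)))
  ch <- gene_chain(genes, list("JQC", c("TOX", "JQC"), character(0)))
  sc <- score_chain(ch, v0 = 50, cor = cs)
  # first TOX is at M, first JQC at A
  expect_equal(sc$tox_begin, 50 * 0.4, tolerance = 1e-12)
  expect_equal(sc$v2, 50 * 0.4 * 0.9, tolerance = 1e-12)   # = v1 here
  expect_equal(sc$jqc_begin, 50, tolerance = 1e-12)
  expect_equal(sc$v3, 50 * get_cor(cs, "A", "E"), tolerance = 1e-12)
})

test_that("v0 accumulates influence coefficients onto the first gene", {
  infl <- data.frame(component = c("c1", "c2", "c3"),
                     target = c("A", "A", "B"), a = c(0.4, 0.25, 0.9))
  cs <- prescribed_cor(c("A", "B"), list(list("A", "B", 0.5)))
  sc <- score_chain(gene_chain(c("A", "B")), influence = infl, cor = cs)
  expect_equal(sc$v0, 0.65)
  expect_equal(sc$v1, 0.65 * 0.5)
  expect_warning(score_chain(gene_chain(c("Z", "B")), influence = infl,
                             cor = cs), "zero initial value")
  expect_error(score_chain(gene_chain("A"), v0 = 1), "at least 2 nodes")
})

test_that("moving a single TOX label later never increases the penalty", {
  # Non-adjacent correlations follow the multiplicative consistency the
  # chain propagation model implies (the exact value for a Gaussian Markov
  # chain): s(X, E) = product of the step correlations between X and E.
  set.seed(20)
  for (rep in 1:40) {
    n <- sample(3:7, 1)
    genes <- paste0("g", seq_len(n))
    s <- runif(n - 1, 0.05, 1)     # strictly positive steps in (0, 1]
    shortcut <- rev(cumprod(rev(s)))  # shortcut[k] = prod(s[k:(n-1)])
    pairs <- c(lapply(seq_len(n - 1), function(k) list(genes[k], genes[k + 1], s[k])),
               lapply(seq_len(n - 2), function(k) list(genes[k], genes[n], shortcut[k])))
    cs <- prescribed_cor(genes, pairs)
    scores <- lapply(seq_len(n), function(pos) {
      labels <- rep(list(character(0)), n)
      labels[[pos]] <- "TOX"
      score_chain(gene_chain(genes, labels), v0 = 1, cor = cs)
    })
    v2s <- vapply(scores, `[[`, numeric(1), "v2")
    expect_true(all(diff(v2s) <= 1e-12))
    # the accumulated toxicity up to the toxic node decreases outright
    begins <- vapply(scores, `[[`, numeric(1), "tox_begin")
    expect_true(all(diff(begins) <= 1e-12))
  }
})

test_that("median retention is strict and matches a sort-and-threshold oracle", {
  mk <- function(v) {
    structure(list(chain = gene_chain(c("A", "B")), v = v), class = "chain_score")
  }
  out <- filter_by_median(lapply(c(1, 2, 3), mk))
  expect_equal(vapply(out$retained, `[[`, numeric(1), "v"), 3)

  allsame <- filter_by_median(lapply(rep(2, 5), mk))
  expect_length(allsame$retained, 0)

  set.seed(30)
  v <- round(rnorm(1000), 3)
  out <- filter_by_median(lapply(v, mk))
  med <- sort(v)[500:501]; med <- mean(med)  # midpoint rule, independent
  expect_equal(out$median, med)
  expect_setequal(vapply(out$retained, `[[`, numeric(1), "v"), v[v > med])
  expect_length(out$retained, sum(v > med))

  expect_error(filter_by_median(list()), "no scored chains")
})

test_that("score table uses the worked-example column layout", {
  cs <- prescribed_cor(c("A", "B"), list(list("A", "B", 0.5)))
  tab <- chain_score_table(list(score_chain(gene_chain(c("A", "B")),
                                            v0 = 2, cor = cs)))
  expect_equal(names(tab),
               c("inital_value", "chain", "Spread value", "Loss value",
                 "tox_begin value", "tox_fin value", "JQC_begin value",
                 "JQC_fin value", "fin_value"))
  expect_equal(tab$fin_value,
               tab[["Spread value"]] - tab[["tox_fin value"]] + tab[["JQC_fin value"]])
})
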