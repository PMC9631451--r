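#' Raw synergy score for one component pair
#'
#' For a primary-herb component A with target set T(A) (size a), a
#' helper-herb component B with target set T(B) (size b), and the toxic
#' target set: `s1 = (|T(A) ∩ T(B)| - c) / (a + b)` where by default
#' `c = |T(A) ∩ tox|`, A's toxic targets among its own targets. Large
#' shared-target overlap raises the score; toxic targets of A depress it,
#' so s1 may be negative.
#'
#' @param net a [ct_network()] containing both components.
#' @param A,B component ids (primary herb, helper herb).
#' @param tox character vector of toxic target genes.
#' @param c_within_overlap count `c` only among the shared targets
#'   `T(A) ∩ T(B)` instead of all of A's targets (default `FALSE`).
#' @return List with `a`, `b`, `overlap`, `c`, `s1`.
#' @export
pair_raw_score <- function(net, A, B, tox, c_within_overlap = FALSE) {
  stopifnot(inherits(net, "ct_network"))
  tA <- ct_targets(net, A)
  tB <- ct_targets(net, B)
  a <- length(tA); b <- length(tB)
  if (a + b == 0) stop("components ", A, " and ", B, " have no targets")
  ov <- intersect(tA, tB)
  cc <- if (c_within_overlap) length(intersect(ov, tox)) else length(intersect(tA, tox))
  list(a = a, b = b, overlap = length(ov), c = cc,
       s1 = (length(ov) - cc) / (a + b))
}

#' Rank cross-herb component pairs by synergy score
#'
#' Computes `s1` for every pair, min-max scales across all evaluated pairs
#' to `s2` in [0, 1], multiplies the two components' normalized betweenness
#' centralities on the common C-T network into `s3 = x * y`, and ranks by
#' `s = s2 + s3` (descending; ties broken lexicographically by component
#' ids). With a single pair or an all-equal `s1` vector the min-max scale
#' is degenerate and `s2` is set to 0 with a warning.
#'
#' @param net the common `ct_network` of both herbs (betweenness is
#'   computed here).
#' @param pairs data frame with columns `componentA`, `componentB` (primary
#'   x helper cross pairs); default all cross pairs of `herbA_ids` x
#'   `herbB_ids`.
#' @param tox toxic target gene set.
#' @param herbA_ids,herbB_ids component id vectors used to build the
#'   default pair grid.
#' @param c_within_overlap see [pair_raw_score()].
#' @return Data frame `componentA, componentB, a, b, overlap, c, s1, s2,
#'   x, y, s3, s`, sorted by `s` descending.
#' @export
rank_pairs <- function(net, pairs = NULL, tox = character(0),
                       herbA_ids = NULL, herbB_ids = NULL,
                       c_within_overlap = FALSE) {
  stopifnot(inherits(net, "ct_network"))
  if (is.null(pairs)) {
    if (is.null(herbA_ids) || is.null(herbB_ids)) {
      stop("supply either a pair table or herbA_ids/herbB_ids")
    }
    pairs <- expand.grid(componentA = herbA_ids, componentB = herbB_ids,
                         stringsAsFactors = FALSE)
  }
  pairs$componentA <- as.character(pairs$componentA)
  pairs$componentB <- as.character(pairs$componentB)
  raw <- lapply(seq_len(nrow(pairs)), function(k) {
    pair_raw_score(net, pairs$componentA[k], pairs$componentB[k], tox,
                   c_within_overlap = c_within_overlap)
  })
  out <- data.frame(
    componentA = pairs$componentA, componentB = pairs$componentB,
    a = vapply(raw, `[[`, numeric(1), "a"),
    b = vapply(raw, `[[`, numeric(1), "b"),
    overlap = vapply(raw, `[[`, numeric(1), "overlap"),
    c = vapply(raw, `[[`, numeric(1), "c"),
    s1 = vapply(raw, `[[`, numeric(1), "s1"),
    stringsAsFactors = FALSE)
  rng <- range(out$s1)
  if (nrow(out) < 2 || rng[1] == rng[2]) {
    warning("degenerate s1 range; s2 set to 0 for all pairs")
    out$s2 <- 0
  } else {
    out$s2 <- (out$s1 - rng[1]) / (rng[2] - rng[1])
  }
  btw <- component_betweenness(net)
  out$x <- unname(btw[out$componentA])
  out$y <- unname(btw[out$componentB])
  out$s3 <- out$x * out$y
  out$s <- out$s2 + out$s3
  out <- out[order(-out$s, out$componentA, out$componentB), , drop = FALSE]
  rownames(out) <- NULL
  out
}
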