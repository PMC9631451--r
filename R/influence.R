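#' Best rank-L approximation by truncated SVD
#'
#' Eckart-Young-Mirsky approximation: among all matrices of rank at most L,
#' the truncated SVD reconstruction minimizes the Frobenius-norm error, and
#' that error equals the root-sum-square of the discarded singular values.
#'
#' @param A numeric matrix.
#' @param L retained rank, `1 <= L <= min(dim(A))`. L may exceed the
#'   numerical rank of A (trailing singular values are then zero).
#' @return List with `A_L` (the rank-L reconstruction), `W` (the first L
#'   left singular vectors, one column per retained direction), `d` (all
#'   singular values) and `residual` (`||A - A_L||_F`).
#' @export
low_rank_approx <- function(A, L) {
  A <- as.matrix(A)
  if (length(L) != 1 || is.na(L) || L < 1) stop("L must be a positive integer")
  L <- as.integer(L)
  if (L > min(dim(A))) stop("L exceeds matrix dimensions")
  sv <- svd(A)
  d <- sv$d
  UL <- sv$u[, seq_len(L), drop = FALSE]
  A_L <- UL %*% (d[seq_len(L)] * t(sv$v[, seq_len(L), drop = FALSE]))
  dimnames(A_L) <- dimnames(A)
  rownames(UL) <- rownames(A)
  list(A_L = A_L, W = UL, d = d,
       residual = sqrt(sum(d[-seq_len(L)]^2)))
}

# Fix the sign of a vector so its largest-magnitude entry is positive
# (resolves the SVD sign ambiguity deterministically).
.fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

#' Estimate the structured mixing matrix Y
#'
#' For each of M sources (components), the rows of W are partitioned into a
#' block W_c attributed to that source and the remaining rows W_r; after the
#' implied reordering the source's mixing column has the structure
#' y_i = [y_tilde_i; 0]. The estimate takes the last L - M + 1 right
#' singular vectors X0 of W_r and sets y_tilde_i to the first left singular
#' vector of W_c X0 X0' (projection onto the orthogonal complement of the
#' dominant row space of W_r). In the L = M case X0 is a single vector x,
#' the last right singular vector of W_r, and y_tilde_i = W_c x directly.
#'
#' @param W numeric matrix (rows = targets, columns = L retained
#'   directions), typically from [low_rank_approx()].
#' @param partitions list of M integer or character row-index vectors, one
#'   per source; entry i gives the rows of W attributed to source i (in the
#'   component-target network: the targets adjacent to component i).
#' @param M number of sources; defaults to `length(partitions)`.
#' @return List with `Y` (rows of W x M matrix, zero outside each source's
#'   block), and `empty` (logical vector flagging sources with an empty
#'   partition, whose columns are all zero).
#' @export
estimate_mixing <- function(W, partitions, M = length(partitions)) {
  W <- as.matrix(W)
  L <- ncol(W)
  if (M > L) stop("M (number of sources) cannot exceed L = ncol(W)")
  if (length(partitions) != M) stop("need one row partition per source")
  n <- nrow(W)
  Y <- matrix(0, n, M)
  rownames(Y) <- rownames(W)
  empty <- logical(M)
  for (i in seq_len(M)) {
    rows <- partitions[[i]]
    if (is.character(rows)) rows <- match(rows, rownames(W))
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0) {
      empty[i] <- TRUE
      next
    }
    Wc <- W[rows, , drop = FALSE]
    Wr <- W[-rows, , drop = FALSE]
    if (nrow(Wr) == 0) {
      # all rows belong to this source: leading left singular vector of Wc
      y <- .fix_sign(svd(Wc)$u[, 1])
    } else if (L == M) {
      x <- svd(Wr, nu = 0, nv = L)$v[, L]
      y <- .fix_sign(drop(Wc %*% x))
    } else {
      sv <- svd(Wr, nu = 0, nv = L)
      X0 <- sv$v[, seq.int(M, L), drop = FALSE]  # last L - M + 1 vectors
      proj <- Wc %*% X0 %*% t(X0)
      y <- .fix_sign(svd(proj)$u[, 1])
    }
    Y[rows, i] <- y
  }
  list(Y = Y, empty = empty)
}

#' Fit the component-influence decomposition model
#'
#' Estimates initial influence coefficients of components on their targets
#' from target-gene expression and the component-target network. The
#' procedure: (1) rank-L Eckart-Young approximation of the (optionally
#' log2(x+1)-transformed and row-centered) target x sample expression
#' matrix A, giving A_L and W = U_L; (2) structured estimation of the
#' mixing matrix Y, one column per component, with each component's block
#' of rows given by its network targets; (3) source matrix S = Y^+ A_L via
#' the Moore-Penrose pseudoinverse. Per-edge coefficients are read off Y
#' (clipped at zero, per-component max-normalized; see
#' [influence_coefficients()]).
#'
#' @param expr numeric gene x sample matrix with gene symbols as row names.
#' @param net a [ct_network()]; its components define the M sources and its
#'   edges the row partition of W.
#' @param L retained rank; default `NULL` means L = M (one direction per
#'   component), the recommended setting.
#' @param transform `"log2"` (log2(x+1), for raw expression counts or
#'   intensities) or `"none"`.
#' @param center row-center the transformed matrix (default `TRUE`; use
#'   `FALSE` when the expression was generated by a factor model whose
#'   scale is meaningful).
#' @return An object of class `influence_model` with elements `A`
#'   (preprocessed matrix), `A_L`, `W`, `Y`, `S`, `d` (singular values),
#'   `L`, `M`, `residual`, `components`, `empty` and `coefficients` (data
#'   frame `component, target, a`).
#' @export
influence_model <- function(expr, net, L = NULL,
                            transform = c("log2", "none"), center = TRUE) {
  stopifnot(inherits(net, "ct_network"))
  transform <- match.arg(transform)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs gene row names")
  A <- expr
  if (transform == "log2") {
    if (any(A < 0, na.rm = TRUE)) stop("log2 transform requires nonnegative expression")
    A <- log2(A + 1)
  }
  if (center) A <- A - rowMeans(A)

  comps <- net$components
  M <- length(comps)
  if (M == 0) stop("network has no components")
  # restrict to expressed targets of the network
  tgt <- intersect(net$targets, rownames(A))
  missing_tgt <- setdiff(net$targets, rownames(A))
  if (length(missing_tgt)) {
    warning(length(missing_tgt),
            " network target(s) lack expression; their edges get a = 0")
  }
  if (length(tgt) < 2) stop("fewer than 2 network targets have expression")
  A <- A[tgt, , drop = FALSE]
  if (is.null(L)) L <- min(M, dim(A))
  lr <- low_rank_approx(A, L)
  partitions <- lapply(comps, function(cid) {
    intersect(ct_targets(net, cid), tgt)
  })
  em <- estimate_mixing(lr$W, partitions, M = M)
  Y <- em$Y
  colnames(Y) <- comps
  S <- MASS::ginv(Y) %*% lr$A_L
  rownames(S) <- comps
  model <- structure(list(A = A, A_L = lr$A_L, W = lr$W, Y = Y, S = S,
                          d = lr$d, L = L, M = M, residual = lr$residual,
                          components = comps, empty = em$empty,
                          missing_targets = missing_tgt,
                          transform = transform, center = center),
                     class = "influence_model")
  model$coefficients <- influence_coefficients(model, net)
  model
}

#' Extract per-edge initial influence coefficients
#'
#' For each component-target edge (i, j) the raw coefficient is the Y entry
#' of target j in component i's column, clipped at zero; coefficients are
#' then max-normalized within each component so every emitted `a` lies in
#' [0, 1]. Edges whose target lacks expression get `a = 0`.
#'
#' @param model an `influence_model`.
#' @param net the `ct_network` the model was fitted to.
#' @return Data frame `component, target, a`.
#' @export
influence_coefficients <- function(model, net) {
  stopifnot(inherits(model, "influence_model"), inherits(net, "ct_network"))
  edges <- net$edges
  a <- numeric(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    j <- edges$target[k]
    i <- edges$component[k]
    a[k] <- if (j %in% rownames(model$Y)) max(model$Y[j, i], 0) else 0
  }
  for (cid in unique(edges$component)) {
    sel <- edges$component == cid
    m <- max(a[sel])
    if (m > 0) a[sel] <- a[sel] / m
  }
  data.frame(component = edges$component, target = edges$target, a = a,
             stringsAsFactors = FALSE)
}

#' @export
print.influence_model <- function(x, ...) {
  cat("Component-influence decomposition model\n")
  cat(sprintf("  targets: %d   samples: %d   components (M): %d   rank (L): %d\n",
              nrow(x$A), ncol(x$A), x$M, x$L))
  cat(sprintf("  ||A - A_L||_F = %.4g\n", x$residual))
  if (any(x$empty)) {
    cat("  components with no expressed targets:",
        paste(x$components[x$empty], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.influence_model <- function(object, ...) object$coefficients

#' @export
fitted.influence_model <- function(object, ...) object$A_L

#' @export
residuals.influence_model <- function(object, ...) object$A - object$A_L
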