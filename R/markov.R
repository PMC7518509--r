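# Degree vector, row-stochastic Markov operator, matrix powers.

#' Degree vector of an affinity matrix
#'
#' Entry i is the row sum `sum_j a_ij`, i.e. the weighted degree of
#' protein i; these are the diagonal entries of the degree matrix D.
#'
#' @param A an [build_affinity()] object or any (sparse) matrix.
#' @return Named numeric vector of length n.
#' @export
degree_vector <- function(A) {
  V <- if (inherits(A, "affinity")) A$values else A
  d <- Matrix::rowSums(V)
  names(d) <- rownames(V)
  d
}

#' Row-stochastic Markov transition operator
#'
#' Computes `M = D^-1 A`, where D is the diagonal degree matrix of the
#' affinity matrix A. Entry `m_ij = a_ij / D_ii` is the probability of a
#' one-step random walk from node i to node j; every row sums to 1.
#' Degree-zero nodes make `D^-1` undefined and are an error here — remove
#' them first with [drop_isolates()].
#'
#' @param A an [build_affinity()] object or a non-negative matrix.
#' @return An object of class `transition`: list with `values` (sparse
#'   row-stochastic matrix), `degrees` (the row sums of A), `nodes`.
#' @export
transition_matrix <- function(A) {
  V <- if (inherits(A, "affinity")) A$values else as(A, "CsparseMatrix")
  if (nrow(V) != ncol(V)) stop("affinity matrix must be square")
  d <- Matrix::rowSums(V)
  zero <- which(d == 0)
  if (length(zero)) {
    who <- if (!is.null(rownames(V))) rownames(V)[zero] else as.character(zero)
    stop("degenerate graph: zero-degree node(s) ",
         paste(head(who, 10L), collapse = ", "),
         if (length(zero) > 10L) sprintf(" (and %d more)", length(zero) - 10L),
         "; drop isolates before building the transition matrix")
  }
  M <- as(Matrix::Diagonal(x = 1 / d) %*% V, "CsparseMatrix")
  dimnames(M) <- dimnames(V)
  rs <- Matrix::rowSums(M)
  if (any(abs(rs - 1) > 1e-12))
    stop("internal error: transition rows deviate from 1 by more than 1e-12")
  structure(list(values = M, degrees = d, nodes = rownames(V)),
            class = "transition")
}

#' @export
print.transition <- function(x, ...) {
  cat(sprintf("transition operator: %d x %d row-stochastic, %d nonzero entries\n",
              nrow(x$values), ncol(x$values), Matrix::nnzero(x$values)))
  invisible(x)
}

#' Apply a power of the Markov operator to a signal matrix
#'
#' Returns `M^t X` by t successive sparse multiplications; the dense
#' power `M^t` is never materialized. With the default `"left"`
#' orientation, node i's new signal is the `m_i.`-weighted average of
#' its neighbors' signals; `"transpose"` instead spreads each node's
#' signal mass to its neighbors.
#'
#' @param M a [transition_matrix()] object or a matrix.
#' @param X numeric matrix (or vector) with one row per node.
#' @param t non-negative integer number of steps.
#' @param operator `"left"` (default) applies `M`; `"transpose"`
#'   applies `t(M)`.
#' @return Dense base matrix `M^t X` (X unchanged for `t = 0`).
#' @export
apply_power <- function(M, X, t, operator = c("left", "transpose")) {
  operator <- match.arg(operator)
  V <- if (inherits(M, "transition")) M$values else M
  if (operator == "transpose") V <- Matrix::t(V)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L, dimnames = list(names(X), NULL))
  X <- as.matrix(X)
  if (nrow(X) != ncol(V))
    stop("shape mismatch: X has ", nrow(X), " rows but the operator expects ",
         ncol(V))
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != round(t))
    stop("'t' must be a single non-negative integer")
  for (k in seq_len(t)) X <- as.matrix(V %*% X)
  X
}
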