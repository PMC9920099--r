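#' Rank-one tensor from an outer product
#'
#' Builds the rank-one matrix `a b'` or, when `c` is supplied, the
#' third-order rank-one tensor with entries `a[i] * b[j] * c[d]`.
#'
#' @param a,b,c numeric vectors; `c` may be omitted for the two-way case.
#' @return a matrix (`length(a)` x `length(b)`) or a 3-way array.
#' @examples
#' outer_rank1(c(1, 2), c(3, 4))
#' @export
outer_rank1 <- function(a, b, c = NULL) {
  if (is.null(c)) outer(a, b) else outer(outer(a, b), c)
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' Column `r` of the result is the row-major vectorization of the outer
#' product of the r-th columns of `B` and `C`, i.e. `kron(B[, r], C[, r])`.
#' This is the vectorization order under which the mode-1 unfolding of a
#' CP model factors as `A %*% t(khatri_rao(B, C))` (see [matricize()]).
#'
#' @param B numeric matrix (J x R).
#' @param C numeric matrix (D x R) with the same number of columns.
#' @return a (J*D) x R matrix.
#' @examples
#' khatri_rao(diag(2), diag(2))
#' @export
khatri_rao <- function(B, C) {
  B <- as.matrix(B)
  C <- as.matrix(C)
  if (ncol(B) != ncol(C))
    stop("column counts differ: ncol(B) = ", ncol(B),
         ", ncol(C) = ", ncol(C))
  out <- matrix(0, nrow(B) * nrow(C), ncol(B))
  for (r in seq_len(ncol(B)))
    out[, r] <- kronecker(B[, r], C[, r])
  out
}

#' Matricization (unfolding) of a third-order tensor
#'
#' Rearranges a 3-way array into a matrix whose rows index the chosen mode
#' and whose columns run over the remaining two modes, with the next mode
#' varying slowest and the last varying fastest. Under this layout the CP
#' identities `matricize(t, 1) == A %*% t(khatri_rao(B, C))` (and the
#' analogous mode-2 / mode-3 forms with `A⊙C` and `A⊙B`) hold exactly.
#'
#' @param t a 3-way numeric array (I x J x D).
#' @param mode which mode to unfold along: 1, 2 or 3.
#' @return a matrix: I x (J*D), J x (I*D) or D x (I*J).
#' @seealso [tensor_fold()] for the inverse operation.
#' @export
matricize <- function(t, mode) {
  d <- dim(t)
  if (length(d) != 3L)
    stop("t must be a 3-way array")
  if (!mode %in% 1:3)
    stop("mode must be 1, 2 or 3, got ", mode)
  # aperm to (mode, other-slow, other-fast), then flatten rows
  perm <- switch(mode, `1` = c(1L, 3L, 2L), `2` = c(2L, 3L, 1L),
                 `3` = c(3L, 2L, 1L))
  x <- aperm(t, perm)
  dim(x) <- c(d[mode], prod(d[-mode]))
  x
}

#' Fold a matricized tensor back into a 3-way array
#'
#' Inverse of [matricize()]: `tensor_fold(matricize(t, mode), mode, dim(t))`
#' restores `t` exactly.
#'
#' @param m an unfolded matrix as produced by [matricize()].
#' @param mode the mode that was unfolded.
#' @param dims the dimensions of the original tensor.
#' @return a 3-way array with dimensions `dims`.
#' @export
tensor_fold <- function(m, mode, dims) {
  if (!mode %in% 1:3) stop("mode must be 1, 2 or 3, got ", mode)
  if (length(dims) != 3L) stop("dims must have length 3")
  if (!all(dim(m) == c(dims[mode], prod(dims[-mode]))))
    stop("matrix shape does not match dims for mode ", mode)
  perm <- switch(mode, `1` = c(1L, 3L, 2L), `2` = c(2L, 3L, 1L),
                 `3` = c(3L, 2L, 1L))
  x <- m
  dim(x) <- c(dims[mode], rev(dims[-mode]))
  aperm(x, order(perm))
}

# Least-squares solve of  min || Y - Out %*% t(Z) ||_F  for Out, i.e.
# Out = Y %*% Z %*% (Z'Z)^-1, with a ridge fallback when Z'Z is singular.
.ls_update <- function(Y, Z) {
  G <- crossprod(Z)
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch) || rcond(G) < 1e-12) {
    warning("rank-deficient Khatri-Rao product; using regularized pseudoinverse")
    G <- G + diag(1e-10 * (mean(diag(G)) + 1), ncol(G))
    ch <- chol(G)
  }
  Y %*% Z %*% chol2inv(ch)
}

#' PARAFAC (CP) decomposition of a third-order tensor by ALS
#'
#' Classic least-squares canonical polyadic decomposition
#' \deqn{X \approx \sum_{r=1}^{R} a^{(r)} \circ b^{(r)} \circ c^{(r)}}
#' fitted by alternating least squares: each factor matrix in turn is
#' updated by the pseudoinverse solution of the corresponding unfolded
#' linear problem (e.g. `A <- X(1) %*% pinv(t(khatri_rao(B, C)))`), which
#' makes the Frobenius objective non-increasing across sweeps.
#'
#' @param t a 3-way numeric array.
#' @param R number of rank-one components; must not exceed, for any mode,
#'   the product of the other two dimensions.
#' @param tol relative change in the Frobenius objective below which the
#'   alternation stops.
#' @param max_iter maximum number of ALS sweeps.
#' @param seed optional integer seed for the random initialization.
#' @return a `cp_factors` object with factor matrices `A`, `B`, `C`, the
#'   per-sweep `objective_trace` (Frobenius norm of the residual) and the
#'   final `objective`.
#' @examples
#' x <- outer_rank1(1:3, c(2, 5), c(1, 1, 4))
#' fit <- parafac_als(x, R = 1, seed = 1)
#' fit$objective  # ~0: exact rank-one input
#' @export
parafac_als <- function(t, R, tol = 1e-8, max_iter = 500L, seed = NULL) {
  d <- dim(t)
  if (length(d) != 3L) stop("t must be a 3-way array")
  R <- as.integer(R)
  if (R < 1L) stop("R must be >= 1")
  maxR <- min(d[2] * d[3], d[1] * d[3], d[1] * d[2])
  if (R > maxR)
    stop("R = ", R, " exceeds the identifiable maximum ", maxR,
         " for dimensions ", paste(d, collapse = "x"))
  if (!is.null(seed)) set.seed(seed)

  A <- matrix(runif(d[1] * R), d[1], R)
  B <- matrix(runif(d[2] * R), d[2], R)
  C <- matrix(runif(d[3] * R), d[3], R)
  X1 <- matricize(t, 1)
  X2 <- matricize(t, 2)
  X3 <- matricize(t, 3)

  obj <- function(A, B, C) {
    sqrt(sum((X1 - tcrossprod(A, khatri_rao(B, C)))^2))
  }
  trace_v <- obj(A, B, C)
  for (it in seq_len(max_iter)) {
    A <- .ls_update(X1, khatri_rao(B, C))
    B <- .ls_update(X2, khatri_rao(A, C))
    C <- .ls_update(X3, khatri_rao(A, B))
    o <- obj(A, B, C)
    trace_v <- c(trace_v, o)
    prev <- trace_v[length(trace_v) - 1L]
    if (abs(prev - o) <= tol * max(prev, 1e-12)) break
  }

  structure(
    list(A = A, B = B, C = C,
         objective = trace_v[length(trace_v)],
         objective_trace = trace_v,
         degenerate = colSums(abs(A)) == 0,
         iterations = length(trace_v) - 1L,
         f = R),
    class = "cp_factors")
}
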