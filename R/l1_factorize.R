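#' Non-negative L1 two-way factorization
#'
#' Approximately minimizes the entrywise L1 reconstruction error
#' \deqn{\sum_{ij} | x_{ij} - \sum_{r=1}^{f} a_i(r)\, b_j(r) |}
#' over non-negative factor matrices `A` (I x f) and `B` (S x f). The L1
#' loss yields sparse reconstructions, which suits binarized or
#' near-binary connectivity stacks better than the least-squares CP fit.
#'
#' Both solvers are iteratively reweighted schemes: each sweep majorizes
#' the L1 loss by a weighted quadratic with weights
#' \eqn{1/\max(|r_{ij}|, \epsilon)} from the current residuals, and solves
#' it for one factor matrix at a time.
#'
#' * `method = "mu"` (default) applies the multiplicative (Lee-Seung type)
#'   update of the weighted quadratic. Iterates remain strictly positive,
#'   so non-negativity is intrinsic and rank-one components are never
#'   annihilated outright; this preserves the weakly-expressed common mode
#'   that the minimum-variance selection of [extract_grand_average()]
#'   relies on when `f` approaches the number of subjects.
#' * `method = "irls"` solves each row's weighted least-squares problem
#'   exactly and clips negative entries to zero. It typically reaches
#'   lower objective values but produces exact zeros, which can eliminate
#'   diffuse components entirely.
#'
#' Neither reweighted step is guaranteed monotone for the L1 objective, so
#' the iterate with the lowest objective seen is the one returned; the
#' final objective therefore never exceeds the objective at
#' initialization. Multiple random restarts are run and the best kept.
#'
#' On return every column of `A` is rescaled to unit L1 norm with the
#' scale absorbed into the corresponding column of `B`, making subject
#' loadings commensurable across factors; identically zero ("dead")
#' factors are kept but flagged in `degenerate`.
#'
#' @param X non-negative numeric matrix (I x S), e.g. vectorized subject
#'   networks in columns.
#' @param f number of rank-one factors; must satisfy `1 <= f <= ncol(X)`
#'   (the column count bounds the rank of `X`).
#' @param tol relative objective-change stopping tolerance of the outer
#'   alternation.
#' @param max_iter maximum outer sweeps per restart.
#' @param n_init number of random restarts; best final objective wins.
#' @param seed optional integer seed for the restart initializations.
#' @param method `"mu"` for multiplicative reweighted updates (default)
#'   or `"irls"` for exact row-wise weighted solves with clipping.
#' @param eps_w IRLS weight smoothing constant.
#' @return an object of class `cp_factors` with elements `A`, `B`,
#'   `objective`, `objective_trace` (of the winning restart),
#'   `degenerate` (logical per factor), `iterations`, and `f`.
#' @examples
#' a <- runif(16); b <- runif(6)
#' X <- outer(a, b)
#' fit <- l1_nonneg_factorize(X, f = 1, seed = 1)
#' fit$objective / sum(X)  # near zero: exact rank-one input
#' @export
l1_nonneg_factorize <- function(X, f, tol = 1e-6, max_iter = 500L,
                                n_init = 5L, seed = NULL,
                                method = c("mu", "irls"), eps_w = 1e-8) {
  method <- match.arg(method)
  core <- if (method == "mu") .l1nn_mu_core else .l1nn_core
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X)))
    stop("X must be a finite numeric matrix")
  if (any(X < 0))
    stop("X must be non-negative elementwise")
  S <- ncol(X)
  I <- nrow(X)
  f <- as.integer(f)
  if (f < 1L)
    stop("f must be >= 1")
  if (f > S)
    stop("f = ", f, " exceeds the number of columns S = ", S,
         "; the factor count cannot exceed rank(X) <= S")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (init in seq_len(n_init)) {
    if (init == 1L) {
      # warm start: every column seeded at the jittered row mean of X, the
      # natural first guess for a pattern shared across columns (and the
      # exact solution when all columns are identical)
      xbar <- rowMeans(X)
      A0 <- xbar * matrix(runif(I * f, 0.5, 1.5), I, f)
      B0 <- matrix(runif(S * f, 0.5, 1.5) / f, S, f)
    } else {
      A0 <- matrix(runif(I * f), I, f)
      B0 <- matrix(runif(S * f), S, f)
    }
    res <- core(X, A0, B0, tol, as.integer(max_iter), eps_w)
    if (is.null(best) || res$objective < best$objective) best <- res
    # an (almost) exact fit cannot be improved by further restarts
    if (best$objective <= 1e-9 * sum(X)) break
  }

  A <- best$A
  B <- best$B
  scale <- colSums(A)
  dead <- scale <= 0
  for (r in which(!dead)) {
    A[, r] <- A[, r] / scale[r]
    B[, r] <- B[, r] * scale[r]
  }

  structure(
    list(A = A, B = B,
         objective = best$objective,
         objective_trace = as.numeric(best$objective_trace),
         degenerate = dead,
         iterations = best$iterations,
         method = method,
         f = f),
    class = "cp_factors")
}

#' @export
print.cp_factors <- function(x, ...) {
  cat("CP factors: A ", nrow(x$A), "x", ncol(x$A),
      ", B ", nrow(x$B), "x", ncol(x$B),
      if (!is.null(x$C)) paste0(", C ", nrow(x$C), "x", ncol(x$C)) else "",
      "\n", sep = "")
  cat("objective:", format(x$objective), "after",
      length(x$objective_trace) - 1L, "iterations\n")
  if (any(x$degenerate))
    cat("degenerate factors:", paste(which(x$degenerate), collapse = ", "), "\n")
  invisible(x)
}
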