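# Grand-average extraction: stack vectorized subject networks into a
# K^2 x S matrix, factorize with the non-negative L1 solver, select the
# rank-one component whose subject loadings have minimum variance, and
# binarize / re-weight it into the group-level network.

#' Stack subject connectivity matrices into a K^2 x S matrix
#'
#' Column `s` is the row-major vectorization of subject s's K x K matrix
#' (entries in the order m\[1,1\], m\[1,2\], ..., m\[1,K\], m\[2,1\], ...,
#' m\[K,K\]).
#'
#' @param mats list of S non-negative K x K matrices (same K throughout).
#' @param subject_ids optional character vector of S labels.
#' @return an object of class `subject_stack`: list with `X` (K^2 x S),
#'   `K`, `subject_ids`, and `node_labels` (taken from the first matrix's
#'   rownames if present).
#' @export
stack_subjects <- function(mats, subject_ids = NULL) {
  if (inherits(mats, "synthetic_dataset")) mats <- mats$subjects
  if (is.matrix(mats)) mats <- list(mats)
  S <- length(mats)
  if (S < 1) stop("need at least one subject matrix")
  K <- nrow(mats[[1L]])
  for (s in seq_len(S)) {
    ms <- as.matrix(mats[[s]])
    if (nrow(ms) != ncol(ms) || nrow(ms) != K)
      stop("subject ", s, " is ", nrow(ms), "x", ncol(ms),
           "; all matrices must be ", K, "x", K)
    if (any(ms < 0))
      stop("subject ", s, " has negative entries")
  }
  X <- vapply(mats, function(m) as.vector(t(as.matrix(m))), numeric(K * K))
  X <- matrix(X, nrow = K * K, ncol = S)
  if (is.null(subject_ids))
    subject_ids <- paste0("S", seq_len(S))
  structure(list(X = X, K = K, subject_ids = subject_ids,
                 node_labels = rownames(mats[[1L]])),
            class = "subject_stack")
}

#' Restore a vectorized network to its K x K matrix form
#'
#' Inverse of the stacking order used by [stack_subjects()] (row-major).
#'
#' @param v numeric vector of length K^2.
#' @param K node count.
#' @return a K x K matrix.
#' @export
unstack_network <- function(v, K) {
  if (length(v) != K * K) stop("length(v) must equal K^2")
  matrix(v, K, K, byrow = TRUE)
}

#' Extract the grand-average network from a subject stack
#'
#' Runs [l1_nonneg_factorize()] on the stacked networks, then selects the
#' factor whose subject-loading column has minimum population variance
#' (after each connectivity column of `A` has been rescaled to unit L1
#' norm, which makes loadings comparable across factors): a pattern truly
#' shared by the group should be expressed about equally in every subject.
#' Degenerate (all-zero) factors are excluded from selection; ties break
#' toward the lower factor index. The selected pattern is then expressed
#' on the scale of an average subject, `a(r) * mean(b(r))` (so the
#' threshold has the units of the input networks and does not depend on
#' the node count), reshaped to K x K, thresholded into a binary network
#' (diagonal forced to zero, self-connections are never considered), and
#' each surviving connection is assigned the mean of that connection's
#' value across the subjects.
#'
#' @param stack a `subject_stack` (or a list of matrices, which is stacked
#'   first).
#' @param f number of factors, `1 <= f <= S`.
#' @param binarize_threshold connections whose selected-factor weight
#'   (on the average-subject scale, see Details) falls below this are set
#'   to 0; default 0.001.
#' @param threshold_scale scale on which the threshold is applied:
#'   `"subject"` (default) thresholds `a(r) * mean(b(r))`, `"unit"`
#'   thresholds the unit-L1-normalized `a(r)` directly.
#' @param seed,tol,max_iter,n_init,method solver options, see
#'   [l1_nonneg_factorize()].
#' @return an object of class `grand_average`: list with `binary` (K x K
#'   0/1), `weighted` (mean subject value on surviving connections, 0
#'   elsewhere), `scores` (the selected factor's continuous weights as a
#'   K x K matrix, before thresholding), `selected_factor`,
#'   `loading_variances`, `factors` (the full `cp_factors` fit), and
#'   `threshold`.
#' @examples
#' ds <- generate_dataset(K = 10, S = 5, m = 0, seed = 7)
#' ga <- extract_grand_average(stack_subjects(ds$subjects), f = 2, seed = 1)
#' all(ga$binary == ds$ground_truth$matrix)  # noiseless case: exact recovery
#' @export
extract_grand_average <- function(stack, f, binarize_threshold = 0.001,
                                  seed = NULL, tol = 1e-6, max_iter = 500L,
                                  n_init = 5L, method = c("mu", "irls"),
                                  threshold_scale = c("subject", "unit")) {
  threshold_scale <- match.arg(threshold_scale)
  if (!inherits(stack, "subject_stack")) stack <- stack_subjects(stack)
  S <- ncol(stack$X)
  K <- stack$K
  if (f > S)
    stop("f = ", f, " exceeds S = ", S,
         "; the factor count is bounded by rank(X) <= S")
  fit <- l1_nonneg_factorize(stack$X, f = f, tol = tol, max_iter = max_iter,
                             n_init = n_init, seed = seed,
                             method = match.arg(method))
  # population variance of each loading column
  loading_var <- apply(fit$B, 2L, function(b) mean((b - mean(b))^2))
  eligible <- which(!fit$degenerate)
  if (length(eligible) == 0L)
    stop("all factors are degenerate (identically zero)")
  sel <- eligible[which.min(loading_var[eligible])]

  w <- if (threshold_scale == "subject")
    fit$A[, sel] * mean(fit$B[, sel]) else fit$A[, sel]
  scores <- unstack_network(w, K)
  binary <- (scores >= binarize_threshold) * 1L
  diag(binary) <- 0L
  mean_mat <- unstack_network(rowMeans(stack$X), K)
  weighted <- ifelse(binary == 1L, mean_mat, 0)
  if (!is.null(stack$node_labels)) {
    dimnames(binary) <- list(stack$node_labels, stack$node_labels)
    dimnames(weighted) <- dimnames(binary)
    dimnames(scores) <- dimnames(binary)
  }
  structure(
    list(binary = binary, weighted = weighted, scores = scores,
         selected_factor = sel, loading_variances = loading_var,
         factors = fit, threshold = binarize_threshold),
    class = "grand_average")
}

#' @export
print.grand_average <- function(x, ...) {
  cat("grand average: ", nrow(x$binary), " nodes, ", sum(x$binary),
      " connections\n", sep = "")
  cat("selected factor ", x$selected_factor, " of ",
      length(x$loading_variances), " (loading variances: ",
      paste(signif(x$loading_variances, 3), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Node degrees of a binary directed network
#'
#' Under the cell convention used throughout the package (entry (i, j) is
#' the influence j -> i), the in-degree of node v is its row sum and the
#' out-degree its column sum; the degree is their total, so summed over
#' all nodes it equals twice the edge count.
#'
#' @param mat binary K x K matrix with zero diagonal.
#' @return a data.frame with columns `node`, `in_degree`, `out_degree`,
#'   `degree`.
#' @export
degrees <- function(mat) {
  mat <- as.matrix(mat)
  .check_binary(mat, "mat")
  nodes <- rownames(mat)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(mat)))
  data.frame(node = nodes,
             in_degree = as.integer(rowSums(mat)),
             out_degree = as.integer(colSums(mat)),
             degree = as.integer(rowSums(mat) + colSums(mat)),
             stringsAsFactors = FALSE)
}
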