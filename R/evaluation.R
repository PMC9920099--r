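# Scoring of recovered grand averages against the generating ground truth,
# and the full seeded simulation harness. All counts and rates are over
# off-diagonal cells only (self-connections are excluded throughout).

.check_binary <- function(mat, name) {
  if (!all(mat %in% c(0, 1)))
    stop(name, " must be binary (0/1)")
  if (any(diag(as.matrix(mat)) != 0))
    stop(name, " must have a zero diagonal")
}

#' Confusion counts between an estimated and a true binary network
#'
#' Counts, over off-diagonal cells only: true positives (edges present in
#' both), false positives (absent in the truth, present in the estimate),
#' false negatives and true negatives. They always sum to `K * (K - 1)`.
#'
#' @param est estimated binary K x K matrix (zero diagonal).
#' @param gt ground-truth binary K x K matrix (zero diagonal), or a
#'   `ground_truth` object.
#' @return a list with integer fields `FP`, `TP`, `FN`, `TN`.
#' @export
confusion <- function(est, gt) {
  if (inherits(gt, "ground_truth")) gt <- gt$matrix
  est <- as.matrix(est)
  gt <- as.matrix(gt)
  if (!all(dim(est) == dim(gt)))
    stop("shape mismatch: est is ", paste(dim(est), collapse = "x"),
         ", gt is ", paste(dim(gt), collapse = "x"))
  .check_binary(est, "est")
  .check_binary(gt, "gt")
  off <- which(diag(nrow(gt)) == 0)
  e <- est[off]
  g <- gt[off]
  list(FP = sum(e == 1 & g == 0), TP = sum(e == 1 & g == 1),
       FN = sum(e == 0 & g == 1), TN = sum(e == 0 & g == 0))
}

#' False positive rate FP / (FP + TN)
#' @param c a confusion list as returned by [confusion()].
#' @return the false positive rate in \[0, 1\].
#' @export
fpr <- function(c) {
  if (c$FP + c$TN == 0) stop("FPR undefined: FP + TN = 0 (no true nulls)")
  c$FP / (c$FP + c$TN)
}

#' False negative rate FN / (TP + FN)
#' @param c a confusion list as returned by [confusion()].
#' @return the false negative rate in \[0, 1\].
#' @export
fnr <- function(c) {
  if (c$TP + c$FN == 0) stop("FNR undefined: TP + FN = 0 (no true edges)")
  c$FN / (c$TP + c$FN)
}

#' Mann-Whitney AUC of continuous edge scores against a binary truth
#'
#' Computes the area under the ROC curve as the Mann-Whitney statistic
#' of the off-diagonal scores for true-edge cells versus true-null cells,
#' with ties counted as half. Used on the selected factor's continuous
#' weights before binarization.
#'
#' @param scores K x K numeric matrix of edge scores.
#' @param gt binary K x K ground truth (or a `ground_truth` object) with
#'   at least one edge and one non-edge off the diagonal.
#' @return the AUC in \[0, 1\].
#' @export
auc <- function(scores, gt) {
  if (inherits(gt, "ground_truth")) gt <- gt$matrix
  scores <- as.matrix(scores)
  gt <- as.matrix(gt)
  if (!all(dim(scores) == dim(gt)))
    stop("shape mismatch between scores and gt")
  .check_binary(gt, "gt")
  off <- which(diag(nrow(gt)) == 0)
  s <- scores[off]
  g <- gt[off]
  n1 <- sum(g == 1)
  n0 <- sum(g == 0)
  if (n1 == 0 || n0 == 0)
    stop("degenerate ground truth: needs at least one edge and one non-edge")
  r <- rank(s)  # midranks: ties count half
  (sum(r[g == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the grand-average recovery simulation study
#'
#' For every combination of nodes `K`, subjects `S` and swap fraction `m`,
#' and for `T` iterations each: generates a fresh ground truth and subject
#' dataset, extracts the grand average at every factor count in `f`, and
#' scores it (FPR and FNR of the binarized network, AUC of the selected
#' factor's continuous weights). Within an iteration the same dataset is
#' factorized at each `f`, mirroring a study design where the factor count
#' is the analysis choice, not part of the data. All per-iteration seeds
#' derive deterministically from `seed`, so the returned table is
#' reproducible and iteration order is immaterial.
#'
#' @param K,S,m,f vectors of grid levels (nodes, subjects, swap fraction,
#'   factor count).
#' @param T_iter iterations per (K, S, m) cell.
#' @param seed master seed for the whole study.
#' @param density ground-truth edge density.
#' @param binarize_threshold threshold passed to [extract_grand_average()].
#' @param ... further solver options passed to [extract_grand_average()].
#' @return a data.frame with columns `iteration, K, S, m, f, seed, FPR,
#'   FNR, AUC, status`; extraction failures are recorded as rows with
#'   `status` holding the error message and NA metrics.
#' @examples
#' head(run_simulation(K = 10, S = 5, m = 0, f = 2, T_iter = 2, seed = 1))
#' @export
run_simulation <- function(K, S, m, f, T_iter = 100L, seed = NULL,
                           density = 0.1, binarize_threshold = 0.001, ...) {
  if (T_iter < 1) stop("T_iter must be >= 1")
  cells <- expand.grid(K = K, S = S, m = m, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # one dataset seed and one solver seed per (cell, iteration)
  seed_tab <- matrix(sample.int(.Machine$integer.max - 1L,
                                2L * nrow(cells) * T_iter),
                     ncol = 2L)
  rows <- vector("list", nrow(cells) * T_iter * length(f))
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    Kc <- cells$K[ci]; Sc <- cells$S[ci]; mc <- cells$m[ci]
    for (it in seq_len(T_iter)) {
      sd_pair <- seed_tab[(ci - 1L) * T_iter + it, ]
      ds <- generate_dataset(Kc, Sc, mc, density = density,
                             seed = sd_pair[1L])
      stack <- stack_subjects(ds$subjects)
      for (fc in f) {
        idx <- idx + 1L
        rec <- tryCatch({
          ga <- extract_grand_average(stack, f = fc,
                                      binarize_threshold = binarize_threshold,
                                      seed = sd_pair[2L] %% 2147483646L + fc,
                                      ...)
          cf <- confusion(ga$binary, ds$ground_truth)
          list(FPR = fpr(cf), FNR = fnr(cf),
               AUC = auc(ga$scores, ds$ground_truth), status = "ok")
        }, error = function(e)
          list(FPR = NA_real_, FNR = NA_real_, AUC = NA_real_,
               status = conditionMessage(e)))
        rows[[idx]] <- data.frame(
          iteration = it, K = Kc, S = Sc, m = mc, f = fc,
          seed = sd_pair[1L], FPR = rec$FPR, FNR = rec$FNR, AUC = rec$AUC,
          status = rec$status, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
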