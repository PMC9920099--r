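# Synthetic swapped-network datasets: a binary directed ground truth of
# fixed density, plus per-subject variants where a fraction of the edges is
# displaced to empty cells. Swaps preserve the edge count exactly, so every
# subject has the same density as the ground truth.

# round half away from zero (base round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

.offdiag_cells <- function(K) which(diag(K) == 0)

#' Generate a random binary directed ground-truth network
#'
#' Samples exactly `round(density * K * (K - 1))` distinct off-diagonal
#' cells uniformly without replacement and sets them to 1; the diagonal
#' (self-connections) is always zero. Density is counted over the
#' `K * (K - 1)` off-diagonal cells.
#'
#' @param K number of nodes (>= 2).
#' @param density target edge density in (0, 1); default 0.1.
#' @param seed optional integer seed.
#' @return an object of class `ground_truth`: list with `matrix` (K x K
#'   binary), `density`, and `edge_count`.
#' @examples
#' gt <- generate_ground_truth(20, 0.1, seed = 1)
#' gt$edge_count  # 38
#' @export
generate_ground_truth <- function(K, density = 0.1, seed = NULL) {
  if (K < 2) stop("K must be >= 2")
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  edge_count <- .round_half_up(density * K * (K - 1))
  if (edge_count < 1)
    stop("density ", density, " yields zero edges at K = ", K)
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(0L, K, K)
  mat[sample(.offdiag_cells(K), edge_count)] <- 1L
  structure(list(matrix = mat, density = density, edge_count = edge_count),
            class = "ground_truth")
}

#' Perturb a ground truth by swapping a fraction of its edges
#'
#' Removes `round(m * edge_count)` uniformly chosen existing edges and
#' places the same number of new edges uniformly among the cells that are
#' empty in the ground truth (off-diagonal, not currently edges, distinct
#' from each other). The subject network therefore keeps exactly
#' `edge_count` edges and shares exactly `edge_count - round(m * edge_count)`
#' of them with the ground truth.
#'
#' @param gt a `ground_truth` object.
#' @param m swap fraction in \[0, 1\] (the simulation's inter-subject
#'   noise level).
#' @param seed optional integer seed.
#' @return a binary K x K matrix with zero diagonal.
#' @export
perturb_subject <- function(gt, m, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (m < 0 || m > 1) stop("m must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(gt$matrix)
  n_swap <- .round_half_up(m * gt$edge_count)
  out <- gt$matrix
  if (n_swap == 0) return(out)
  edges <- which(out == 1L)
  empty <- setdiff(.offdiag_cells(K), edges)
  if (length(empty) < n_swap)
    stop("not enough empty off-diagonal cells (", length(empty),
         ") to place ", n_swap, " swapped edges")
  out[sample(edges, n_swap)] <- 0L
  out[sample(empty, n_swap)] <- 1L
  out
}

#' Generate a full synthetic subject dataset
#'
#' One fresh ground truth plus `S` independent swapped variants
#' (see [perturb_subject()]). All randomness derives from `seed`: the
#' ground-truth seed and one stream seed per subject are drawn from a
#' generator seeded with it, so the whole dataset is reproducible and the
#' subjects are mutually independent.
#'
#' @param K number of nodes.
#' @param S number of subjects.
#' @param m swap fraction per subject.
#' @param density ground-truth edge density; default 0.1.
#' @param seed optional integer seed.
#' @return an object of class `synthetic_dataset`: list with
#'   `ground_truth`, `subjects` (list of S binary matrices),
#'   `swap_fraction`, and `seed`.
#' @export
generate_dataset <- function(K, S, m, density = 0.1, seed = NULL) {
  if (S < 1) stop("S must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, S + 1L)
  gt <- generate_ground_truth(K, density, seed = sub_seeds[1L])
  subjects <- lapply(seq_len(S), function(s)
    perturb_subject(gt, m, seed = sub_seeds[s + 1L]))
  structure(list(ground_truth = gt, subjects = subjects,
                 swap_fraction = m, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground truth: ", nrow(x$matrix), " nodes, ", x$edge_count,
      " edges (density ", x$density, ")\n", sep = "")
  invisible(x)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  print(x$ground_truth)
  cat(length(x$subjects), "subjects, swap fraction", x$swap_fraction, "\n")
  invisible(x)
}
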