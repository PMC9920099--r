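# Shared fixtures: all test inputs are generated in code.

# random stable MVAR coefficient set: draws lag matrices and shrinks them
# until the companion matrix has spectral radius < 0.9
random_stable_mvar <- function(K, order, seed) {
  set.seed(seed)
  repeat {
    coeffs <- lapply(seq_len(order), function(p)
      matrix(rnorm(K * K, sd = 0.4 / p), K, K))
    comp <- matrix(0, K * order, K * order)
    comp[seq_len(K), ] <- do.call(cbind, coeffs)
    if (order > 1)
      comp[(K + 1):(K * order), seq_len(K * (order - 1))] <-
        diag(K * (order - 1))
    rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
    if (rho < 0.9) return(coeffs)
    coeffs <- NULL
  }
}

# brute-force L1 objective minimum for a 3x3 matrix, rank-1 factors with
# entries restricted to a coarse grid
grid_min_l1 <- function(X, grid = seq(0, 1, by = 0.25)) {
  avec <- as.matrix(expand.grid(grid, grid, grid))
  best <- Inf
  for (i in seq_len(nrow(avec))) {
    a <- avec[i, ]
    for (j in seq_len(nrow(avec))) {
      o <- sum(abs(X - outer(a, avec[j, ])))
      if (o < best) best <- o
    }
  }
  best
}

# a tiny manually-built PDC spectrum object for band-averaging tests
make_spectrum <- function(values, freqs, fs = 128) {
  structure(list(values = values, freqs = freqs, fs = fs),
            class = "pdc_spectrum")
}
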