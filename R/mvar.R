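# MVAR fitting for multichannel epochs. The model is the conventional
# vector autoregression Y(t) = sum_p A_p Y(t-p) + e(t); coefficients are
# estimated by ordinary least squares over lag-embedded rows stacked
# across trials (no lag ever crosses a trial boundary).

#' Construct a multichannel epochs object
#'
#' @param data numeric array, K channels x T samples x N trials; a K x T
#'   matrix is treated as a single trial.
#' @param fs sampling rate in Hz.
#' @param channel_names optional K channel labels (default from dimnames
#'   or ch1..chK).
#' @return an object of class `epochs`.
#' @export
epochs <- function(data, fs, channel_names = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    stop("data must be a K x T x N array")
  if (anyNA(data) || any(!is.finite(data)))
    stop("epochs must contain finite values only")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(channel_names)) channel_names <- dimnames(data)[[1L]]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[1L]))
  dimnames(data) <- list(channel_names, NULL, NULL)
  structure(list(data = data, fs = fs), class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("epochs: ", d[1L], " channels x ", d[2L], " samples x ", d[3L],
      " trials @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

# Lag-embedded regression blocks for one burn-in length. Returns the
# stacked response (rows x K) and design (rows x K*order) matrices.
.mvar_design <- function(data, order, burn) {
  K <- dim(data)[1L]; Tn <- dim(data)[2L]; N <- dim(data)[3L]
  rows_per <- Tn - burn
  Y <- matrix(0, rows_per * N, K)
  Z <- matrix(0, rows_per * N, K * order)
  for (n in seq_len(N)) {
    tr <- data[, , n, drop = FALSE]
    dim(tr) <- dim(data)[1:2]
    idx <- (n - 1L) * rows_per + seq_len(rows_per)
    Y[idx, ] <- t(tr[, (burn + 1L):Tn, drop = FALSE])
    for (p in seq_len(order))
      Z[idx, (p - 1L) * K + seq_len(K)] <-
        t(tr[, (burn + 1L - p):(Tn - p), drop = FALSE])
  }
  list(Y = Y, Z = Z)
}

.fit_mvar_burn <- function(ep, order, burn) {
  K <- dim(ep$data)[1L]; Tn <- dim(ep$data)[2L]; N <- dim(ep$data)[3L]
  if (Tn <= burn)
    stop("model order ", order, " >= trial length ", Tn)
  M <- N * (Tn - burn)
  if (M <= K * order)
    stop("not enough samples: ", M, " regression rows for ", K * order,
         " coefficients per channel (K = ", K, ", order = ", order, ")")
  de <- .mvar_design(ep$data, order, burn)
  qz <- qr(de$Z)
  if (qz$rank < ncol(de$Z))
    stop("singular regressor matrix (rank ", qz$rank, " < ", ncol(de$Z),
         "): channels are linearly dependent or constant (K = ", K, ")")
  theta <- qr.coef(qz, de$Y)                 # (K*order) x K
  resid <- de$Y - de$Z %*% theta
  noise_cov <- crossprod(resid) / M          # ML residual covariance
  noise_cov <- (noise_cov + t(noise_cov)) / 2
  coeffs <- lapply(seq_len(order), function(p)
    t(theta[(p - 1L) * K + seq_len(K), , drop = FALSE]))
  structure(list(order = as.integer(order), coeffs = coeffs,
                 noise_cov = noise_cov, fs = ep$fs, n_obs = M,
                 channel_names = dimnames(ep$data)[[1L]]),
            class = "mvar_model")
}

#' Fit a multivariate autoregressive model by least squares
#'
#' Minimizes the summed squared one-step prediction error over all trials;
#' trials are stacked at the regression level so no lagged predictor ever
#' crosses a trial boundary. `coeffs[[p]]` is the K x K coefficient matrix
#' at lag p of `Y(t) = sum_p coeffs[[p]] Y(t-p) + e(t)`; `noise_cov` is
#' the maximum-likelihood residual covariance.
#'
#' @param ep an `epochs` object.
#' @param order model order p >= 1.
#' @return an object of class `mvar_model` with fields `order`, `coeffs`,
#'   `noise_cov`, `fs`, `n_obs`.
#' @export
fit_mvar <- function(ep, order) {
  stopifnot(inherits(ep, "epochs"))
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  .fit_mvar_burn(ep, order, burn = order)
}

#' @export
print.mvar_model <- function(x, ...) {
  cat("MVAR(", x$order, ") model: ", nrow(x$noise_cov), " channels, ",
      x$n_obs, " regression rows @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Select the MVAR model order by AIC
#'
#' Fits every candidate order p in `1:max_order` with a fixed burn-in of
#' `max_order` samples, so that all candidates use the same regression
#' rows and their likelihoods are comparable, and returns the minimizer
#' of `AIC(p) = N_eff * ln det(noise_cov(p)) + 2 p K^2`.
#'
#' @param ep an `epochs` object.
#' @param max_order largest candidate order.
#' @return the selected order (integer).
#' @export
select_order_aic <- function(ep, max_order) {
  stopifnot(inherits(ep, "epochs"))
  max_order <- as.integer(max_order)
  if (max_order < 1L) stop("max_order must be >= 1")
  K <- dim(ep$data)[1L]
  aic <- vapply(seq_len(max_order), function(p) {
    m <- tryCatch(.fit_mvar_burn(ep, p, burn = max_order),
                  error = function(e)
                    stop("candidate order ", p, " failed: ",
                         conditionMessage(e), call. = FALSE))
    d <- determinant(m$noise_cov, logarithm = TRUE)
    m$n_obs * as.numeric(d$modulus) + 2 * p * K^2
  }, 0)
  which.min(aic)
}

#' Simulate from a stable MVAR model
#'
#' Utility for testing and null calibration: draws trials from
#' `Y(t) = sum_p coeffs[[p]] Y(t-p) + e(t)` with Gaussian innovations.
#'
#' @param coeffs list of K x K lag coefficient matrices.
#' @param T_samples samples per trial (after discarding a 200-sample
#'   burn-in).
#' @param n_trials number of trials.
#' @param fs sampling rate in Hz.
#' @param noise_sd innovation standard deviation (spherical).
#' @param seed optional integer seed.
#' @return an `epochs` object.
#' @export
simulate_mvar <- function(coeffs, T_samples, n_trials = 1L, fs = 128,
                          noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(coeffs[[1L]])
  P <- length(coeffs)
  burn <- 200L
  data <- array(0, dim = c(K, T_samples, n_trials))
  for (n in seq_len(n_trials)) {
    y <- matrix(0, K, T_samples + burn)
    e <- matrix(rnorm(K * (T_samples + burn), sd = noise_sd), K)
    for (t in seq.int(P + 1L, T_samples + burn)) {
      acc <- e[, t]
      for (p in seq_len(P)) acc <- acc + coeffs[[p]] %*% y[, t - p]
      y[, t] <- acc
    }
    data[, , n] <- y[, burn + seq_len(T_samples)]
  }
  epochs(data, fs)
}
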