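# Squared partial directed coherence from a fitted MVAR model, band
# averaging, and a surrogate-based binarization against the null of no
# directed coupling. Cell convention throughout: entry (i, j) is the
# influence of channel j on channel i.

#' Standard EEG frequency bands (Hz)
#'
#' Closed intervals for the theta (3-7), alpha (8-12), beta (13-30) and
#' gamma (31-40) bands.
#' @export
eeg_bands <- list(theta = c(3, 7), alpha = c(8, 12),
                  beta = c(13, 30), gamma = c(31, 40))

#' Spectral transfer matrix of an MVAR model
#'
#' \deqn{\Lambda_{ij}(f) = \delta_{ij} - \sum_{p=1}^{P} a_{ij}(p)
#'   e^{-\mathrm{i} 2\pi (f/f_s) p}}
#' where `a(p)` are the lag coefficient matrices of the fitted model and
#' the exponent uses the frequency normalized by the sampling rate.
#'
#' @param model an `mvar_model`.
#' @param freq frequency in Hz, `0 <= freq <= fs/2`.
#' @return a complex K x K matrix.
#' @export
transfer_matrix <- function(model, freq) {
  stopifnot(inherits(model, "mvar_model"))
  if (freq < 0 || freq > model$fs / 2)
    stop("freq must lie in [0, fs/2] = [0, ", model$fs / 2, "]")
  K <- nrow(model$noise_cov)
  lam <- diag(K) + 0i
  for (p in seq_len(model$order))
    lam <- lam - model$coeffs[[p]] * exp(-1i * 2 * pi * (freq / model$fs) * p)
  lam
}

#' Squared partial directed coherence spectrum
#'
#' For each frequency, the squared, column-normalized PDC
#' \deqn{\pi_{ij}(f) = |\Lambda_{ij}(f)|^2 / \sum_m |\Lambda_{mj}(f)|^2,}
#' so entry (i, j, f) measures the directed influence j -> i and every
#' column of every frequency slice sums to one.
#'
#' @param model an `mvar_model`.
#' @param freqs frequencies in Hz; default an integer grid from 1 Hz to
#'   `fs/2` capped at 40 Hz (the upper edge of the gamma band).
#' @return an object of class `pdc_spectrum`: list with `values`
#'   (K x K x F array) and `freqs`.
#' @export
pdc <- function(model, freqs = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  if (is.null(freqs)) freqs <- seq_len(min(floor(model$fs / 2), 40))
  K <- nrow(model$noise_cov)
  vals <- array(0, dim = c(K, K, length(freqs)))
  for (k in seq_along(freqs)) {
    lam2 <- Mod(transfer_matrix(model, freqs[k]))^2
    denom <- colSums(lam2)
    if (any(denom <= 0))
      stop("degenerate transfer matrix: column ", which(denom <= 0)[1L],
           " is identically zero at ", freqs[k], " Hz")
    vals[, , k] <- sweep(lam2, 2L, denom, "/")
  }
  dimnames(vals) <- list(model$channel_names, model$channel_names, NULL)
  structure(list(values = vals, freqs = freqs, fs = model$fs),
            class = "pdc_spectrum")
}

#' @export
print.pdc_spectrum <- function(x, ...) {
  cat("squared PDC spectrum: ", dim(x$values)[1L], " channels, ",
      length(x$freqs), " frequencies (", min(x$freqs), "-", max(x$freqs),
      " Hz)\n", sep = "")
  invisible(x)
}

#' Band-averaged PDC network
#'
#' Arithmetic mean of the squared PDC over the frequency bins inside the
#' closed interval `band`.
#'
#' @param spec a `pdc_spectrum`.
#' @param band length-2 numeric interval in Hz, or the name of a band in
#'   [eeg_bands] (e.g. `"alpha"`).
#' @return an object of class `band_network`: the K x K matrix with
#'   attributes `band` and `band_name`.
#' @export
band_average <- function(spec, band) {
  stopifnot(inherits(spec, "pdc_spectrum"))
  band_name <- NULL
  if (is.character(band)) {
    band_name <- band
    if (!band %in% names(eeg_bands))
      stop("unknown band '", band, "'; available: ",
           paste(names(eeg_bands), collapse = ", "))
    band <- eeg_bands[[band]]
  }
  sel <- spec$freqs >= band[1L] & spec$freqs <= band[2L]
  if (!any(sel))
    stop("band [", band[1L], ", ", band[2L],
         "] Hz contains none of the spectrum's frequencies")
  out <- apply(spec$values[, , sel, drop = FALSE], c(1L, 2L), mean)
  structure(out, band = band, band_name = band_name, class = "band_network")
}

#' @export
print.band_network <- function(x, ...) {
  b <- attr(x, "band")
  cat("band-averaged PDC network (", b[1L], "-", b[2L], " Hz), ",
      nrow(x), " channels\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

# Phase-randomized surrogate of one epochs object: each channel of each
# trial gets an independent random phase spectrum while its amplitude
# spectrum (hence autocorrelation) is preserved, destroying cross-channel
# coupling under the null.
.phase_randomize <- function(ep) {
  d <- dim(ep$data)
  out <- ep$data
  Tn <- d[2L]
  for (n in seq_len(d[3L])) {
    for (k in seq_len(d[1L])) {
      x <- ep$data[k, , n]
      X <- fft(x)
      nfree <- if (Tn %% 2L == 0L) Tn / 2L - 1L else (Tn - 1L) / 2L
      if (nfree > 0L) {
        ph <- runif(nfree, 0, 2 * pi)
        idx <- seq.int(2L, 1L + nfree)
        X[idx] <- Mod(X[idx]) * exp(1i * ph)
        X[Tn + 2L - idx] <- Conj(X[idx])
      }
      if (Tn %% 2L == 0L) X[Tn / 2L + 1L] <- Mod(X[Tn / 2L + 1L]) *
          sample(c(-1, 1), 1L)
      out[k, , n] <- Re(fft(X, inverse = TRUE)) / Tn
    }
  }
  epochs(out, ep$fs)
}

#' Binarize a connectivity network against a surrogate null
#'
#' Builds an empirical null distribution for every connection by
#' phase-randomizing the epochs (which preserves each channel's spectrum
#' but destroys cross-channel coupling), re-estimating the same statistic
#' (MVAR fit, squared PDC, band average) on each surrogate, and taking
#' the per-connection `(1 - alpha)` quantile as threshold. Observed
#' connections exceeding their threshold are set to 1; the diagonal is
#' forced to 0.
#'
#' @param observed the observed statistic: a `band_network` (or plain
#'   K x K matrix) computed from `ep`.
#' @param ep the `epochs` the statistic was computed from (K >= 2
#'   channels).
#' @param order MVAR model order used for the statistic.
#' @param band frequency band of the statistic (interval or band name);
#'   required unless `threshold_fn` is supplied.
#' @param freqs frequency grid passed to [pdc()] (default as there).
#' @param alpha significance level in (0, 1).
#' @param n_surrogates number of surrogates (>= 20).
#' @param seed optional integer seed.
#' @param threshold_fn optional replacement for the surrogate null: a
#'   function `(ep, order, band, freqs, alpha)` returning a K x K
#'   threshold matrix, e.g. an asymptotic-theory threshold.
#' @return a binary K x K matrix with zero diagonal.
#' @export
binarize_null <- function(observed, ep, order, band = NULL, freqs = NULL,
                          alpha = 0.05, n_surrogates = 100L, seed = NULL,
                          threshold_fn = NULL) {
  stopifnot(inherits(ep, "epochs"))
  K <- dim(ep$data)[1L]
  if (K < 2L) stop("binarization needs K >= 2 channels (no off-diagonal connections)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  obs <- unclass(as.matrix(observed))
  if (!is.null(threshold_fn)) {
    thr <- threshold_fn(ep, order, band, freqs, alpha)
  } else {
    if (n_surrogates < 20L) stop("n_surrogates must be >= 20")
    if (is.null(band)) stop("band is required for the surrogate null")
    if (!is.null(seed)) set.seed(seed)
    null_stats <- array(0, dim = c(K, K, n_surrogates))
    for (b in seq_len(n_surrogates)) {
      sur <- .phase_randomize(ep)
      null_stats[, , b] <- band_average(pdc(fit_mvar(sur, order), freqs), band)
    }
    thr <- apply(null_stats, c(1L, 2L), quantile, probs = 1 - alpha,
                 names = FALSE)
  }
  out <- (obs > thr) * 1L
  diag(out) <- 0L
  dimnames(out) <- dimnames(obs)
  out
}
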