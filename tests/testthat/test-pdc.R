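test_that("transfer matrix has the expected closed-form structure", {
  # all-zero coefficients -> identity at every frequency
  ep <- simulate_mvar(list(matrix(0, 2, 2)), 500, seed = 1)
  m0 <- fit_mvar(ep, 1)
  m0$coeffs[[1]][] <- 0
  for (fr in c(0, 10, 40))
    expect_equal(transfer_matrix(m0, fr), diag(2) + 0i)

  # univariate, coefficient 0.5, f = 0: Lambda = 1 - 0.5
  m1 <- structure(list(order = 1L, coeffs = list(matrix(0.5, 1, 1)),
                       noise_cov = matrix(1, 1, 1), fs = 128,
                       channel_names = "ch1"),
                  class = "mvar_model")
  expect_equal(transfer_matrix(m1, 0), matrix(0.5 + 0i, 1, 1))

  # diagonal model stays diagonal at every frequency
  md <- m0
  md$coeffs[[1]] <- diag(c(0.4, -0.3))
  for (fr in c(3, 17)) {
    lam <- transfer_matrix(md, fr)
    expect_equal(lam[1, 2], 0 + 0i)
    expect_equal(lam[2, 1], 0 + 0i)
  }
  expect_error(transfer_matrix(m1, 100), "fs/2")
})

test_that("squared PDC is column-normalized and respects zero coupling", {
  # univariate: trivially 1 everywhere
  ep1 <- simulate_mvar(list(matrix(0.5, 1, 1)), 500, seed = 2)
  sp1 <- pdc(fit_mvar(ep1, 1))
  expect_true(all(abs(sp1$values - 1) < 1e-12))

  # no influence 2 -> 1 in the generating model: pi_12 = 0 exactly when
  # the fitted coefficient is zeroed
  m <- fit_mvar(simulate_mvar(list(rbind(c(0.5, 0), c(0.4, 0.3))),
                              1000, seed = 3), 1)
  m$coeffs[[1]][1, 2] <- 0
  sp <- pdc(m)
  expect_true(all(sp$values[1, 2, ] == 0))

  # random stable models: columns sum to one, entries in [0, 1]
  for (s in 1:5) {
    cf <- random_stable_mvar(3, 2, seed = 30 + s)
    mm <- fit_mvar(simulate_mvar(cf, 600, seed = 60 + s), 2)
    v <- pdc(mm)$values
    expect_true(all(v >= 0 & v <= 1))
    expect_lt(max(abs(apply(v, c(2, 3), sum) - 1)), 1e-8)
  }
})

test_that("squared PDC is invariant to a common channel rescaling", {
  cf <- random_stable_mvar(3, 1, seed = 41)
  ep <- simulate_mvar(cf, 1500, seed = 42)
  ep_scaled <- epochs(ep$data * 7.3, ep$fs)
  v1 <- pdc(fit_mvar(ep, 1))$values
  v2 <- pdc(fit_mvar(ep_scaled, 1))$values
  expect_lt(max(abs(v1 - v2)), 1e-6)
})

test_that("band averaging takes the arithmetic mean over in-band bins", {
  K <- 2
  freqs <- 1:40
  vals <- array(0.25, dim = c(K, K, length(freqs)))
  sp <- make_spectrum(vals, freqs)

  # constant spectrum: the band average equals the constant
  expect_true(all(band_average(sp, c(8, 12)) == 0.25))

  # single-bin band returns that slice unchanged
  vals2 <- vals
  vals2[, , 10] <- matrix(c(0.1, 0.9, 0.4, 0.6), 2, 2)
  sp2 <- make_spectrum(vals2, freqs)
  expect_equal(unclass(band_average(sp2, c(10, 10))),
               vals2[, , 10], ignore_attr = TRUE)

  # theta band on a 1-Hz grid averages the slices at 3..7 Hz
  vals3 <- vals
  for (k in 3:7) vals3[, , k] <- matrix(k / 10, K, K)
  sp3 <- make_spectrum(vals3, freqs)
  expect_equal(unclass(band_average(sp3, "theta"))[1, 1], mean(3:7 / 10))

  expect_error(band_average(sp, c(50, 60)), "frequencies")
  expect_error(band_average(sp, "delta"), "unknown band")
})
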