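test_that("confusion counts partition the off-diagonal cells", {
  gt <- generate_ground_truth(20, 0.1, seed = 1)

  cf <- confusion(gt$matrix, gt)
  expect_equal(cf, list(FP = 0L, TP = 38L, FN = 0L, TN = 342L))

  all1 <- matrix(1L, 20, 20); diag(all1) <- 0L
  cf1 <- confusion(all1, gt)
  expect_equal(cf1, list(FP = 342L, TP = 38L, FN = 0L, TN = 0L))

  cf0 <- confusion(matrix(0L, 20, 20), gt)
  expect_equal(cf0$FN, 38L)
  expect_equal(cf0$TP, 0L)
  expect_equal(Reduce(`+`, cf0), 20L * 19L)

  expect_error(confusion(matrix(0, 3, 3), gt), "shape")
  expect_error(confusion(matrix(0.5, 20, 20), gt), "binary")
})

test_that("FPR and FNR follow their defining ratios", {
  expect_equal(fpr(list(FP = 2, TN = 358, TP = 0, FN = 0)), 2 / 360)
  expect_equal(fnr(list(FP = 0, TN = 0, TP = 38, FN = 0)), 0)
  expect_error(fpr(list(FP = 0, TN = 0, TP = 1, FN = 1)), "FP \\+ TN")
  expect_error(fnr(list(FP = 1, TN = 1, TP = 0, FN = 0)), "TP \\+ FN")
})

test_that("AUC equals the Mann-Whitney statistic with half-ties", {
  gt <- generate_ground_truth(10, 0.1, seed = 2)
  expect_equal(auc(gt$matrix + 0, gt), 1)
  expect_equal(auc(matrix(0.4, 10, 10), gt), 0.5)
  expect_equal(auc(1 - gt$matrix, gt), 0)
  expect_error(auc(matrix(0, 3, 3), matrix(0L, 3, 3)), "degenerate")

  # agrees with an independent ROC implementation on continuous scores
  skip_if_not_installed("pROC")
  set.seed(3)
  sc <- matrix(runif(100), 10, 10)
  off <- row(sc) != col(sc)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = gt$matrix[off], predictor = sc[off], quiet = TRUE,
    direction = "<")))
  expect_equal(auc(sc, gt), ref, tolerance = 1e-12)
})

test_that("the simulation harness is deterministic and fills its contract", {
  sim <- run_simulation(K = 20, S = 10, m = 0.1, f = 2, T_iter = 3,
                        seed = 42)
  expect_equal(nrow(sim), 3L)
  expect_named(sim, c("iteration", "K", "S", "m", "f", "seed",
                      "FPR", "FNR", "AUC", "status"))
  expect_true(all(sim$status == "ok"))
  expect_true(all(sim$FPR >= 0 & sim$FPR <= 1))
  expect_true(all(sim$AUC >= 0 & sim$AUC <= 1))

  sim2 <- run_simulation(K = 20, S = 10, m = 0.1, f = 2, T_iter = 3,
                         seed = 42)
  expect_identical(sim, sim2)

  # zero swap noise: perfect recovery at every iteration
  sim0 <- run_simulation(K = 20, S = 10, m = 0, f = c(2, 5), T_iter = 2,
                         seed = 7)
  expect_true(all(sim0$FPR == 0))
  expect_true(all(sim0$FNR == 0))
  expect_true(all(sim0$AUC == 1))
})

test_that("recovery degrades with factor count and noise, improves with subjects", {
  sim <- run_simulation(K = 20, S = c(10, 50), m = c(0.1, 0.5),
                        f = c(2, 10), T_iter = 10, seed = 11)
  agg <- aggregate(cbind(FPR, FNR, AUC) ~ S + m + f, sim, mean)
  for (mm in c(0.1, 0.5)) for (ss in c(10, 50)) {
    # more factors never help the false positive rate (Monte-Carlo slack)
    expect_gte(agg$FPR[agg$S == ss & agg$m == mm & agg$f == 10] + 0.005,
               agg$FPR[agg$S == ss & agg$m == mm & agg$f == 2])
  }
  for (mm in c(0.1, 0.5)) for (ff in c(2, 10)) {
    # larger cohorts mitigate the false positive rate
    expect_lte(agg$FPR[agg$S == 50 & agg$m == mm & agg$f == ff],
               agg$FPR[agg$S == 10 & agg$m == mm & agg$f == ff])
  }
  for (ss in c(10, 50)) for (ff in c(2, 10)) {
    # AUC does not improve when swap noise increases (Monte-Carlo slack)
    expect_lte(agg$AUC[agg$S == ss & agg$m == 0.5 & agg$f == ff],
               agg$AUC[agg$S == ss & agg$m == 0.1 & agg$f == ff] + 0.02)
  }
})
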