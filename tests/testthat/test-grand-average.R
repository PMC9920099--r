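test_that("stacking uses row-major vectorization and round-trips", {
  m <- rbind(c(0, 1), c(2, 3))
  st <- stack_subjects(list(m))
  expect_equal(st$X[, 1], c(0, 1, 2, 3))
  expect_equal(unstack_network(st$X[, 1], 2), m)

  mats <- list(matrix(runif(16), 4, 4), matrix(runif(16), 4, 4))
  st2 <- stack_subjects(mats)
  expect_equal(unstack_network(st2$X[, 2], 4), mats[[2]])

  expect_error(stack_subjects(list(matrix(-1, 2, 2))), "negative")
  expect_error(stack_subjects(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "matrices must be")
})

test_that("a stack of identical subjects is recovered exactly for every f", {
  ds <- generate_dataset(K = 15, S = 6, m = 0, seed = 31)
  st <- stack_subjects(ds$subjects)
  for (f in c(1, 3, 6)) {
    for (sd in c(1, 2)) {
      ga <- extract_grand_average(st, f = f, seed = sd)
      expect_equal(unname(ga$binary), ds$ground_truth$matrix,
                   ignore_attr = TRUE)
      # identical 0/1 subjects: the weighted network equals the binary one
      expect_equal(unname(ga$weighted), ds$ground_truth$matrix + 0,
                   ignore_attr = TRUE)
    }
  }
})

test_that("extraction is equivariant under node permutation", {
  ds <- generate_dataset(K = 12, S = 8, m = 0.1, seed = 32)
  set.seed(1)
  perm <- sample(12)
  mats_p <- lapply(ds$subjects, function(m) m[perm, perm])
  ga <- extract_grand_average(stack_subjects(ds$subjects), f = 2, seed = 5)
  ga_p <- extract_grand_average(stack_subjects(mats_p), f = 2, seed = 5)
  expect_equal(unname(ga_p$binary), unname(ga$binary[perm, perm]))
})

test_that("extraction does not depend on subject order", {
  ds <- generate_dataset(K = 12, S = 8, m = 0.1, seed = 33)
  set.seed(2)
  shuf <- sample(8)
  ga <- extract_grand_average(stack_subjects(ds$subjects), f = 2, seed = 6)
  ga_s <- extract_grand_average(stack_subjects(ds$subjects[shuf]), f = 2,
                                seed = 6)
  expect_equal(unname(ga_s$binary), unname(ga$binary))
})

test_that("weighted values are population means bounded by the subjects", {
  ds <- generate_dataset(K = 12, S = 8, m = 0.3, seed = 34)
  st <- stack_subjects(ds$subjects)
  ga <- extract_grand_average(st, f = 2, seed = 7)
  arr <- simplify2array(ds$subjects)
  mx <- apply(arr, c(1, 2), max)
  mn <- apply(arr, c(1, 2), min)
  on_cells <- ga$binary == 1
  expect_true(all(ga$weighted[on_cells] <= mx[on_cells] + 1e-12))
  expect_true(all(ga$weighted[on_cells] >= mn[on_cells] - 1e-12))
  expect_true(all(ga$weighted[!on_cells] == 0))
  # weighted is nonzero exactly where binary = 1 (mean of >= 1 positive
  # binary entries is positive)
  expect_identical(unname(ga$weighted > 0), unname(on_cells))
})

test_that("the binarization threshold separates factor weights as documented", {
  # identical weighted subjects whose unit-L1 factor has entries
  # 0.0005 / 0.5 / 0.4995: only the two cells above 0.001 survive
  m <- rbind(c(0, 0.5, 0.4995), c(0.0005, 0, 0), c(0, 0, 0))
  st <- stack_subjects(list(m, m, m))
  ga <- extract_grand_average(st, f = 1, seed = 1)
  expect_equal(sum(ga$binary), 2)
  expect_equal(ga$binary[1, 2], 1L)
  expect_equal(ga$binary[2, 1], 0L)  # 0.0005 falls below 0.001
  # the selected factor minimizes the loading variance
  expect_equal(ga$selected_factor,
               which.min(ga$loading_variances))
})

test_that("degrees follow the j-to-i cell convention", {
  # node 1: two incoming (row) and three outgoing (column) connections
  m <- matrix(0L, 5, 5)
  m[1, c(2, 3)] <- 1L           # incoming to node 1
  m[c(2, 4, 5), 1] <- 1L        # outgoing from node 1
  d <- degrees(m)
  expect_equal(d$in_degree[1], 2L)
  expect_equal(d$out_degree[1], 3L)
  expect_equal(d$degree[1], 5L)
  expect_equal(sum(d$degree), 2L * sum(m))

  expect_true(all(degrees(matrix(0, 3, 3))$degree == 0))
  expect_error(degrees(matrix(0.5, 2, 2)), "binary")
})
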