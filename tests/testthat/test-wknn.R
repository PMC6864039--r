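test_that("hand-computed inverse-distance example is reproduced", {
  # train x = 0 (neg), x = 1 (pos); query 0.25 with k = 2:
  # weights 4 and 4/3 give p_neg = 0.75, p_pos = 0.25
  m <- TrainedWKNN(cbind(c(0, 1)), c(0L, 1L), k = 2)
  p <- predictProba(m, 0.25)
  expect_equal(p$p_pos, 0.25)
  expect_equal(p$p_neg, 0.75)
  expect_equal(p$p_pos + p$p_neg, 1)
})

test_that("zero-distance queries take the coincident points' labels", {
  m <- TrainedWKNN(cbind(c(0, 1, 2)), c(1L, 0L, 0L), k = 3)
  expect_equal(predictProba(m, 0)$p_pos, 1)       # single coincident positive
  expect_equal(predictProba(m, 1)$p_pos, 0)       # single coincident negative
  # two coincident points with opposite labels split the mass evenly
  m2 <- TrainedWKNN(cbind(c(0, 0, 5)), c(1L, 0L, 0L), k = 2)
  expect_equal(predictProba(m2, 0)$p_pos, 0.5)
})

test_that("probabilities match the brute-force oracle on random problems", {
  set.seed(2024)
  for (rep in 1:20) {
    n <- sample(50:500, 1)
    d <- 5
    train <- matrix(rnorm(n * d), n, d)
    labels <- rbinom(n, 1, 0.3)
    k <- sample(1:n, 1)
    query <- matrix(rnorm(10 * d), 10, d)
    got <- wknnProbabilities(train, labels, query, k)[, 1, 1]
    ref <- apply(query, 1, function(qv) bruteForceWKNN(train, labels, qv, k))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("tied distances at the k-th neighbor expand the neighbor set", {
  # four training points all at distance 1 from the query; k = 2 must use all
  train <- cbind(c(1, 1, 1, -1))
  labels <- c(1L, 0L, 1L, 0L)
  p <- unname(wknnProbabilities(train, labels, matrix(0, 1, 1), 2L)[1, 1, 1])
  expect_equal(p, 0.5)   # equal weights over all four tied points

  # duplicated points beyond the k-th position must not be dropped
  train2 <- cbind(c(0.5, 1, 1, 1, 3))
  labels2 <- c(0L, 1L, 1L, 0L, 0L)
  p2 <- unname(wknnProbabilities(train2, labels2, matrix(0, 1, 1), 2L)[1, 1, 1])
  # neighbors: 0.5 (w=2) plus the three tied at distance 1 (w=1 each)
  expect_equal(p2, 2 / 5)
})

test_that("results are invariant to training row permutation", {
  set.seed(31)
  n <- 200
  train <- matrix(rnorm(n * 5), n, 5)
  labels <- rbinom(n, 1, 0.4)
  query <- matrix(rnorm(5 * 5), 5, 5)
  p1 <- wknnProbabilities(train, labels, query, c(7L, 30L))
  ord <- sample(n)
  p2 <- wknnProbabilities(train[ord, ], labels[ord], query, c(7L, 30L))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the multi-k path agrees with repeated single-k calls", {
  set.seed(77)
  n <- 300
  train <- matrix(rnorm(n * 5), n, 5)
  labels <- cbind(a = rbinom(n, 1, 0.2), b = rbinom(n, 1, 0.5))
  query <- matrix(rnorm(8 * 5), 8, 5)
  kg <- c(3L, 25L, 120L)
  multi <- wknnProbabilities(train, labels, query, kg)
  for (ki in seq_along(kg)) for (j in 1:2) {
    single <- wknnProbabilities(train, labels[, j], query, kg[ki])
    expect_equal(multi[, ki, j], single[, 1, 1], tolerance = 1e-12)
  }
})

test_that("symmetric training sets give an even split at full k", {
  # balanced labels placed symmetrically around the query
  train <- cbind(c(-2, -1, 1, 2))
  labels <- c(1L, 0L, 1L, 0L)
  p <- unname(wknnProbabilities(train, labels, matrix(0, 1, 1), 4L)[1, 1, 1])
  expect_equal(p, 0.5)
})

test_that("predictPatient guards the leave-one-patient-out contract", {
  fm <- cachedTinyCohort()$fm
  sp <- looSplit(fm, 1)
  pr <- predictPatient(sp$train, sp$test, "CNEC", 25L)
  expect_equal(nrow(pr), nrow(sp$test))     # one probability pair per voxel
  expect_true(all(abs(pr$p_pos + pr$p_neg - 1) < 1e-12))
  # identical inputs give identical outputs
  pr2 <- predictPatient(sp$train, sp$test, "CNEC", 25L)
  expect_identical(pr, pr2)
  expect_error(predictPatient(fm, sp$test, "CNEC", 25L), "overlap")
  expect_error(predictPatient(sp$train, sp$test, "CNEC", nrow(sp$train) + 1L),
               "exceeds|out of range")
})

test_that("well-separated phantom classes classify accurately at k = 25", {
  fm <- cachedTinyCohort()$fm
  accs <- numeric(0)
  for (id in unique(fm$patient_id)) {
    sp <- looSplit(fm, id)
    for (oc in c("CNEC", "MVP")) {
      col <- multiscaleMRI:::outcomeColumns()[match(oc, outcomeNames())]
      # the held-out class must exist in training for the check to be fair
      if (sp$test[[col]][1] == 1L && sum(tapply(sp$train[[col]],
          sp$train$patient_id, max)) == 0) next
      pr <- predictPatient(sp$train, sp$test, oc, 25L)
      accs <- c(accs, mean(as.integer(pr$p_pos > 0.5) == sp$test[[col]]))
    }
  }
  expect_gte(mean(accs), 0.9)
})
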