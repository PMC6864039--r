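test_that("Pearson transform reproduces hand-computed values", {
  half <- BackgroundDistribution("CNEC", 1, 1)
  expect_equal(pearsonChi2(1, half, 10), 10)            # k*(0.25/0.5 + 0.25/0.5)
  mvp <- BackgroundDistribution("MVP", 21, 979)         # q = 0.021
  expect_equal(pearsonChi2(0, mvp, 1), 0.021^2 / 0.021 + 0.021^2 / 0.979,
               tolerance = 1e-12)
  expect_equal(pearsonChi2(0, mvp, 1), 0.0215, tolerance = 5e-3)
  # null identity and strict growth in |p - q|
  q <- BackgroundDistribution("IDH1", 3, 7)
  expect_equal(pearsonChi2(q@pPos, q, 50), 0)
  ps <- seq(q@pPos, 1, length.out = 40)
  expect_true(all(diff(pearsonChi2(ps, q, 5)) > 0))
  degenerate <- new("BackgroundDistribution", outcome = "IDH1", pPos = 1,
                    pNeg = 0, nPos = 5, nNeg = 0)
  expect_error(pearsonChi2(0.5, degenerate, 1), "degenerate")
})

test_that("chi-square tail probabilities behave canonically", {
  expect_equal(chi2ToP(0, 1), 1)
  expect_equal(chi2ToP(3.841459, 1), 0.05, tolerance = 1e-6)
  grid <- seq(0, 30, length.out = 100)
  expect_true(all(diff(chi2ToP(grid, 1)) < 0))
  expect_error(chi2ToP(-1), "nonnegative")
})

test_that("BH step-up matches the hand example and the reference route", {
  res <- bhReject(c(0.01, 0.02, 0.04, 0.5), 0.05)
  expect_equal(res@reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res@threshold, 0.02)
  expect_false(any(bhReject(rep(1, 10), 0.05)@reject))
  expect_length(bhReject(numeric(0))@reject, 0)

  # equivalence with stats::p.adjust on random p-vectors
  set.seed(404)
  for (r in 1:200) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(c(1, 2, 0.5), 1)
    mine <- bhReject(p, 0.05)@reject
    ref <- p.adjust(p, method = "BH") <= 0.05
    expect_identical(mine, ref)
  }
})

test_that("BH controls the false discovery rate in simulation", {
  set.seed(808)
  reps <- 500; m <- 400
  fdp <- numeric(reps)
  for (r in seq_len(reps)) {
    p <- runif(m)                 # complete null: all discoveries are false
    rej <- bhReject(p, 0.05)@reject
    fdp[r] <- sum(rej) / max(1, sum(rej))
  }
  mc <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(fdp), 0.05 + 3 * mc)
})

test_that("accuracy averages over patients with rejected voxels only", {
  pred <- c(1, 1, 1, 0, 1, 1)
  truth <- c(1, 1, 0, 0, 0, 1)
  pid <- c(1, 1, 1, 1, 2, 2)
  rej <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  ca <- confusionAccuracy(pred, truth, pid, rej)
  expect_equal(unname(ca$perPatient), c(0.75, 0.5))
  expect_equal(ca$acc, 0.625)
  expect_equal(dim(ca$confusion[["1"]]), c(2, 2))
  # a patient with no rejections is excluded, not counted as zero
  rej2 <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(confusionAccuracy(pred, truth, pid, rej2)$acc, 0.75)
  # all correct everywhere
  expect_equal(confusionAccuracy(truth, truth, pid, rej)$acc, 1)
  # nothing rejected anywhere: undefined
  expect_true(is.na(confusionAccuracy(pred, truth, pid, rep(FALSE, 6))$acc))
})

test_that("sensitivity reports per-patient and pooled forms", {
  s <- sensitivity(c(10, 30), c(100, 100))
  expect_equal(s$perPatient, 20)
  expect_equal(s$pooled, 20)
  s2 <- sensitivity(c(10, 30), c(100, 300))
  expect_equal(s2$perPatient, 100 * mean(c(0.1, 0.1)))
  expect_equal(s2$pooled, 100 * 40 / 400)
  expect_equal(sensitivity(c(100, 50), c(100, 50))$perPatient, 100)
  expect_equal(sensitivity(c(0, 0), c(10, 10))$perPatient, 0)
})

test_that("k selection maximizes sensitivity under the accuracy floor", {
  tr <- data.frame(k = c(100, 200, 300), acc = c(0.99, 0.96, 0.90),
                   sens = c(2, 5, 50))
  expect_equal(optimizeK(tr)$kOpt, 200L)
  # no k qualifies
  tr2 <- data.frame(k = c(100, 200), acc = c(0.8, 0.9), sens = c(10, 20))
  expect_true(is.na(optimizeK(tr2)$kOpt))
  # NA accuracy (no rejections) never qualifies
  tr3 <- data.frame(k = c(100, 200), acc = c(NA, NA), sens = c(0, 0))
  expect_true(is.na(optimizeK(tr3)$kOpt))
  # ties in sensitivity break toward the smaller k
  tr4 <- data.frame(k = c(300, 100, 200), acc = c(1, 1, 1), sens = c(7, 7, 7))
  expect_equal(optimizeK(tr4)$kOpt, 100L)
  # single qualifying k
  tr5 <- data.frame(k = 400, acc = 0.97, sens = 1)
  expect_equal(optimizeK(tr5)$kOpt, 400L)
})

test_that("whole-brain map is consistent with the biopsy-space pipeline", {
  tiny <- cachedTinyCohort()
  fm <- tiny$fm
  id <- unique(fm$patient_id)[2]
  pvs <- tiny$normalized[[id]]
  bg <- backgroundDistribution(fm, "CNEC")
  map <- wholeBrainMap(fm, pvs, "CNEC", 25L, bg)

  expect_s4_class(map, "ChiSquareMap")
  expect_equal(map@space, "brain")
  expect_identical(dim(map@values), dim(pvs@brainMask))
  # defined exactly on the brain mask
  expect_true(all(is.na(map@values[!pvs@brainMask])))
  expect_true(all(is.finite(map@values[pvs@brainMask])))
  expect_true(all(map@values[pvs@brainMask] >= 0))

  # consistency oracle: biopsy voxels equal the leave-one-out per-voxel route
  sp <- looSplit(fm, id)
  pr <- predictPatient(sp$train, sp$test, "CNEC", 25L)
  chi2Ref <- pearsonChi2(pr$p_pos, bg, 1)
  dm <- dim(pvs@brainMask)
  bidx <- sp$test$voxel_i + (sp$test$voxel_j - 1L) * dm[1] +
    (sp$test$voxel_k - 1L) * dm[1] * dm[2]
  inBrain <- pvs@brainMask[bidx]
  expect_equal(map@values[bidx][inBrain], chi2Ref[inBrain], tolerance = 1e-10)

  expect_error(wholeBrainMap(fm, pvs, "CNEC", NA), "missing")
})
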