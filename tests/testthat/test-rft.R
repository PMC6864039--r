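test_that("chi-square fields Gaussianize with clipping", {
  expect_equal(chi2FieldToZ(0, df = 1), -8.2)        # p = 1 clips at the floor
  expect_equal(chi2FieldToZ(3.841459, df = 1), qnorm(0.95), tolerance = 1e-5)
  grid <- seq(0, 40, length.out = 101)
  z <- chi2FieldToZ(grid, df = 1)
  expect_true(all(diff(z) >= 0))
  expect_true(all(z <= 8.2 & z >= -8.2))
  # NA passes through (voxels outside the mask)
  expect_true(is.na(chi2FieldToZ(c(NA, 1), df = 1)[1]))
})

test_that("smoothness estimator recovers white-noise and 6 mm truths", {
  set.seed(3001)
  msk <- array(TRUE, dim = c(64, 64, 64))
  f <- array(rnorm(64^3), dim = c(64, 64, 64))
  sm <- estimateSmoothness(f, msk, c(1, 1, 1))
  # unsmoothed noise: lattice first differences imply sqrt(2 ln 2) ~ 1.18 vox
  expect_true(all(abs(sm@fwhm - 1) / 1 < 0.2))
  expect_equal(sm@resels, 64^3 / prod(sm@fwhm), tolerance = 1e-8)

  est <- replicate(10, {
    g <- smoothGaussianField(c(64, 64, 64), 6, c(1, 1, 1))
    mean(estimateSmoothness(g, msk, c(1, 1, 1))@fwhm)
  })
  expect_true(all(abs(est - 6) / 6 < 0.15))

  # doubling the spacing doubles the estimated FWHM in mm
  g <- smoothGaussianField(c(48, 48, 48), 5, c(1, 1, 1))
  s1 <- estimateSmoothness(g, array(TRUE, dim = dim(g)), c(1, 1, 1))
  s2 <- estimateSmoothness(g, array(TRUE, dim = dim(g)), c(2, 2, 2))
  expect_equal(s2@fwhm, 2 * s1@fwhm)

  expect_error(estimateSmoothness(array(1, dim = c(16, 16, 16)),
                                  array(TRUE, dim = c(16, 16, 16))),
               "zero variance")
  tinyMask <- array(FALSE, dim = c(16, 16, 16)); tinyMask[1:3, 1:3, 1:3] <- TRUE
  expect_error(estimateSmoothness(array(rnorm(16^3), dim = c(16, 16, 16)),
                                  tinyMask), "too few")
})

test_that("expected Euler characteristic has its known shape", {
  expect_equal(expectedEC(1, 1000), 0)              # density root at z = 1
  expect_equal(expectedEC(3, 2000), 2 * expectedEC(3, 1000))   # linear in resels
  z <- seq(2.5, 5, length.out = 30)
  expect_true(all(diff(expectedEC(z, 500)) < 0))    # decreasing beyond the mode
})

test_that("high-threshold exceedance matches the expected EC on null fields", {
  set.seed(3100)
  reps <- 200
  mx <- replicate(reps, max(smoothGaussianField(c(64, 64, 64), 6)))
  resels <- 64^3 / 6^3
  for (t in c(3.5, 4.0)) {
    pref <- min(1, expectedEC(t, resels))
    phat <- mean(mx > t)
    se <- sqrt(max(pref * (1 - pref), 0.002) / reps)
    expect_lt(abs(phat - pref), 4 * se + 0.02)
  }
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(3200)
  for (conn in c(26, 6)) {
    for (r in 1:5) {
      dm <- c(16L, 16L, 16L)
      mask <- array(runif(prod(dm)) < 0.12, dim = dm)
      got <- labelComponents(mask, conn)
      ref <- floodFillLabels(mask, conn)
      expect_equal(max(got), max(ref))
      expect_identical(canonicalComponents(got), canonicalComponents(ref))
    }
  }
  # two disjoint blobs with exact voxel counts
  m <- array(FALSE, dim = c(20, 20, 20))
  m[2:4, 2:4, 2:4] <- TRUE          # 27 voxels
  m[10:15, 10, 10] <- TRUE          # 6 voxels
  lab <- labelComponents(m, 26)
  expect_equal(max(lab), 2)
  expect_equal(sort(tabulate(lab[lab > 0])), c(6, 27))
})

test_that("cluster inference handles empty and structured fields", {
  msk <- array(TRUE, dim = c(24, 24, 24))
  sm <- new("SmoothnessEstimate", fwhm = c(3, 3, 3), resels = 24^3 / 27,
            dlh = (4 * log(2))^1.5 / 27, nMaskVoxels = 24^3,
            spacing = c(1, 1, 1))
  zero <- array(0, dim = c(24, 24, 24))
  ct0 <- clusterInference(zero, msk, sm, 3.3, 0.05)
  expect_equal(nrow(ct0@clusters), 0)
  expect_length(ct0@survivors, 0)

  # one large blob must survive; its p must be far below a tiny blob's
  f <- array(0, dim = c(24, 24, 24))
  f[6:14, 6:14, 6:14] <- 5
  f[20, 20, 20] <- 5
  ct <- clusterInference(f, msk, sm, 3.3, 0.05)
  expect_equal(nrow(ct@clusters), 2)
  big <- which.max(ct@clusters$size)
  expect_lt(ct@clusters$p[big], 0.05)
  expect_true(big %in% ct@survivors)
  expect_gt(ct@clusters$p[-big], ct@clusters$p[big])
  expect_equal(sum(survivingClusterMask(ct)),
               sum(ct@clusters$size[ct@clusters$label %in% ct@survivors]))
})

test_that("cluster p-values decrease in cluster size at fixed smoothness", {
  msk <- array(TRUE, dim = c(32, 32, 32))
  sm <- new("SmoothnessEstimate", fwhm = c(4, 4, 4), resels = 32^3 / 64,
            dlh = (4 * log(2))^1.5 / 64, nMaskVoxels = 32^3,
            spacing = c(1, 1, 1))
  ps <- sapply(c(2, 4, 8, 12), function(w) {
    f <- array(0, dim = c(32, 32, 32))
    f[seq_len(w) + 4, seq_len(w) + 4, seq_len(w) + 4] <- 5
    ct <- clusterInference(f, msk, sm, 3.3, 0.05)
    ct@clusters$p[1]
  })
  expect_true(all(diff(ps) < 0))
})
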