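test_that("a fixed seed reproduces the cohort exactly", {
  spec <- tinyPhantomSpec(seed = 123L, nPatients = 3L)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$pvs@contrasts[["T1w"]]@data,
                     b[[i]]$pvs@contrasts[["T1w"]]@data)
    expect_identical(a[[i]]$truth$trueLabels, b[[i]]$truth$trueLabels)
    expect_identical(vapply(a[[i]]$samples, function(s) s@coreVolume, 1),
                     vapply(b[[i]]$samples, function(s) s@coreVolume, 1))
  }
  # a different seed changes the data
  c <- generateCohort(tinyPhantomSpec(seed = 124L, nPatients = 3L))
  expect_false(identical(a[[1]]$pvs@contrasts[["T1w"]]@data,
                         c[[1]]$pvs@contrasts[["T1w"]]@data))
})

test_that("the noiseless limit places tumors exactly at the summed signature", {
  spec <- tinyPhantomSpec(seed = 5L, nPatients = 3L)
  spec@noiseSD <- 1e-9
  coh <- generateCohort(spec)
  for (p in coh) {
    pvs <- normalizeToWM(p$pvs)
    offset <- drop(p$truth$trueLabels %*% spec@signature)
    tm <- p$truth$tumorMask
    for (a in seq_along(contrastNames())) {
      vol <- pvs@contrasts[[contrastNames()[a]]]@data
      expect_equal(mean(vol[tm]), unname(1 + offset[a]), tolerance = 1e-5)
      expect_equal(mean(vol[!tm & pvs@brainMask]), 1, tolerance = 1e-5)
    }
  }
})

test_that("label margins and co-occurrence structure are as designed", {
  spec <- defaultPhantomSpec(seed = 99L)
  set.seed(spec@seed)
  lab <- multiscaleMRI:::drawCohortLabels(spec)
  npos <- colSums(lab$true)
  expect_equal(unname(npos), c(2, 1, 9, 8))     # fixed positive margins
  # structured co-occurrence: MVP+ within CNEC+, IDH1/MGMT outside CNEC+
  expect_true(all(lab$true[lab$true[, "MVP"] == 1, "CNEC"] == 1))
  expect_equal(sum(lab$true[, "IDH1"] & lab$true[, "CNEC"]), 0)
  expect_equal(sum(lab$true[, "MGMT"] & lab$true[, "IDH1"]), 0)
  # triage only ever hits true negatives => recorded equals true
  expect_true(all(lab$true[lab$triaged] == 0L))
  expect_identical(lab$recorded, lab$true)
})

test_that("triage margins concentrate near their expected counts", {
  spec <- defaultPhantomSpec()
  set.seed(1234)
  draws <- t(replicate(200, colSums(multiscaleMRI:::drawCohortLabels(spec)$triaged)))
  target <- spec@triageRate * spec@nPatients    # 18, 24, 11, 18
  for (j in 1:4)
    expect_lt(abs(mean(draws[, j]) - target[j]),
              3 * sqrt(var(draws[, j]) / 200) + 0.5)
})

test_that("positive patients carry shrunken sampled volumes", {
  coh <- cachedTinyCohort()$cohort
  spec <- tinyPhantomSpec()
  for (p in coh) {
    mult <- prod(spec@volumeFactor[p$truth$trueLabels == 1L])
    vols <- vapply(p$samples, function(s) s@coreVolume, 1)
    # log-normal(meanlog, sdlog) scaled by mult: all draws within 5 sd of meanlog
    expect_true(all(abs(log(vols / mult) - spec@coreVolumeMeanLog) <
                    5 * spec@coreVolumeSDLog))
  }
})

test_that("default spec validates and yields non-degenerate backgrounds", {
  spec <- defaultPhantomSpec()
  expect_true(validObject(spec))
  fm <- cachedTinyCohort()$fm
  for (oc in outcomeNames()) {
    bg <- backgroundDistribution(fm, oc)
    expect_gt(bg@pPos, 0)
    expect_lt(bg@pPos, 1)
  }
})

test_that("cohort disk round trip reproduces the feature matrix", {
  coh <- generateCohort(tinyPhantomSpec(seed = 21L, nPatients = 3L))
  dir <- file.path(tempdir(), "cohort-rt")
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_length(back, 3)

  fmA <- buildFeatureMatrix(lapply(seq_along(coh), function(i)
    extractBiopsyVoxels(normalizeToWM(coh[[i]]$pvs), coh[[i]]$samples)))
  fmB <- buildFeatureMatrix(lapply(seq_along(back), function(i)
    extractBiopsyVoxels(normalizeToWM(back[[i]]$pvs), back[[i]]$samples)))
  expect_equal(dim(fmA), dim(fmB))
  expect_equal(fmA$t1w, fmB$t1w, tolerance = 1e-5)
  expect_identical(fmA$idh1, fmB$idh1)
  expect_identical(fmA$prov_mgmt, fmB$prov_mgmt)
  unlink(dir, recursive = TRUE)
})

test_that("biopsy sample invariants hold for generated cores", {
  coh <- cachedTinyCohort()$cohort
  smp <- coh[[1]]$samples[[1]]
  expect_equal(smp@sphere@radius, radiusFromVolume(smp@coreVolume))
  expect_true(all(smp@outcomes[smp@provenance == "triaged"] == 0L))
  # validity enforcement: a triaged positive is rejected
  expect_error(new("BiopsySample", patientId = 1L,
                   sphere = SphereROI(c(0, 0, 0), radiusFromVolume(100)),
                   coreVolume = 100,
                   outcomes = c(IDH1 = 1L, MGMT = 0L, CNEC = 0L, MVP = 0L),
                   provenance = c(IDH1 = "triaged", MGMT = "tested",
                                  CNEC = "tested", MVP = "tested")),
               "triaged")
})
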