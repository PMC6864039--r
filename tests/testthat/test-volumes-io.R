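test_that("radiusFromVolume inverts the sphere volume", {
  expect_equal(radiusFromVolume(4 * pi / 3), 1.0)
  expect_equal(radiusFromVolume(8 * 4 * pi / 3), 2.0)
  expect_equal(radiusFromVolume(4119.5), 9.944, tolerance = 1e-3)
  expect_error(radiusFromVolume(0), "positive")
  expect_error(radiusFromVolume(-5), "positive")
  # strictly increasing in volume
  v <- sort(runif(50, 1, 5000))
  expect_true(all(diff(radiusFromVolume(v)) > 0))
})

test_that("sphereMask matches an exhaustive per-voxel distance check", {
  geom <- list(dim = c(11L, 11L, 11L), spacing = c(1, 1, 1),
               origin = c(-5, -5, -5))
  roi <- SphereROI(c(0.3, -0.7, 0.2), 2.5)
  msk <- sphereMask(roi, geom)
  ref <- array(FALSE, dim = geom$dim)
  for (i in 1:11) for (j in 1:11) for (k in 1:11) {
    w <- geom$origin + (c(i, j, k) - 1) * geom$spacing
    ref[i, j, k] <- sqrt(sum((w - roi@center)^2)) <= roi@radius
  }
  expect_identical(msk, ref)
})

test_that("a sub-voxel sphere on a voxel center captures exactly one voxel", {
  geom <- list(dim = c(9L, 9L, 9L), spacing = c(1, 1, 1), origin = c(-4, -4, -4))
  msk <- sphereMask(SphereROI(c(0, 0, 0), 0.5), geom)
  expect_equal(sum(msk), 1)
  expect_true(msk[5, 5, 5])
  # an empty rasterization warns rather than errors
  expect_warning(sphereMask(SphereROI(c(0.5, 0.5, 0.5), 0.2), geom), "empty")
  # zero radius violates the ROI invariant
  expect_error(SphereROI(c(0, 0, 0), 0), "positive")
})

test_that("rasterized sphere volume converges to the analytic volume", {
  vol <- 65   # mm^3; radius ~2.49 mm
  r <- radiusFromVolume(vol)
  geom <- list(dim = c(32L, 32L, 32L), spacing = c(0.25, 0.25, 0.25),
               origin = -c(31, 31, 31) / 2 * 0.25)
  msk <- sphereMask(SphereROI(c(0, 0, 0), r), geom)
  expect_equal(sum(msk) * 0.25^3, vol, tolerance = 0.05)
})

test_that("white-matter normalization is exact, idempotent, scale-invariant", {
  spec <- tinyPhantomSpec()
  coh <- generateCohort(tinyPhantomSpec(nPatients = 2L))
  pvs <- coh[[1]]$pvs
  geom <- gridGeometry(pvs)
  wm <- sphereMask(pvs@wmROI, geom)

  norm1 <- normalizeToWM(pvs)
  for (nm in contrastNames())
    expect_equal(mean(norm1@contrasts[[nm]]@data[wm]), 1.0, tolerance = 1e-12)

  # uniform volume normalizes to exactly 1 everywhere
  uni <- pvs
  for (nm in contrastNames()) uni@contrasts[[nm]]@data[] <- 200
  nuni <- normalizeToWM(uni)
  expect_equal(range(nuni@contrasts[["T1w"]]@data), c(1, 1))

  # idempotent
  norm2 <- normalizeToWM(norm1)
  expect_equal(norm2@contrasts[["ADC"]]@data, norm1@contrasts[["ADC"]]@data)

  # scale-invariant: scaling one raw contrast by c > 0 changes nothing
  scaled <- pvs
  scaled@contrasts[["T2w"]]@data <- scaled@contrasts[["T2w"]]@data * 37.5
  nscaled <- normalizeToWM(scaled)
  expect_equal(nscaled@contrasts[["T2w"]]@data, norm1@contrasts[["T2w"]]@data,
               tolerance = 1e-12)
})

test_that("simple voxel arithmetic of normalization holds", {
  # voxel at 300 with a reference mean of 200 normalizes to 1.5
  dm <- c(9L, 9L, 9L)
  arr <- array(200, dim = dm)
  arr[2, 2, 2] <- 300
  contrasts <- setNames(lapply(contrastNames(), function(nm) arr), contrastNames())
  pvs <- PatientVolumeSet(1L, contrasts, array(TRUE, dm),
                          SphereROI(c(2, 2, 2), 2))
  # reference region excludes the hot voxel
  pvs@wmROI <- SphereROI(c(-2, -2, -2), 1.4)
  npvs <- normalizeToWM(pvs)
  expect_equal(npvs@contrasts[["T1w"]]@data[2, 2, 2], 1.5)
})

test_that("NIfTI round trip preserves voxel values and geometry", {
  coh <- generateCohort(tinyPhantomSpec(seed = 11L, nPatients = 2L))
  pvs <- coh[[1]]$pvs
  dir <- file.path(tempdir(), "rt-patient")
  paths <- writePatient(pvs, dir)
  back <- readPatient(as.list(paths),
                      list(patient_id = 1L, wm_center = pvs@wmROI@center,
                           wm_radius = pvs@wmROI@radius))
  for (nm in contrastNames())
    expect_equal(back@contrasts[[nm]]@data, pvs@contrasts[[nm]]@data,
                 tolerance = 1e-6)
  expect_equal(gridGeometry(back)$spacing, gridGeometry(pvs)$spacing)
  expect_equal(gridGeometry(back)$origin, gridGeometry(pvs)$origin,
               tolerance = 1e-5)
  expect_identical(back@brainMask, pvs@brainMask)
  unlink(dir, recursive = TRUE)
})

test_that("readPatient reports missing contrasts and grid mismatches", {
  coh <- generateCohort(tinyPhantomSpec(seed = 12L, nPatients = 2L))
  dir <- file.path(tempdir(), "bad-patient")
  paths <- writePatient(coh[[1]]$pvs, dir)
  short <- as.list(paths[setdiff(names(paths), "T2-FLAIR")])
  expect_error(readPatient(short, list(patient_id = 1L, wm_center = c(8, 0, 0),
                                       wm_radius = 3)),
               "missing contrast T2-FLAIR")

  # shrink one volume: the error must name both shapes
  small <- coh[[2]]$pvs@contrasts[["T2w"]]@data[1:16, 1:16, 1:16]
  multiscaleMRI:::writeNiftiVolume(small, paths[["T2w"]], c(1, 1, 1), c(0, 0, 0))
  expect_error(readPatient(as.list(paths),
                           list(patient_id = 1L, wm_center = c(8, 0, 0),
                                wm_radius = 3)),
               "16x16x16")
  unlink(dir, recursive = TRUE)
})
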