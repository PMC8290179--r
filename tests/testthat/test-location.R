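test_that("slice diameter equals the closed-form and brute-force values", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE
  expect_equal(sliceDiameter(m), 0)             # single voxel: no pair
  expect_equal(sliceDiameter(matrix(FALSE, 4, 4)), 0)
  m[2, 2] <- FALSE; m[1, 1] <- m[4, 5] <- TRUE
  expect_equal(sliceDiameter(m), 5)             # 3-4-5 triangle
  expect_equal(sliceDiameter(m, spacing = c(2, 2)), 10)
  expect_error(sliceDiameter(array(TRUE, c(2, 2, 2))), "2D")
})

test_that("slice diameter matches the all-pairs oracle on random blobs", {
  for (seed in c(7, 21, 99)) {
    m <- randomMask(seed, 25, 25, 200)
    for (sp in list(c(1, 1), c(0.5, 2)))
      expect_identical(sliceDiameter(m, sp), bruteDiameter(m, sp))
  }
})

test_that("location features recover known ellipsoid geometry", {
  shape <- c(48, 48, 32)
  bm <- array(TRUE, shape)
  # centered sphere: offsets ~0 relative to brain centroid, slice = center
  res <- makeLabeledVolume(shape, tumorSpec(c(24, 24, 16), c(8, 8, 6)))
  lf <- extractLocationFeatures(res$volume, brainMask = bm)
  expect_equal(lf@sliceIndex, 16L)
  expect_lt(abs(lf@xOffsetMM - (24 - 24.5)), 0.5)
  expect_lt(abs(lf@yOffsetMM - (24 - 24.5)), 0.5)

  # known offset from brain centroid (di = 6, dj = -4)
  res2 <- makeLabeledVolume(shape, tumorSpec(c(30, 20, 16), c(7, 5, 6)))
  lf2 <- extractLocationFeatures(res2$volume, brainMask = bm)
  expect_lt(abs(lf2@xOffsetMM - (30 - 24.5)), 0.5)
  expect_lt(abs(lf2@yOffsetMM - (20 - 24.5)), 0.5)
  expect_equal(lf2@sliceIndex, 16L)
  expect_lt(abs(lf2@diameterMM - 14), sqrt(2))

  expect_error(extractLocationFeatures(
    labeledVolume(array(0L, c(4, 4, 4))), brainMask = array(TRUE, c(4, 4, 4))),
    "empty tumor")
})

test_that("equal maximal diameters resolve to the lower slice index", {
  vox <- array(0L, c(10, 10, 6))
  vox[2:6, 5, 2] <- 1L   # identical bars on slices 2 and 4
  vox[2:6, 5, 4] <- 1L
  lf <- extractLocationFeatures(labeledVolume(vox),
                                brainMask = array(TRUE, c(10, 10, 6)))
  expect_equal(lf@sliceIndex, 2L)
})

test_that("diameter is translation invariant; offsets track the shift", {
  vox <- array(0L, c(32, 32, 8))
  blob <- randomMask(13, 10, 10, 25)
  vox[6:15, 6:15, 4][blob] <- 2L
  bm <- array(TRUE, c(32, 32, 8))
  base <- extractLocationFeatures(labeledVolume(vox), brainMask = bm)
  shifted <- array(0L, c(32, 32, 8))
  shifted[14:23, 11:20, 4][blob] <- 2L   # +8 in i, +5 in j
  sh <- extractLocationFeatures(labeledVolume(shifted), brainMask = bm)
  expect_equal(sh@diameterMM, base@diameterMM)
  expect_equal(sh@xOffsetMM - base@xOffsetMM, 8)
  expect_equal(sh@yOffsetMM - base@yOffsetMM, 5)
})

test_that("features scale linearly with voxel spacing", {
  res <- makeLabeledVolume(c(24, 24, 16), tumorSpec(c(14, 10, 8), c(5, 4, 4)))
  bm <- array(TRUE, c(24, 24, 16))
  v1 <- extractLocationFeatures(res$volume, brainMask = bm)
  vox2 <- labeledVolume(voxels(res$volume), spacing = c(2, 2, 2))
  v2 <- extractLocationFeatures(vox2, brainMask = bm)
  expect_equal(v2@diameterMM, 2 * v1@diameterMM)
  expect_equal(v2@xOffsetMM, 2 * v1@xOffsetMM)
  expect_equal(v2@yOffsetMM, 2 * v1@yOffsetMM)
  expect_equal(v2@sliceIndex, v1@sliceIndex)
})

test_that("enlarging the tumor mask never shrinks the diameter", {
  set.seed(17)
  for (rep in 1:5) {
    vox <- array(0L, c(20, 20, 10))
    idx <- cbind(sample(20, 30, TRUE), sample(20, 30, TRUE),
                 sample(10, 30, TRUE))
    vox[idx[1:15, ]] <- 1L
    small <- extractLocationFeatures(labeledVolume(vox),
                                     brainMask = array(TRUE, dim(vox)))
    vox[idx] <- 1L
    big <- extractLocationFeatures(labeledVolume(vox),
                                   brainMask = array(TRUE, dim(vox)))
    expect_gte(big@diameterMM, small@diameterMM)
  }
})

test_that("tumor label subsets and brain-mask errors behave", {
  vox <- array(0L, c(16, 16, 8))
  vox[4:6, 4:6, 4] <- 2L      # edema away from core
  vox[10:12, 10:12, 4] <- 1L  # core
  bm <- array(TRUE, dim(vox))
  whole <- extractLocationFeatures(labeledVolume(vox), brainMask = bm)
  core <- extractLocationFeatures(labeledVolume(vox), tumorLabels = c(1L, 4L),
                                  brainMask = bm)
  expect_gt(whole@diameterMM, core@diameterMM)
  expect_error(extractLocationFeatures(labeledVolume(vox),
                                       brainMask = array(TRUE, c(2, 2, 2))),
               "shape")
})
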