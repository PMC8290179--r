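test_that("unit-radius ellipsoid voxelizes to the 6-neighbourhood ball", {
  res <- makeLabeledVolume(c(9, 9, 9),
                           tumorSpec(c(5, 5, 5), c(1, 1, 1),
                                     shellFractions = 1, shellLabels = 2L))
  vox <- voxels(res$volume)
  # oracle: enumerate voxels satisfying the closed ellipsoid inequality
  inside <- which(vox != 0, arr.ind = TRUE)
  expect_lte(nrow(inside), 7)
  for (r in seq_len(nrow(inside)))
    expect_lte(sum((inside[r, ] - 5)^2), 1 + 1e-12)
  expect_equal(res$truth$maxSlice, 5)
})

test_that("voxelized sphere diameter matches the analytic value", {
  res <- makeLabeledVolume(c(31, 31, 31),
                           tumorSpec(c(16, 16, 16), c(10, 10, 10)))
  mask <- voxels(res$volume)[, , 16] != 0
  d <- bruteDiameter(mask)
  expect_lt(abs(d - 20), sqrt(2))   # within one voxel diagonal of 20 mm
  expect_equal(res$truth$diameterMM, 20)
  expect_error(makeLabeledVolume(c(9, 9, 9), tumorSpec(c(5, 5, 5), c(0, 1, 1))),
               "radii")
  expect_error(makeLabeledVolume(c(9, 9, 9), tumorSpec(c(5, 5, 5), c(6, 1, 1))),
               "exceeds grid")
})

test_that("intensity generator is exact when noiseless and seeded when not", {
  res <- makeLabeledVolume(c(16, 16, 12), tumorSpec(c(8, 8, 6), c(4, 3, 3)))
  means <- c("0" = 10, "1" = 50, "2" = 30, "4" = 80)
  iv <- makeIntensityVolume(res$volume, means, biasAmplitude = 0, noiseSD = 0)
  expect_equal(unname(voxels(iv)[1, 1, 1]), 10)
  expect_true(all(voxels(iv)[voxels(res$volume) == 4] == 80))

  a <- makeIntensityVolume(res$volume, means, noiseSD = 5, seed = 9)
  b <- makeIntensityVolume(res$volume, means, noiseSD = 5, seed = 9)
  expect_identical(voxels(a), voxels(b))
  expect_error(makeIntensityVolume(res$volume, c("0" = 1)), "missing tissue")
})

test_that("single-tissue noise variance matches the requested SD", {
  vol <- labeledVolume(array(0L, c(30, 30, 12)))
  iv <- makeIntensityVolume(vol, c("0" = 100), noiseSD = 5, seed = 4)
  v <- var(as.vector(voxels(iv)))   # >= 1e4 voxels
  expect_lt(abs(v - 25) / 25, 0.2)
})

test_that("feature blocks reach the requested correlation", {
  res <- makeFeatureTable(500, nBlocks = 1, blockSize = 5,
                          withinBlockCorr = 0.99, seed = 11)
  r <- cor(as.matrix(res$table))
  offdiag <- r[upper.tri(r)]
  expect_true(all(offdiag > 0.95))

  # zero correlation: empirical |r| small at n = 200
  res0 <- makeFeatureTable(200, nBlocks = 2, blockSize = 4,
                           withinBlockCorr = 0, nNoiseFeatures = 4, seed = 12)
  r0 <- cor(as.matrix(res0$table))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.2)

  expect_equal(unname(res$blockMap["blk1_f1"]), 1)
  expect_error(makeFeatureTable(1, 1, 2, 0.5), "at least 2")
  expect_error(makeFeatureTable(10, 1, 2, 1), "withinBlockCorr")
})

test_that("cohort generator follows the linear survival model and clips", {
  lf <- list(A = locationFeatureSet(10, 30, 5, 10))
  mod <- survivalModelSpec(400, c(Y = -15), noiseSD = 0)
  coh <- makeCohort(lf, mod, seed = 1)
  expect_equal(survivalDays(coh), 250)   # 400 - 15*10

  high <- survivalModelSpec(5000, noiseSD = 0)
  expect_equal(survivalDays(makeCohort(lf, high, seed = 1)), 1767)
  low <- survivalModelSpec(-10, noiseSD = 0)
  expect_equal(survivalDays(makeCohort(lf, low, seed = 1)), 3)

  # all-zero coefficients: everyone gets the intercept
  lfs <- lapply(1:5, function(i) locationFeatureSet(i, i, i, i))
  names(lfs) <- paste0("P", 1:5)
  flat <- makeCohort(lfs, survivalModelSpec(700, noiseSD = 0), seed = 1)
  expect_equal(survivalDays(flat), rep(700, 5))

  expect_error(makeCohort(list(), mod), "empty")
  expect_error(makeCohort(lf, survivalModelSpec(1, c(Qq = 2))), "unknown")
})

test_that("generators are pure functions of their seed", {
  s1 <- makeSyntheticStudy(nPatients = 12, seed = 33)
  s2 <- makeSyntheticStudy(nPatients = 12, seed = 33)
  expect_identical(as.matrix(s1$location), as.matrix(s2$location))
  expect_identical(as.matrix(s1$radiomics), as.matrix(s2$radiomics))
  expect_identical(as.data.frame(s1$cohort), as.data.frame(s2$cohort))
  s3 <- makeSyntheticStudy(nPatients = 12, seed = 34)
  expect_false(identical(as.matrix(s1$radiomics), as.matrix(s3$radiomics)))
})
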