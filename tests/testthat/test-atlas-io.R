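test_that("masks and volumes round-trip through NIfTI", {
  g <- tinyGrid(5)
  m <- sphereMask(g, 2.5, c(1, 0, -1))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(m, path)
  back <- readVolume(path)
  expect_equal(back@data, maskArray(m) * 1, tolerance = 1e-6)
  expect_equal(gridOrigin(back@grid), gridOrigin(g), tolerance = 1e-6)
  expect_equal(voxelSpacing(back@grid), voxelSpacing(g), tolerance = 1e-6)

  atlas <- buildProbabilisticAtlas(smallCohort(2), "STN", "L")
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(atlas, p2)
  back2 <- readVolume(p2, kind = "probability")
  expect_equal(back2@data, atlas@data, tolerance = 1e-6)
})

test_that("non-RAS storage is normalized without moving voxels in the world", {
  g <- tinyGrid(4, spacing = 1)
  m <- emptyMask(g)
  m@data[3, 4, 5] <- TRUE          # world coordinate (-2, -1, 0)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(m, path)
  img <- RNifti::readNifti(path)
  RNifti::orientation(img) <- "LPS" # store flipped on disk
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, p2)
  back <- readVolume(p2)
  hit <- which(back@data > 0.5, arr.ind = TRUE)
  expect_equal(nrow(hit), 1)
  expect_equal(unname(drop(indexToMm(back@grid, hit - 1))), c(-2, -1, 0))
})

test_that("declared probability maps are range-checked", {
  g <- tinyGrid(3, spacing = 1)
  bad <- new("BrainVolume", grid = g,
             data = array(1.2, gridDim(g)), space = "MNI", kind = "scalar")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(bad, path)
  expect_error(readVolume(path, kind = "probability"), "\\[0, 1\\]")
})

test_that("probability thresholding is strict and monotone", {
  atlas <- buildProbabilisticAtlas(smallCohort(3), "STN", "L")
  support <- thresholdProbability(atlas, 0)
  expect_identical(maskArray(support), atlas@data > 0)
  expect_false(any(maskArray(thresholdProbability(atlas, 1))))
  m25 <- maskArray(thresholdProbability(atlas, 0.25))
  m75 <- maskArray(thresholdProbability(atlas, 0.75))
  expect_true(all(m25[m75]))        # higher level is a subset
  expect_true(all(maskArray(support)[m25]))
  expect_error(thresholdProbability(atlas, 1.5), "\\[0, 1\\]")
})

test_that("conjunct masking is an idempotent, commutative intersection", {
  g <- tinyGrid(8)
  a <- sphereMask(g, 3, c(-1, 0, 0))
  b <- sphereMask(g, 3, c(2, 0, 0))
  expect_identical(maskArray(conjunctMasks(a, a)), maskArray(a))
  expect_identical(maskArray(conjunctMasks(a, b)),
                   maskArray(a) & maskArray(b))
  expect_identical(maskArray(conjunctMasks(a, b)),
                   maskArray(conjunctMasks(b, a)))
  far <- sphereMask(g, 1.5, c(3.5, 3.5, 0))
  expect_false(any(maskArray(conjunctMasks(a, far))))
  expect_error(conjunctMasks(a, sphereMask(tinyGrid(7), 2)), "different grids")
})

test_that("centres of mass are intensity-weighted and translation-equivariant", {
  g <- tinyGrid(4, spacing = 1)
  v <- new("BrainVolume", grid = g, data = array(0, gridDim(g)), space = "MNI",
           kind = "scalar")
  v@data[3, 4, 5] <- 2.5
  expect_equal(centerOfMassMm(v), drop(indexToMm(g, c(2, 3, 4))))
  sph <- sphereMask(tinyGrid(6), 3, c(1, 1, -2))
  expect_equal(centerOfMassMm(sph), c(1, 1, -2), tolerance = 1e-9)
  # brute-force weighted-sum oracle on an arbitrary volume
  set.seed(2)
  v@data[] <- stats::runif(length(v@data))
  acc <- c(0, 0, 0); tot <- 0
  for (i in 1:gridDim(g)[1]) for (j in 1:gridDim(g)[2]) for (k in 1:gridDim(g)[3]) {
    w <- v@data[i, j, k]
    acc <- acc + w * indexToMm(g, c(i, j, k) - 1); tot <- tot + w
  }
  expect_equal(centerOfMassMm(v), acc / tot, tolerance = 1e-12)
  # shifting the grid origin shifts the centre of mass identically
  v2 <- v; v2@grid@origin <- v@grid@origin + c(3, -2, 7)
  expect_equal(centerOfMassMm(v2), centerOfMassMm(v) + c(3, -2, 7),
               tolerance = 1e-9)
  empty <- new("BrainVolume", grid = g, data = array(0, gridDim(g)),
               space = "MNI", kind = "scalar")
  expect_error(centerOfMassMm(empty), "empty")
})
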