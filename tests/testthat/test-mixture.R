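test_that("centre voxel is the grid voxel nearest the centre of mass", {
  g <- tinyGrid(6)
  one <- emptyMask(g)
  one@data[10, 12, 14] <- TRUE
  expect_equal(centerVoxel(one), indexToMm(g, c(9, 11, 13)))
  sph <- sphereMask(g, 3, c(1, -2, 0.5))
  expect_equal(centerVoxel(sph), c(1, -2, 0.5))
  expect_error(centerVoxel(emptyMask(g)), "empty")
})

test_that("a C-shaped mask falls back to the nearest in-mask voxel", {
  g <- tinyGrid(6)
  cmask <- emptyMask(g)
  # ring of voxels at radius ~3 mm in the z = 0 plane, open on one side:
  # the centre of mass lies near the origin, outside the mask itself
  coords <- which(array(TRUE, gridDim(g)), arr.ind = TRUE)
  mm <- indexToMm(g, coords - 1L)
  r <- sqrt(mm[, 1]^2 + mm[, 2]^2)
  ring <- r > 2.4 & r < 3.6 & mm[, 3] == 0 & mm[, 1] < 2
  cmask@data[coords[ring, , drop = FALSE]] <- TRUE
  com <- colMeans(mm[ring, , drop = FALSE])
  comIdx <- mmToIndex(g, com)
  expect_false(cmask@data[matrix(comIdx + 1L, 1)])
  # brute-force nearest in-mask voxel
  inMask <- mm[ring, , drop = FALSE]
  want <- unname(inMask[which.min(rowSums(sweep(inMask, 2, com)^2)), ])
  expect_equal(centerVoxel(cmask), want)
})

test_that("a delta kernel attributes all signal to the nucleus at the point", {
  g <- tinyGrid(12)
  stn <- sphereMask(g, 3)
  sn <- sphereMask(g, 3.5, c(0, 0, -7))
  mix <- mixtureAtPoint(c(0, 0, 0), stn, sn, kernelSpec(0))
  expect_identical(mix@fromStn, 1)
  expect_identical(mix@fromSn, 0)
  expect_identical(mix@fromElsewhere, 0)
  mixSn <- mixtureAtPoint(c(0, 0, -7), stn, sn, kernelSpec(0))
  expect_identical(mixSn@fromSn, 1)
})

test_that("fractions are proper and sum to one across kernel sizes", {
  g <- tinyGrid(12)
  stn <- sphereMask(g, 3)
  sn <- sphereMask(g, 3.5, c(0, 0, -7))
  for (f in c(0, 1, 2.5, 4, 8, 12)) {
    mix <- mixtureAtPoint(c(0.5, -0.5, 0), stn, sn, kernelSpec(f))
    fr <- c(mix@fromStn, mix@fromSn, mix@fromElsewhere)
    expect_true(all(fr >= 0 & fr <= 1))
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
})

test_that("spherical-mask mixtures match the chi-3 closed form", {
  g <- tinyGrid(10)
  r <- 3.06
  stn <- sphereMask(g, r)
  sn <- emptyMask(g)
  # the worked example: sigma for FWHM 8 gives ~15.3% self-capture
  mix8 <- mixtureAtPoint(c(0, 0, 0), stn, sn, kernelSpec(8))
  expect_equal(mix8@fromStn, 0.153, tolerance = 0.01)
  for (sigma in c(1, 1.7, 2.5, 3.3973)) {
    mix <- mixtureAtPoint(c(0, 0, 0), stn, sn,
                          kernelSpec(sigmaToFwhm(sigma)))
    expect_equal(mix@fromStn, chi3Mass(r, sigma), tolerance = 0.01)
    expect_equal(mix@fromStn, sphereFraction(r, sigma), tolerance = 0.01)
  }
})

test_that("results are insensitive to the truncation radius", {
  co <- smallCohort(1)
  s <- co[[1]]
  pt <- centerVoxel(s@stnL)
  for (f in c(2, 4, 8)) {
    m4 <- mixtureAtPoint(pt, s@stnL, s@snL, kernelSpec(f, truncation = 4))
    m6 <- mixtureAtPoint(pt, s@stnL, s@snL, kernelSpec(f, truncation = 6))
    expect_lt(abs(m4@fromStn - m6@fromStn), 1e-4)
    expect_lt(abs(m4@fromSn - m6@fromSn), 1e-4)
    expect_lt(abs(m4@fromElsewhere - m6@fromElsewhere), 1e-4)
  }
})

test_that("own-nucleus capture decreases monotonically with FWHM", {
  co <- smallCohort(2)
  sim <- simulateCohort(co, 0:10)
  ev <- curveEvaluations(sim)
  own <- ev[ev$source == ev$destination, ]
  for (key in split(own, list(own$subject, own$hemisphere, own$destination))) {
    key <- key[order(key$fwhm_mm), ]
    expect_true(all(diff(key$fraction) <= 1e-12))
    expect_identical(key$fraction[key$fwhm_mm == 0], 1)
  }
})

test_that("cohort curves aggregate to unit totals per destination", {
  co <- smallCohort(2)
  sim <- simulateCohort(co, c(0, 4, 8))
  tot <- stats::aggregate(mean_fraction ~ fwhm_mm + destination,
                          data = sim@summary, FUN = sum)
  expect_equal(tot$mean_fraction, rep(1, nrow(tot)))
})

test_that("mismatched grids are rejected", {
  g1 <- tinyGrid(6); g2 <- tinyGrid(7)
  expect_error(mixtureAtPoint(c(0, 0, 0), sphereMask(g1, 2), sphereMask(g2, 2),
                              kernelSpec(4)), "share a grid")
})
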