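fixtureFoci <- loadFoci()

test_that("the packaged literature table parses and validates", {
  expect_equal(length(unique(fixtureFoci$study_id)), 52)
  expect_equal(nrow(fixtureFoci), 122)
  # unspecified coordinates are retained as missing rows
  ns <- fixtureFoci[is.na(fixtureFoci$x), ]
  expect_gt(nrow(ns), 0)
  expect_true(all(!is.na(ns$study_id)))
})

test_that("malformed tables are rejected with the offending row", {
  bad <- fixtureFoci[1:3, ]
  bad$structure[2] <- "STM"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(loadFoci(path, manifest = NULL), "STM.*row 2")
  bad2 <- fixtureFoci[1:3, ]
  bad2$x <- as.character(bad2$x); bad2$x[3] <- "12,5"
  utils::write.csv(bad2, path, row.names = FALSE)
  expect_error(loadFoci(path, manifest = NULL), "non-numeric")
})

test_that("kernel summary reproduces the literature statistics", {
  ks <- kernelSummary(fixtureFoci)
  expect_equal(ks$median, 6)
  expect_equal(ks$mode, 8)
  expect_equal(ks$nModeStudies, 16)
  expect_equal(ks$mean, 6.3, tolerance = 0.5 / 6.3)
  # degenerate case: a single kernel everywhere
  flat <- fixtureFoci
  flat$fwhm_mm <- 5
  kf <- kernelSummary(flat)
  expect_equal(kf$mean, 5); expect_equal(kf$median, 5)
  expect_equal(kf$mode, 5); expect_equal(kf$nModeStudies, 52)
})

test_that("voxel-volume summary reproduces the literature statistics", {
  vs <- voxelSummary(fixtureFoci)
  expect_equal(vs$mean, 34, tolerance = 0.5 / 34)
  expect_equal(vs$range, c(3.38, 103.82))
  one <- voxelSummary(fixtureFoci[1, , drop = FALSE])
  expect_equal(one$nReporting, 1)
  expect_true(is.na(one$sd))
})

test_that("the Talairach transform is an invertible affine", {
  pts <- rbind(c(0, 0, 0), c(10, -15, -5), c(-42, 31, 7))
  expect_equal(mniToTal(talToMni(pts)), pts, tolerance = 1e-9)
  expect_equal(talToMni(mniToTal(pts)), pts, tolerance = 1e-9)
  # affinity: f(a + t b) - f(a) is linear in t
  a <- c(3, -8, 2); b <- c(1, 2, -1)
  d1 <- talToMni(a + b) - talToMni(a)
  d3 <- talToMni(a + 3 * b) - talToMni(a)
  expect_equal(d3, 3 * d1, tolerance = 1e-9)
  # the origin maps to the inverse matrix's translation column
  M <- rbind(c(0.9357, 0.0029, -0.0072, -1.0423),
             c(-0.0065, 0.9396, -0.0726, -1.3940),
             c(0.0103, 0.0752, 0.8967, 3.6475),
             c(0, 0, 0, 1))
  expect_equal(talToMni(c(0, 0, 0)), solve(M)[1:3, 4], tolerance = 1e-12)
})

test_that("hemisphere assignment puts the midline with the right", {
  expect_identical(assignHemisphere(c(-12, 0, 8)), c("L", "R", "R"))
  expect_error(assignHemisphere(c(1, NA)), "missing")
})

test_that("deviation statistics match hand-computed and brute-force values", {
  refs <- data.frame(structure = c("STN", "STN", "SN", "SN"),
                     hemisphere = c("L", "R", "L", "R"),
                     x = c(-10, 10, -9, 9), y = c(-13, -13, -16, -16),
                     z = c(-7, -7, -12, -12), source = "user_supplied")
  atCom <- data.frame(study_id = "s1", task = "t", field_strength_t = 3,
                      voxel_volume_mm3 = 27, fwhm_mm = 6, structure = "STN",
                      space = "MNI", x = -10, y = -13, z = -7,
                      slice_gap = FALSE, excluded_from_figure = FALSE)
  d0 <- deviationStats(atCom, refs)
  expect_equal(unlist(d0[c("mean_dx", "mean_dy", "mean_dz", "mean_total")]),
               c(mean_dx = 0, mean_dy = 0, mean_dz = 0, mean_total = 0))
  off <- atCom; off$x <- -7; off$z <- -3   # 3-4-5 triangle
  d1 <- deviationStats(off, refs)
  expect_equal(d1$mean_total, 5)
  expect_equal(d1$mean_dx, 3); expect_equal(d1$mean_dz, 4)

  # full-fixture brute-force oracle: per-focus loop, no shared code path
  dev <- deviationStats(fixtureFoci, refs)
  f <- fixtureFoci[!is.na(fixtureFoci$x), ]
  for (i in seq_len(nrow(dev))) {
    grp <- dev[i, ]
    rows <- f[f$structure == grp$structure_group &
                ifelse(f$x < 0, "L", "R") == grp$hemisphere, ]
    rs <- if (grp$structure_group == "STN") "STN" else "SN"
    r <- refs[refs$structure == rs & refs$hemisphere == grp$hemisphere, ]
    dx <- rows$x - r$x; dy <- rows$y - r$y; dz <- rows$z - r$z
    expect_equal(grp$n_coordinates, nrow(rows))
    expect_equal(grp$n_studies, length(unique(rows$study_id)))
    expect_identical(grp$mean_dx, mean(dx))
    expect_identical(grp$sd_dy, stats::sd(dy))
    expect_identical(grp$mean_total, mean(sqrt(dx^2 + dy^2 + dz^2)))
  }
})

test_that("left-hemisphere group sizes match the published table", {
  refs <- data.frame(structure = c("STN", "STN", "SN", "SN"),
                     hemisphere = c("L", "R", "L", "R"),
                     x = c(-10, 10, -9, 9), y = -14, z = c(-7, -7, -12, -12),
                     source = "user_supplied")
  dev <- deviationStats(fixtureFoci, refs)
  pick <- function(s, h) dev[dev$structure_group == s & dev$hemisphere == h, ]
  expect_equal(pick("SN", "L")$n_coordinates, 12)
  expect_equal(pick("SN", "L")$n_studies, 9)
  expect_equal(pick("SN/VTA", "L")$n_coordinates, 17)
  expect_equal(pick("STN", "L")$n_coordinates, 20)
  expect_equal(pick("STN", "L")$n_studies, 12)
  # the lone right-hemisphere SN/STN focus
  expect_equal(pick("SN/STN", "R")$n_coordinates, 1)
})

test_that("summaries are invariant under row permutation", {
  set.seed(5)
  shuffled <- fixtureFoci[sample(nrow(fixtureFoci)), ]
  expect_equal(kernelSummary(shuffled), kernelSummary(fixtureFoci))
  expect_equal(voxelSummary(shuffled), voxelSummary(fixtureFoci))
  refs <- data.frame(structure = c("STN", "STN", "SN", "SN"),
                     hemisphere = c("L", "R", "L", "R"),
                     x = c(-10, 10, -9, 9), y = -14, z = c(-7, -7, -12, -12),
                     source = "user_supplied")
  a <- deviationStats(shuffled, refs); b <- deviationStats(fixtureFoci, refs)
  expect_equal(a[order(a$structure_group, a$hemisphere), ],
               b[order(b$structure_group, b$hemisphere), ],
               ignore_attr = TRUE)
})

test_that("coordinate-kernel correlation behaves on synthetic and fixture data", {
  lin <- data.frame(study_id = paste0("s", 1:6), structure = "SN",
                    fwhm_mm = 1:6, x = NA, y = NA, z = 2 * (1:6) + 3)
  expect_equal(coordKernelCorrelation(lin, "SN", "z")$r, 1)
  lin$z <- -lin$z
  expect_equal(coordKernelCorrelation(lin, "SN", "z")$r, -1)
  lin$fwhm_mm <- 4
  expect_error(coordKernelCorrelation(lin, "SN", "z"), "constant")
  # SN-type z coordinates shift superior with larger kernels
  snz <- coordKernelCorrelation(fixtureFoci)
  expect_gt(snz$r, 0)
  expect_equal(snz$df, sum(fixtureFoci$structure %in% c("SN", "SN/VTA", "SN/STN") &
                             !is.na(fixtureFoci$z) & !is.na(fixtureFoci$fwhm_mm)) - 2)
})

test_that("ROI-to-nucleus volume ratios reproduce the motivating example", {
  expect_equal(roiVolumeRatio(1000, 1000), 1)
  expect_equal(roiVolumeRatio(1000, 131.75), 7.59, tolerance = 1e-3)
  expect_equal(roiVolumeRatio(1000, 119.88), 8.34, tolerance = 1e-3)
  expect_error(roiVolumeRatio(-1, 5), "positive")
})
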