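# shared fixtures, built in code at test time

# small empty grid centred on the origin
tinyGrid <- function(half = 12, spacing = 0.5) {
  makeGrid(c(-half, -half, -half), c(half, half, half), spacing)
}

# spherical mask of a given radius centred on a voxel centre
sphereMask <- function(grid, radius, center = c(0, 0, 0)) {
  generateNucleusMask(grid, nucleusGeometry(center, c(1, 1, 1),
                                            4 / 3 * pi * radius^3))
}

emptyMask <- function(grid) {
  new("BinaryMask", grid = grid, data = array(FALSE, gridDim(grid)))
}

# a small, quick cohort at the default anatomy
smallCohort <- function(n = 2, seed = 1, ...) {
  generateCohort(cohortConfig(nSubjects = n, seed = seed, maxFwhm = 8, ...))
}

# chi-3 CDF via the incomplete gamma function: an oracle for sphereFraction
# and spherical-mask mixtures that shares no code with the implementation
chi3Mass <- function(radius, sigma) stats::pgamma((radius / sigma)^2 / 2, 3 / 2)
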