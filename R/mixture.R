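# converged 1-D lattice sum of a Gaussian: sum over the (conceptually
# infinite) voxel-centre lattice along one axis of exp(-d^2 / (2 sigma^2)),
# where d is the signed distance from `point` and the lattice has the given
# spacing and phase. Terms beyond 9 sigma are below double precision noise.
latticeSum1d <- function(spacing, sigma, phase = 0) {
  if (sigma == 0) return(1)
  K <- as.integer(ceiling(9 * sigma / spacing)) + 1L
  d <- phase + (-K:K) * spacing
  sum(exp(-d^2 / (2 * sigma^2)))
}

# total kernel mass over the full lattice aligned with `grid`, relative to
# `point` (the product of per-axis sums)
latticeTotalMass <- function(grid, point, sigma) {
  prod(vapply(1:3, function(d) {
    ph <- (grid@origin[d] - point[d]) %% grid@spacing[d]
    latticeSum1d(grid@spacing[d], sigma[d], ph)
  }, numeric(1)))
}

# unnormalised Gaussian mass of a set of voxel centres (n x 3 mm matrix)
# around `point`, restricted to the per-axis truncation box
rawGaussMass <- function(coords, point, sigma, truncation) {
  if (!nrow(coords)) return(0)
  keep <- rep(TRUE, nrow(coords))
  e <- numeric(nrow(coords))
  for (d in 1:3) {
    dd <- coords[, d] - point[d]
    if (sigma[d] == 0) keep <- keep & abs(dd) < 1e-9
    else {
      keep <- keep & abs(dd) <= truncation * sigma[d]
      e <- e + dd^2 / (2 * sigma[d]^2)
    }
  }
  sum(exp(-e[keep]))
}

#' Centre voxel of a binary mask
#'
#' Returns the mm centre of the grid voxel nearest the mask's binary centre
#' of mass. If that voxel falls outside the mask (possible for non-convex
#' shapes), the nearest in-mask voxel is returned instead, breaking distance
#' ties by lowest linear index.
#'
#' @param mask a [BinaryMask-class] (non-empty).
#' @return mm triple.
#' @export
centerVoxel <- function(mask) {
  coords <- maskCoords(mask)
  if (!nrow(coords)) stop("empty mask")
  com <- unname(colMeans(coords))
  idx <- pmin(pmax(mmToIndex(mask@grid, com), 0L), mask@grid@dim - 1L)
  if (mask@data[matrix(idx + 1L, 1)])
    return(indexToMm(mask@grid, idx))
  d2 <- rowSums(sweep(coords, 2L, com)^2)
  unname(coords[which.min(d2), ])
}

#' Signal-origin decomposition at a point
#'
#' Evaluates the Gaussian kernel centred at `point` over the voxel centres of
#' the STN and SN masks, giving the unnormalised mass sums
#' \deqn{mass_X = \sum_{v \in X} \exp\!\big(-\textstyle\sum_d (v_d - p_d)^2 / 2\sigma_d^2\big),}
#' then divides by the total kernel mass over the full voxel lattice so that
#' a unit-strength signal everywhere yields fractions summing to one. The
#' remainder is attributed to tissue outside both nuclei. A zero-FWHM kernel
#' is treated as a delta: all signal comes from the voxel at `point`.
#'
#' @param point mm triple, usually a [centerVoxel()].
#' @param stn,sn [BinaryMask-class] objects on the same grid.
#' @param kernel a [KernelSpec-class].
#' @return a [MixtureFractions-class].
#' @export
mixtureAtPoint <- function(point, stn, sn, kernel) {
  if (!identical(stn@grid, sn@grid))
    stop("STN and SN masks must share a grid")
  if (any(stn@data & sn@data)) stop("STN and SN masks overlap")
  grid <- stn@grid
  rel <- (point - grid@origin) / grid@spacing
  if (any(rel < -0.5) || any(rel > grid@dim - 0.5))
    stop("'point' lies outside the grid")
  sigma <- kernel@sigma
  if (all(sigma == 0)) {
    idx <- pmin(pmax(mmToIndex(grid, point), 0L), grid@dim - 1L)
    cell <- matrix(idx + 1L, 1)
    fStn <- as.numeric(stn@data[cell]); fSn <- as.numeric(sn@data[cell])
    return(new("MixtureFractions", fromStn = fStn, fromSn = fSn,
               fromElsewhere = 1 - fStn - fSn,
               rawMassStn = fStn, rawMassSn = fSn))
  }
  if (any(sigma == 0)) stop("mixed zero/non-zero sigma axes are not supported")
  mStn <- rawGaussMass(maskCoords(stn), point, sigma, kernel@truncation)
  mSn <- rawGaussMass(maskCoords(sn), point, sigma, kernel@truncation)
  tot <- latticeTotalMass(grid, point, sigma)
  new("MixtureFractions", fromStn = mStn / tot, fromSn = mSn / tot,
      fromElsewhere = 1 - (mStn + mSn) / tot,
      rawMassStn = mStn, rawMassSn = mSn)
}

setMethod("show", "MixtureFractions", function(object) {
  cat(sprintf("MixtureFractions: STN %.1f%%, SN %.1f%%, elsewhere %.1f%%\n",
              100 * object@fromStn, 100 * object@fromSn,
              100 * object@fromElsewhere))
})

#' Simulate signal mixing across a cohort and kernel sizes
#'
#' For every subject, hemisphere and FWHM, evaluates [mixtureAtPoint()] at the
#' centre voxel of each destination nucleus (STN and SN) and records the
#' fraction of signal originating from each source (STN, SN, elsewhere).
#'
#' @param cohort list of [SubjectAnatomy-class] from [generateCohort()].
#' @param fwhms numeric vector of kernel FWHMs in mm.
#' @param truncation kernel support half-width in sigmas.
#' @return a [SimulationCurves-class].
#' @export
simulateCohort <- function(cohort, fwhms, truncation = 6) {
  if (!length(cohort)) stop("empty cohort")
  if (!length(fwhms)) stop("empty FWHM list")
  rows <- vector("list", 0L)
  for (subj in cohort) {
    for (h in c("L", "R")) {
      stn <- subjectMask(subj, "STN", h)
      sn <- subjectMask(subj, "SN", h)
      centers <- list(STN = centerVoxel(stn), SN = centerVoxel(sn))
      for (f in fwhms) {
        kern <- kernelSpec(f, truncation)
        for (dest in c("STN", "SN")) {
          mix <- tryCatch(
            mixtureAtPoint(centers[[dest]], stn, sn, kern),
            error = function(e) stop(sprintf("subject %d hemisphere %s: %s",
                                             subj@subject, h, conditionMessage(e))))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj@subject, hemisphere = h, fwhm_mm = f,
            destination = dest, source = c("STN", "SN", "elsewhere"),
            fraction = c(mix@fromStn, mix@fromSn, mix@fromElsewhere))
        }
      }
    }
  }
  ev <- do.call(rbind, rows)
  new("SimulationCurves", evaluations = ev, summary = curveSummary(ev))
}

#' Summarise mixture evaluations into cohort curves
#'
#' @param evaluations data.frame as in [SimulationCurves-class] (or the object
#'   itself).
#' @return data.frame of mean and SD fraction per FWHM x destination x source.
#'   At every FWHM and destination the mean fractions over sources sum to 1.
#' @export
curveSummary <- function(evaluations) {
  if (is(evaluations, "SimulationCurves"))
    evaluations <- evaluations@evaluations
  agg <- stats::aggregate(fraction ~ fwhm_mm + destination + source,
                          data = evaluations,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(agg[c("fwhm_mm", "destination", "source")],
                    mean_fraction = agg$fraction[, "mean"],
                    sd_fraction = agg$fraction[, "sd"],
                    n = agg$fraction[, "n"])
  out[order(out$fwhm_mm, out$destination, out$source), , drop = FALSE]
}

setMethod("show", "SimulationCurves", function(object) {
  cat(sprintf("SimulationCurves: %d evaluations, FWHM %s mm\n",
              nrow(object@evaluations),
              paste(sort(unique(object@evaluations$fwhm_mm)), collapse = ", ")))
})

#' @describeIn SimulationCurves-class per-evaluation fractions
#' @param curves a [SimulationCurves-class]
#' @export
curveEvaluations <- function(curves) curves@evaluations
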