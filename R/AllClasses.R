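#' @import methods
NULL

#' Voxel grid in MNI RAS millimetre space
#'
#' A regular, axis-aligned voxel grid. The affine mapping from a zero-based
#' integer index \code{(i, j, k)} to world millimetres is
#' \code{origin + index * spacing}; \code{origin} is the world coordinate of
#' the centre of voxel \code{(0, 0, 0)}.
#'
#' @slot dim integer(3), number of voxels along x, y, z.
#' @slot spacing numeric(3), voxel edge length in mm (strictly positive).
#' @slot origin numeric(3), mm coordinate of the centre of the first voxel.
#'
#' @seealso [makeGrid()], [indexToMm()], [mmToIndex()]
#' @export
setClass("VoxelGrid",
  representation(dim = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@dim) != 3L || any(object@dim < 1L))
      msg <- c(msg, "'dim' must be three positive integers")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be three strictly positive numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "'origin' must be three finite numbers")
    if (is.null(msg)) TRUE else msg
  }
)

#' Binary occupancy mask on a voxel grid
#'
#' A 0/1 voxel occupancy map (stored as a logical array) together with its
#' [VoxelGrid-class]. Used for individual STN and SN segmentation masks.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot data logical array with \code{dim(data) == gridDim(grid)}.
#'
#' @export
setClass("BinaryMask",
  representation(grid = "VoxelGrid", data = "array"),
  validity = function(object) {
    if (!is.logical(object@data))
      return("'data' must be a logical array")
    if (!identical(dim(object@data), object@grid@dim))
      return("dim(data) must match the grid dimensions")
    TRUE
  }
)

#' Scalar volume on a voxel grid
#'
#' A numeric 3-D field (e.g. a probability map or a smoothed signal field)
#' with its grid and a coordinate-space tag.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot data numeric array matching the grid dimensions.
#' @slot space character, \code{"MNI"} or \code{"other"}.
#' @slot kind character, \code{"scalar"} or \code{"probability"}; probability
#'   volumes must lie in \code{[0, 1]}.
#'
#' @export
setClass("BrainVolume",
  representation(grid = "VoxelGrid", data = "array", space = "character",
                 kind = "character"),
  prototype(space = "MNI", kind = "scalar"),
  validity = function(object) {
    if (!is.numeric(object@data))
      return("'data' must be a numeric array")
    if (!identical(dim(object@data), object@grid@dim))
      return("dim(data) must match the grid dimensions")
    if (!object@space %in% c("MNI", "other"))
      return("'space' must be 'MNI' or 'other'")
    if (!object@kind %in% c("scalar", "probability"))
      return("'kind' must be 'scalar' or 'probability'")
    if (object@kind == "probability") {
      rng <- range(object@data, na.rm = TRUE)
      if (rng[1] < 0 || rng[2] > 1)
        return("probability volume has values outside [0, 1]")
    }
    TRUE
  }
)

#' Gaussian smoothing kernel specification
#'
#' Per-axis FWHM in mm with the derived standard deviation
#' \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})}. \code{truncation} is the kernel
#' support half-width in multiples of \eqn{\sigma}; it limits which voxels
#' enter the raw mass sums while the normalising constant is always the full
#' (converged) lattice sum, so mass accounting does not depend on the grid
#' extent.
#'
#' @slot fwhm numeric(3), non-negative, mm.
#' @slot sigma numeric(3), derived, mm.
#' @slot truncation numeric(1), support half-width in sigmas (default 6).
#'
#' @seealso [kernelSpec()], [fwhmToSigma()]
#' @export
setClass("KernelSpec",
  representation(fwhm = "numeric", sigma = "numeric", truncation = "numeric"),
  validity = function(object) {
    if (length(object@fwhm) != 3L || any(object@fwhm < 0))
      return("'fwhm' must be three non-negative numbers")
    if (!isTRUE(all.equal(object@sigma, fwhmToSigma(object@fwhm))))
      return("'sigma' must equal fwhm / (2*sqrt(2*log(2)))")
    if (length(object@truncation) != 1L || object@truncation <= 0)
      return("'truncation' must be a single positive number")
    TRUE
  }
)

#' Rotated-ellipsoid nucleus geometry
#'
#' @slot center numeric(3), mm centre of the ellipsoid.
#' @slot semiAxes numeric(3), mm semi-axis lengths (positive).
#' @slot rotation 3x3 orthonormal matrix; columns are the world directions of
#'   the three semi-axes.
#' @slot targetVolume numeric(1), mm^3; must agree with
#'   \eqn{(4/3)\pi abc} within 1 per cent.
#'
#' @export
setClass("NucleusGeometry",
  representation(center = "numeric", semiAxes = "numeric",
                 rotation = "matrix", targetVolume = "numeric"),
  validity = function(object) {
    if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
      return("'semiAxes' must be three positive numbers")
    R <- object@rotation
    if (!identical(dim(R), c(3L, 3L)) ||
        max(abs(crossprod(R) - diag(3))) > 1e-8)
      return("'rotation' must be a 3x3 orthonormal matrix")
    v <- 4 / 3 * pi * prod(object@semiAxes)
    if (abs(v - object@targetVolume) / object@targetVolume > 0.01)
      return("ellipsoid volume disagrees with targetVolume by more than 1%")
    TRUE
  }
)

#' Paired STN/SN masks for one synthetic subject
#'
#' Holds one STN and one SN binary mask per hemisphere. Within a hemisphere
#' the two masks share a grid and are disjoint.
#'
#' @slot subject integer subject index within the cohort.
#' @slot stnL,snL,stnR,snR [BinaryMask-class] objects.
#'
#' @export
setClass("SubjectAnatomy",
  representation(subject = "integer", stnL = "BinaryMask", snL = "BinaryMask",
                 stnR = "BinaryMask", snR = "BinaryMask"),
  validity = function(object) {
    for (h in c("L", "R")) {
      stn <- slot(object, paste0("stn", h))
      sn  <- slot(object, paste0("sn", h))
      if (!identical(stn@grid, sn@grid))
        return(sprintf("STN and SN masks of hemisphere %s are on different grids", h))
      if (any(stn@data & sn@data))
        return(sprintf("STN and SN masks of hemisphere %s overlap", h))
      if (!any(stn@data) || !any(sn@data))
        return(sprintf("empty mask in hemisphere %s", h))
    }
    TRUE
  }
)

#' Synthetic cohort configuration
#'
#' All tunable parameters of the synthetic-anatomy generator. The defaults
#' (see [cohortConfig()]) encode the emulated study conditions: 30 subjects,
#' 0.5 mm isotropic grid, mean conjunct STN volume 119.88 mm^3, STN-SN
#' centre-of-mass separations 6.4 mm (left) and 6.7 mm (right).
#'
#' @slot nSubjects integer, cohort size.
#' @slot seed integer, base random seed; per-subject substreams are derived by
#'   a fixed offset so earlier subjects are unchanged when the cohort grows.
#' @slot spacing numeric(1), isotropic voxel size in mm.
#' @slot stnVolumeMean,stnVolumeSd numeric, mm^3, subject STN volume distribution.
#' @slot snVolumeMean,snVolumeSd numeric, mm^3, subject SN volume distribution.
#' @slot comSeparation numeric(2), mm STN-SN centre separation, left then right.
#' @slot centerJitterSd numeric, mm per-axis positional jitter SD.
#' @slot rotationJitterSd numeric, degrees per-axis orientation jitter SD.
#' @slot erosionProb numeric, probability that a subject's mask is rated
#'   conservatively (one-voxel erosion), emulating two-rater conjunct masking.
#' @slot stnRatio,snRatio numeric(3), ellipsoid semi-axis ratios.
#' @slot stnCenterLeft numeric(3), mm, left STN centre (right is mirrored in x).
#' @slot separationDir numeric(3), unit vector from STN to SN centre for the
#'   left hemisphere (ventro-medio-posterior); mirrored in x on the right.
#' @slot snTiltDeg numeric, tilt of the SN medium axis off the separation axis, degrees.
#' @slot maxFwhm numeric, largest smoothing FWHM (mm) the cohort grid must
#'   support without boundary truncation (sets the grid margin to 4 sigma).
#'
#' @export
setClass("CohortConfig",
  representation(nSubjects = "integer", seed = "integer", spacing = "numeric",
                 stnVolumeMean = "numeric", stnVolumeSd = "numeric",
                 snVolumeMean = "numeric", snVolumeSd = "numeric",
                 comSeparation = "numeric", centerJitterSd = "numeric",
                 rotationJitterSd = "numeric", erosionProb = "numeric",
                 stnRatio = "numeric", snRatio = "numeric",
                 stnCenterLeft = "numeric", separationDir = "numeric",
                 snTiltDeg = "numeric", maxFwhm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nSubjects < 1L) msg <- c(msg, "'nSubjects' must be >= 1")
    if (object@spacing <= 0) msg <- c(msg, "'spacing' must be positive")
    sds <- c(object@stnVolumeSd, object@snVolumeSd, object@centerJitterSd,
             object@rotationJitterSd)
    if (any(sds < 0)) msg <- c(msg, "all jitter SDs must be >= 0")
    if (object@stnVolumeMean <= 0 || object@snVolumeMean <= 0)
      msg <- c(msg, "mean volumes must be positive")
    if (length(object@comSeparation) != 2L || any(object@comSeparation <= 0))
      msg <- c(msg, "'comSeparation' must be two positive separations (L, R)")
    if (object@erosionProb < 0 || object@erosionProb > 1)
      msg <- c(msg, "'erosionProb' must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' Signal-origin decomposition at one voxel
#'
#' Fractions of the smoothed signal at an evaluation point that originate
#' from the STN, from the SN and from everywhere else, together with the
#' unnormalised Gaussian mass sums over each mask. Fractions are obtained by
#' dividing the raw masses by the total kernel mass over the full voxel
#' lattice, so they lie in \code{[0, 1]} and sum to 1.
#'
#' @slot fromStn,fromSn,fromElsewhere numeric fractions summing to 1.
#' @slot rawMassStn,rawMassSn numeric, unnormalised mask mass sums.
#'
#' @export
setClass("MixtureFractions",
  representation(fromStn = "numeric", fromSn = "numeric",
                 fromElsewhere = "numeric", rawMassStn = "numeric",
                 rawMassSn = "numeric"),
  validity = function(object) {
    f <- c(object@fromStn, object@fromSn, object@fromElsewhere)
    if (any(f < -1e-9) || any(f > 1 + 1e-9))
      return("fractions must lie in [0, 1]")
    if (abs(sum(f) - 1) > 1e-9)
      return("fractions must sum to 1")
    if (object@rawMassStn < 0 || object@rawMassSn < 0)
      return("raw masses must be non-negative")
    TRUE
  }
)

#' Cohort smoothing-mixture curves
#'
#' Per-evaluation signal-origin fractions (one row per subject, hemisphere,
#' FWHM, destination nucleus and source) plus their cohort summary (mean and
#' SD across subjects and hemispheres for every source-destination pair as a
#' function of FWHM).
#'
#' @slot evaluations data.frame with columns subject, hemisphere, fwhm_mm,
#'   destination, source, fraction.
#' @slot summary data.frame with columns fwhm_mm, destination, source,
#'   mean_fraction, sd_fraction, n.
#'
#' @export
setClass("SimulationCurves",
  representation(evaluations = "data.frame", summary = "data.frame"))
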