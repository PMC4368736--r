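gridAffine <- function(grid) {
  A <- diag(4)
  A[cbind(1:3, 1:3)] <- grid@spacing
  A[1:3, 4] <- grid@origin
  A
}

#' Read a NIfTI volume
#'
#' Loads a NIfTI-1/NIfTI-2 file, reorients it to RAS, and converts it to a
#' [BrainVolume-class]. Only axis-aligned affines (after reorientation) are
#' supported, matching the package's regular-grid model; rotated or sheared
#' affines are an error. Declared probability maps are range-checked.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param kind `"scalar"` or `"probability"`; probability data outside
#'   \code{[0, 1]} raise an error.
#' @param space coordinate-space tag, `"MNI"` or `"other"`.
#' @return a [BrainVolume-class].
#' @export
readVolume <- function(path, kind = c("scalar", "probability"),
                       space = "MNI") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  RNifti::orientation(img) <- "RAS"
  A <- RNifti::xform(img)
  if (abs(det(A[1:3, 1:3])) < 1e-12) stop("non-invertible affine in ", path)
  offdiag <- A[1:3, 1:3]; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 * max(abs(A[1:3, 1:3])))
    stop("only axis-aligned (non-oblique) volumes are supported")
  grid <- new("VoxelGrid", dim = dim(img)[1:3],
              spacing = abs(diag(A[1:3, 1:3])), origin = A[1:3, 4])
  new("BrainVolume", grid = grid, data = array(as.numeric(img), dim(img)[1:3]),
      space = space, kind = kind)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks are written as uint8 0/1 data; volumes as float32. The affine is the
#' grid's diagonal RAS mm mapping.
#'
#' @param x a [BrainVolume-class] or [BinaryMask-class].
#' @param path output file (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "BinaryMask")) {
    data <- array(as.integer(x@data), x@grid@dim)
    dt <- "uint8"
  } else {
    data <- x@data
    dt <- "float"
  }
  attr(data, "pixdim") <- x@grid@spacing
  img <- RNifti::asNifti(data, datatype = dt)
  RNifti::qform(img) <- structure(gridAffine(x@grid), code = 2L)
  RNifti::sform(img) <- structure(gridAffine(x@grid), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Threshold a probability volume into a binary mask
#'
#' A voxel is included iff its value is strictly greater than `level`, so
#' level 0 gives the map's support and level 1 an empty mask. Thresholding is
#' monotone: a higher level always gives a subset.
#'
#' @param vol a [BrainVolume-class].
#' @param level threshold in \code{[0, 1]}.
#' @return a [BinaryMask-class].
#' @export
thresholdProbability <- function(vol, level) {
  if (level < 0 || level > 1) stop("'level' must be in [0, 1]")
  new("BinaryMask", grid = vol@grid,
      data = array(vol@data > level, vol@grid@dim))
}

#' Conjunct (two-rater) mask
#'
#' Voxelwise AND of two masks on the same grid: only voxels labelled by both
#' raters survive.
#'
#' @param a,b [BinaryMask-class] objects on one grid.
#' @return a [BinaryMask-class].
#' @export
conjunctMasks <- function(a, b) {
  if (!identical(a@grid, b@grid)) stop("masks are on different grids")
  new("BinaryMask", grid = a@grid, data = a@data & b@data)
}

#' Centre of mass in millimetres
#'
#' Intensity-weighted mean of voxel world coordinates: probability volumes
#' use their probabilities as weights, binary masks weight every set voxel
#' equally.
#'
#' @param x a [BrainVolume-class] or [BinaryMask-class].
#' @return mm triple.
#' @export
setGeneric("centerOfMassMm", function(x) standardGeneric("centerOfMassMm"))

#' @rdname centerOfMassMm
setMethod("centerOfMassMm", "BrainVolume", function(x) {
  w <- as.numeric(x@data)
  if (any(w < 0)) stop("negative weights")
  tot <- sum(w)
  if (tot <= 0) stop("empty volume: total mass is zero")
  unname(vapply(1:3, function(d) {
    ax <- axisCoords(x@grid, d)
    m <- apply(x@data, d, sum)
    sum(ax * m) / tot
  }, numeric(1)))
})

#' @rdname centerOfMassMm
setMethod("centerOfMassMm", "BinaryMask", function(x) {
  coords <- maskCoords(x)
  if (!nrow(coords)) stop("empty mask")
  unname(colMeans(coords))
})
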