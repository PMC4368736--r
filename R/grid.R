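#' Construct a voxel grid covering a bounding box
#'
#' Builds an axis-aligned [VoxelGrid-class] whose voxel centres tile the given
#' world-space box. The box should enclose every structure of interest plus a
#' margin of at least four kernel standard deviations so that smoothed fields
#' are never truncated at the boundary; [generateCohort()] chooses its margin
#' this way from \code{maxFwhm}.
#'
#' @param lower,upper numeric(3), mm corners of the bounding box.
#' @param spacing voxel size in mm; a single number (isotropic) or three.
#' @return a [VoxelGrid-class] with one voxel cell per `spacing` step of the
#'   box: a 40 mm box at 0.5 mm spacing gives 80 voxels per axis. The first
#'   voxel centre sits at `lower`.
#' @examples
#' g <- makeGrid(c(-20, -20, -20), c(20, 20, 20), 0.5)
#' gridDim(g)  # 80 voxels per axis
#' @export
makeGrid <- function(lower, upper, spacing = 0.5) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be strictly positive")
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(upper < lower))
    stop("'lower' and 'upper' must be mm triples with upper >= lower")
  if (any(upper - lower < spacing))
    stop("bounding box is smaller than one voxel")
  dim <- as.integer(ceiling(round((upper - lower) / spacing, 9)))
  new("VoxelGrid", dim = dim, spacing = spacing, origin = lower)
}

#' Map voxel indices to world millimetres
#'
#' @param grid a [VoxelGrid-class].
#' @param index numeric matrix (n x 3) or vector of zero-based voxel indices.
#' @return mm coordinates, same shape as `index`.
#' @export
indexToMm <- function(grid, index) {
  if (is.null(dim(index)))
    return(grid@origin + index * grid@spacing)
  sweep(sweep(index, 2L, grid@spacing, `*`), 2L, grid@origin, `+`)
}

#' Map world millimetres to the nearest voxel index
#'
#' @param grid a [VoxelGrid-class].
#' @param mm numeric matrix (n x 3) or vector of mm coordinates.
#' @return zero-based integer indices (not clamped to the grid).
#' @export
mmToIndex <- function(grid, mm) {
  if (is.null(dim(mm)))
    return(as.integer(round((mm - grid@origin) / grid@spacing)))
  round(sweep(sweep(mm, 2L, grid@origin, `-`), 2L, grid@spacing, `/`))
}

#' @describeIn VoxelGrid-class grid dimensions (voxels per axis)
#' @param grid a [VoxelGrid-class]
#' @export
gridDim <- function(grid) grid@dim

#' @describeIn VoxelGrid-class voxel spacing in mm
#' @export
voxelSpacing <- function(grid) grid@spacing

#' @describeIn VoxelGrid-class mm coordinate of the first voxel centre
#' @export
gridOrigin <- function(grid) grid@origin

#' @describeIn VoxelGrid-class volume of one voxel in mm^3
#' @export
voxelVolume <- function(grid) prod(grid@spacing)

# voxel-centre coordinates along one axis (d in 1:3)
axisCoords <- function(grid, d) {
  grid@origin[d] + (seq_len(grid@dim[d]) - 1) * grid@spacing[d]
}

# n x 3 matrix of mm centres of TRUE voxels of a mask (in linear index order)
maskCoords <- function(mask) {
  idx <- which(mask@data, arr.ind = TRUE)
  dimnames(idx) <- NULL
  indexToMm(mask@grid, idx - 1L)
}

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              object@dim[1], object@dim[2], object@dim[3],
              paste(format(object@spacing), collapse = " x "),
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "BinaryMask", function(object) {
  n <- sum(object@data)
  cat(sprintf("BinaryMask: %d voxels set (%.2f mm^3) on %d x %d x %d grid (%g mm spacing)\n",
              n, n * voxelVolume(object@grid),
              object@grid@dim[1], object@grid@dim[2], object@grid@dim[3],
              object@grid@spacing[1]))
})

setMethod("show", "BrainVolume", function(object) {
  cat(sprintf("BrainVolume (%s, %s): %d x %d x %d voxels, range [%g, %g]\n",
              object@kind, object@space,
              object@grid@dim[1], object@grid@dim[2], object@grid@dim[3],
              min(object@data), max(object@data)))
})

#' Accessors for masks and volumes
#'
#' @param x a [BinaryMask-class] or [BrainVolume-class].
#' @return `maskArray` the underlying array; `maskVolumeMm3` the occupied
#'   volume in mm^3; `volumeGrid` the [VoxelGrid-class].
#' @export
maskArray <- function(x) x@data

#' @rdname maskArray
#' @export
maskVolumeMm3 <- function(x) sum(x@data) * voxelVolume(x@grid)

#' @rdname maskArray
#' @export
volumeGrid <- function(x) x@grid
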