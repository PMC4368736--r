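#' Smooth a binary mask with a separable Gaussian kernel
#'
#' Convolves the 0/1 indicator field with the discrete Gaussian sampled at
#' voxel centres, axis by axis. Kernel taps extend to the kernel's truncation
#' radius and are normalised by the converged full-lattice sum, so the value
#' at any voxel equals the raw mask mass of [mixtureAtPoint()] divided by the
#' total kernel mass, and the field integral (sum times voxel volume) is
#' conserved for masks away from the grid boundary. A zero-FWHM kernel
#' returns the input field unchanged.
#'
#' @param mask a [BinaryMask-class] (non-empty).
#' @param kernel a [KernelSpec-class].
#' @return a scalar [BrainVolume-class].
#' @export
smoothField <- function(mask, kernel) {
  if (!any(mask@data)) stop("empty mask")
  grid <- mask@grid
  field <- array(as.numeric(mask@data), grid@dim)
  for (d in 1:3) {
    s <- kernel@sigma[d]
    if (s == 0) next
    h <- grid@spacing[d]
    K <- as.integer(ceiling(kernel@truncation * s / h))
    w <- exp(-((-K:K) * h)^2 / (2 * s^2)) / latticeSum1d(h, s)
    field <- convolveAxis(field, w, d)
  }
  new("BrainVolume", grid = grid, data = field, space = "MNI", kind = "scalar")
}

# convolve a 3-D array along axis `d` with a centred weight vector, zero
# padding at the boundary; implemented as a banded-matrix product so the
# inner loop runs in BLAS
convolveAxis <- function(a, w, d) {
  dm <- dim(a)
  n <- dm[d]
  K <- (length(w) - 1L) / 2L
  Tm <- matrix(0, n, n)
  for (k in -K:K) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1 & j <= n
    Tm[cbind(i[ok], j[ok])] <- w[k + K + 1L]
  }
  perm <- switch(d, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  pd <- dim(ap)
  res <- Tm %*% matrix(ap, pd[1], pd[2] * pd[3])
  dim(res) <- pd
  aperm(res, order(perm))
}
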