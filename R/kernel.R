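#' Convert Gaussian kernel FWHM to standard deviation
#'
#' \eqn{\sigma = FWHM / (2\sqrt{2 \ln 2})}, the standard relation between the
#' full width at half maximum of a Gaussian and its standard deviation.
#'
#' @param fwhm numeric, FWHM in mm (vectorised, non-negative).
#' @return sigma in mm.
#' @examples
#' fwhmToSigma(8)            # 3.39729...
#' sigmaToFwhm(fwhmToSigma(8))
#' @export
fwhmToSigma <- function(fwhm) {
  if (any(fwhm < 0)) stop("'fwhm' must be non-negative")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' @rdname fwhmToSigma
#' @param sigma numeric, standard deviation in mm.
#' @export
sigmaToFwhm <- function(sigma) {
  if (any(sigma < 0)) stop("'sigma' must be non-negative")
  sigma * 2 * sqrt(2 * log(2))
}

#' Create a Gaussian kernel specification
#'
#' @param fwhm FWHM in mm; one number (isotropic) or three (per axis).
#' @param truncation kernel support half-width in multiples of sigma
#'   (default 6). Limits which voxels enter raw mass sums and which taps enter
#'   the discrete convolution kernel; the normalising total is always the
#'   converged full lattice sum.
#' @return a [KernelSpec-class].
#' @export
kernelSpec <- function(fwhm, truncation = 6) {
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  new("KernelSpec", fwhm = fwhm, sigma = fwhmToSigma(fwhm),
      truncation = as.numeric(truncation))
}

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf("KernelSpec: FWHM (%s) mm, sigma (%s) mm, truncation %g sigma\n",
              paste(format(object@fwhm), collapse = ", "),
              paste(format(object@sigma, digits = 5), collapse = ", "),
              object@truncation))
})

#' Mass of an isotropic 3-D Gaussian within a sphere
#'
#' Closed-form fraction of a 3-D isotropic Gaussian centred at the sphere's
#' centre that falls within radius `radius`: with \eqn{z = r/\sigma},
#' \deqn{P = \mathrm{erf}(z/\sqrt 2) - \sqrt{2/\pi}\, z\, e^{-z^2/2},}
#' i.e. the chi distribution with three degrees of freedom. Serves as an
#' independent oracle for [mixtureAtPoint()] on spherical masks.
#'
#' @param radius sphere radius in mm (non-negative, vectorised).
#' @param sigma Gaussian standard deviation in mm (positive).
#' @return fraction in \code{[0, 1]}.
#' @examples
#' sphereFraction(1, 1)  # 0.19875...
#' @export
sphereFraction <- function(radius, sigma) {
  if (any(radius < 0)) stop("'radius' must be non-negative")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  z <- radius / sigma
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  erf(z / sqrt(2)) - sqrt(2 / pi) * z * exp(-z^2 / 2)
}
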