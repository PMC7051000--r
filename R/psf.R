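fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}

#' Focal-plane intensity PSF by scalar Fourier optics
#'
#' Computes |FT{A exp(i(mask + defocus phase))}|^2 on a zero-padded grid and
#' normalizes so the unaberrated flat-mask peak is exactly 1. The focal-plane
#' pixel pitch is lambda * pupil_fill / (2 * NA * oversample) nm — the
#' pupil diameter maps to the 2NA/lambda spatial-frequency band.
#'
#' Scalar diffraction is used deliberately (see the methods vignette): the
#' correction method is propagator-agnostic and scalar keeps desk-scale
#' runtime; vectorial high-NA polarization effects are out of scope.
#'
#' @param grid a [pupil_grid()].
#' @param mask phase matrix in radians (default: flat). Wrapping is
#'   irrelevant here since only exp(i*phase) enters.
#' @param defocus_um axial offset in micrometres; adds the spherical-cap
#'   pupil phase [defocus_phase()].
#' @param oversample integer >= 2, zero-padding factor (>= 2 prevents
#'   aliasing of the focal field).
#' @return object of class `intensity_psf`: numeric matrix (side
#'   `oversample * n_pixels`) with attributes `pixel_size_nm` and
#'   `wavelength_nm`. Centre of the pattern is at pixel (N/2+1, N/2+1).
#' @export
focal_psf <- function(grid, mask = NULL, defocus_um = 0, oversample = 4L) {
  stopifnot(inherits(grid, "pupil_grid"))
  oversample <- as.integer(oversample)
  if (oversample < 2L) stop("oversample must be >= 2 (padding prevents aliasing)")
  n <- grid$n_pixels
  if (is.null(mask)) mask <- matrix(0, n, n)
  if (!identical(dim(mask), c(n, n))) stop("mask shape does not match grid")
  if (any(!is.finite(mask))) stop("non-finite phase in mask")
  phi <- mask
  if (defocus_um != 0) phi <- phi + defocus_phase(grid, defocus_um)

  field <- matrix(0 + 0i, n * oversample, n * oversample)
  amp <- ifelse(grid$aperture, 1, 0)
  field[1:n, 1:n] <- amp * exp(1i * phi)
  inten <- Mod(stats::fft(field))^2
  inten <- fftshift2(inten)
  inten <- inten / sum(amp)^2  # flat-mask peak == 1 exactly

  px_nm <- grid$wavelength_nm * grid$pupil_fill / (2 * grid$na * oversample)
  structure(inten, pixel_size_nm = px_nm, wavelength_nm = grid$wavelength_nm,
            class = c("intensity_psf", "matrix"))
}

#' @export
print.intensity_psf <- function(x, ...) {
  cat(sprintf("intensity_psf: %dx%d, pixel %.2f nm, peak %.4g\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"), max(x)))
  invisible(x)
}

#' Half-max full width of a PSF along a central axis
#'
#' Linear interpolation of the two half-maximum crossings of the profile
#' through the brightest pixel. Model-free companion to the Gaussian-fit
#' [metric_fwhm()]; used for PSF-level resolution checks.
#'
#' @param psf an [focal_psf()] result (or any matrix with a
#'   `pixel_size_nm` attribute).
#' @param axis "x" (profile along rows through the peak) or "y".
#' @return FWHM in nm.
#' @export
psf_fwhm <- function(psf, axis = c("x", "y")) {
  axis <- match.arg(axis)
  px <- attr(psf, "pixel_size_nm")
  if (is.null(px)) stop("psf lacks a pixel_size_nm attribute")
  pk <- which(psf == max(psf), arr.ind = TRUE)[1, ]
  prof <- if (axis == "x") psf[, pk[2]] else psf[pk[1], ]
  ctr <- if (axis == "x") pk[1] else pk[2]
  half <- prof[ctr] / 2
  left <- ctr; while (left > 1 && prof[left] > half) left <- left - 1
  right <- ctr; while (right < length(prof) && prof[right] > half) right <- right + 1
  if (prof[left] > half || prof[right] > half)
    stop("profile does not fall below half maximum inside the field")
  xl <- left + (half - prof[left]) / (prof[left + 1] - prof[left])
  xr <- right - (half - prof[right]) / (prof[right - 1] - prof[right])
  unname((xr - xl) * px)
}

#' Axial PSF stack
#'
#' Stack of [focal_psf()] intensities at evenly spaced defocus planes — the
#' simulated XZ view used to inspect donut quality above/below focus.
#'
#' @param grid a [pupil_grid()].
#' @param mask phase matrix.
#' @param z_range_um length-2 numeric, axial range in micrometres.
#' @param n_planes integer >= 1.
#' @param oversample passed to [focal_psf()].
#' @return 3-D array (x, y, z) with attributes `pixel_size_nm` and `z_um`.
#' @export
axial_stack <- function(grid, mask = NULL, z_range_um = c(-1, 1),
                        n_planes = 11L, oversample = 4L) {
  if (n_planes < 1) stop("n_planes must be >= 1")
  zs <- if (n_planes == 1) mean(z_range_um)
        else seq(z_range_um[1], z_range_um[2], length.out = n_planes)
  planes <- lapply(zs, function(z) focal_psf(grid, mask, z, oversample))
  out <- array(unlist(planes), dim = c(dim(planes[[1]]), n_planes))
  attr(out, "pixel_size_nm") <- attr(planes[[1]], "pixel_size_nm")
  attr(out, "z_um") <- zs
  out
}
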