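#' Gaussian-fit FWHM along a line profile
#'
#' Extracts a bilinearly interpolated intensity profile along a line and fits
#' amplitude/centre/sigma/offset by least squares — the standard way
#' resolution is read off dotted-line profiles across a bead or filament.
#' Returns 2*sqrt(2*ln 2)*sigma in nm.
#'
#' @param image matrix with a `pixel_size_nm` attribute (an `image_stack` or
#'   `intensity_psf`), or a bare matrix plus `pixel_size_nm`.
#' @param start_px,end_px length-2 numeric, line endpoints in (fractional)
#'   pixel coordinates.
#' @param pixel_size_nm overrides the attribute if given.
#' @param n_samples profile sampling density (default: ~2 per pixel).
#' @return FWHM in nm, with attributes `sigma_nm`, `centre_nm` (along the
#'   line), `residual` (RMS of fit residuals / amplitude) and `profile`
#'   (data.frame t_nm, intensity).
#' @export
metric_fwhm <- function(image, start_px, end_px, pixel_size_nm = NULL,
                        n_samples = NULL) {
  px <- if (!is.null(pixel_size_nm)) pixel_size_nm
        else attr(image, "pixel_size_nm")
  if (is.null(px)) stop("pixel_size_nm not given and not an image attribute")
  m <- as.matrix(image)
  L_px <- sqrt(sum((end_px - start_px)^2))
  if (L_px <= 0) stop("degenerate line")
  if (is.null(n_samples)) n_samples <- max(16L, ceiling(2 * L_px))
  t <- seq(0, 1, length.out = n_samples)
  xs <- start_px[1] + t * (end_px[1] - start_px[1])
  ys <- start_px[2] + t * (end_px[2] - start_px[2])
  if (any(xs < 1 | xs > nrow(m) | ys < 1 | ys > ncol(m)))
    stop("line extends outside the image")
  prof <- bilinear_at(m, xs, ys)
  t_nm <- t * L_px * px
  if (max(prof) - min(prof) <= .Machine$double.eps * max(abs(prof), 1))
    stop("no peak: profile is flat")

  # moment-based initialisation, then Nelder-Mead least squares
  off0 <- min(prof); a0 <- max(prof) - off0
  w <- pmax(prof - off0, 0); w <- w / sum(w)
  mu0 <- sum(w * t_nm)
  s0 <- sqrt(max(sum(w * (t_nm - mu0)^2), (t_nm[2] - t_nm[1])^2))
  obj <- function(p) sum((p[1] * exp(-(t_nm - p[2])^2 / (2 * p[3]^2)) +
                            p[4] - prof)^2)
  fit <- stats::optim(c(a0, mu0, s0, off0), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  a <- fit$par[1]; mu <- fit$par[2]; sg <- abs(fit$par[3]); off <- fit$par[4]
  if (a <= 0) stop("no peak: fitted amplitude is not positive")
  fwhm <- 2 * sqrt(2 * log(2)) * sg
  structure(fwhm, sigma_nm = sg, centre_nm = mu,
            residual = sqrt(fit$value / length(prof)) / a,
            profile = data.frame(t_nm = t_nm, intensity = prof))
}

bilinear_at <- function(m, xs, ys) {
  n1 <- nrow(m); n2 <- ncol(m)
  i0 <- pmin(pmax(floor(xs), 1L), n1 - 1L)
  j0 <- pmin(pmax(floor(ys), 1L), n2 - 1L)
  fx <- xs - i0; fy <- ys - j0
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i0 + 1L, j0)] * fx * (1 - fy) +
    m[cbind(i0, j0 + 1L)] * (1 - fx) * fy +
    m[cbind(i0 + 1L, j0 + 1L)] * fx * fy
}

#' Donut null depth
#'
#' Ratio of the central intensity to the ring maximum,
#' I(centre) / max(ring) — the contrast between the donut minimum and its
#' surrounding illumination. 1 for a flat-mask PSF (the centre IS the max);
#' < 1e-6 for a clean vortex; grows quickly with residual aberration.
#'
#' @param psf an `intensity_psf` (centre at N/2+1 by the grid convention).
#' @return dimensionless ratio.
#' @export
metric_null_depth <- function(psf) {
  n <- nrow(psf)
  ctr <- n / 2 + 1
  psf[ctr, ctr] / max(psf)
}

#' Azimuthal ring uniformity of a donut
#'
#' Finds the ring radius (peak of the radial profile) and returns
#' max/min intensity around that circle (bilinear sampling). 1 = perfectly
#' uniform ring; aberrations break the symmetry and push it up.
#'
#' @param psf an `intensity_psf`.
#' @param n_theta azimuthal samples (default 180).
#' @return ratio >= 1.
#' @export
metric_ring_uniformity <- function(psf, n_theta = 180L) {
  m <- as.matrix(psf)
  n <- nrow(m); ctr <- n / 2 + 1
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]
  r_ring <- sqrt((pk[1] - ctr)^2 + (pk[2] - ctr)^2)
  if (r_ring < 1) stop("no ring: peak at the centre")
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  vals <- bilinear_at(m, ctr + r_ring * cos(th), ctr + r_ring * sin(th))
  max(vals) / min(vals)
}

#' Mean image intensity
#'
#' Arithmetic mean over all pixels — the whole-frame statistic used to
#' compare signal before/after correction. Only meaningful as a ratio
#' between images taken under the same conditions.
#'
#' @param image a matrix.
#' @return scalar mean.
#' @export
metric_mean_intensity <- function(image) {
  if (length(image) == 0) stop("empty image")
  mean(image)
}
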