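#' Aberration screen
#'
#' A hidden pupil-plane phase the optimizer must compensate without reading
#' it (the black-box constraint of sensorless correction). Applied additively
#' inside the propagator; a zero screen is the unaberrated system.
#'
#' @param phase phase matrix in radians.
#' @param source one of "system", "sample", "artificial_defocus".
#' @param description free text.
#' @return object of class `aberration_screen`.
#' @export
aberration_screen <- function(phase,
                              source = c("system", "sample",
                                         "artificial_defocus"),
                              description = "") {
  source <- match.arg(source)
  structure(list(source = source, phase = phase, description = description),
            class = "aberration_screen")
}

#' @export
print.aberration_screen <- function(x, ...) {
  cat(sprintf("aberration_screen [%s]: %s\n", x$source,
              if (nzchar(x$description)) x$description else "(no description)"))
  invisible(x)
}

#' Guide star (scattering feedback target)
#'
#' A point scatterer (gold nanoparticle in the experiment) whose
#' back-scattered signal — proportional to the local illumination
#' intensity — is the GA's fitness. Positions and radii are physical (nm)
#' so they are independent of the focal-grid oversampling.
#'
#' @param position_nm length-2 lateral offset of the scatterer from the scan
#'   centre, nm.
#' @param pinhole_radius_nm detection radius over which intensity is
#'   integrated; `NULL` (default) means one Airy radius 0.61*lambda/NA of
#'   the grid it is used with.
#' @return object of class `guide_star`.
#' @export
guide_star <- function(position_nm = c(0, 0), pinhole_radius_nm = NULL) {
  if (length(position_nm) != 2) stop("position_nm must be length 2")
  if (!is.null(pinhole_radius_nm) && pinhole_radius_nm < 0)
    stop("pinhole_radius_nm must be >= 0")
  structure(list(position_nm = as.numeric(position_nm),
                 pinhole_radius_nm = pinhole_radius_nm),
            class = "guide_star")
}

star_radius_nm <- function(star, grid) {
  if (!is.null(star$pinhole_radius_nm)) star$pinhole_radius_nm
  else 0.61 * grid$wavelength_nm / grid$na
}

#' Guide-star fitness signal
#'
#' The image-quality metric the GA maximizes: focal intensity of the beam
#' carrying `compose(correction, screen)` integrated over the pinhole disk at
#' the guide-star position, normalized so the unaberrated (zero screen, zero
#' correction) value is 1. Optionally perturbed by additive Gaussian noise
#' emulating PMT/voltage noise. The physical PMT voltage is negative and
#' grows in magnitude with signal; the simulator standardizes on
#' maximize-positive.
#'
#' Correction is performed on the Gaussian (non-vortex) beam, as in the
#' experiment; the corrected donut is obtained afterwards by composing the
#' spiral phase with the recovered correction.
#'
#' @param correction phase matrix (the optimizer's candidate).
#' @param screen an [aberration_screen()] (or a bare phase matrix).
#' @param grid a [pupil_grid()].
#' @param star a [guide_star()].
#' @param noise_sd additive Gaussian noise sd on the normalized signal.
#' @param rng_seed integer seed used only when `noise_sd > 0`; `NULL` draws
#'   from the current RNG stream.
#' @param oversample passed to [focal_psf()].
#' @return positive scalar fitness (1 = unaberrated ceiling).
#' @export
guide_star_signal <- function(correction, screen, grid, star = guide_star(),
                              noise_sd = 0, rng_seed = NULL, oversample = 4L) {
  scr <- if (inherits(screen, "aberration_screen")) screen$phase else screen
  psf <- focal_psf(grid, compose_masks(correction, scr), oversample = oversample)
  sig <- pinhole_sum(psf, star, grid)
  ref <- pinhole_sum(focal_psf(grid, oversample = oversample), star, grid)
  out <- sig / ref
  if (noise_sd > 0) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    out <- out + stats::rnorm(1, 0, noise_sd)
  }
  out
}

pinhole_sum <- function(psf, star, grid) {
  px <- attr(psf, "pixel_size_nm")
  n <- nrow(psf)
  ctr <- n / 2 + 1
  cx <- ctr + star$position_nm[1] / px
  cy <- ctr + star$position_nm[2] / px
  r_px <- star_radius_nm(star, grid) / px
  if (cx - r_px < 1 || cx + r_px > n || cy - r_px < 1 || cy + r_px > n)
    stop("guide star (plus pinhole) outside the simulated field")
  ix <- matrix(seq_len(n), n, n)
  iy <- matrix(seq_len(n), n, n, byrow = TRUE)
  sum(psf[(ix - cx)^2 + (iy - cy)^2 <= r_px^2])
}

#' Fast guide-star fitness engine
#'
#' Precomputes a direct-DFT transfer matrix from aperture pixels to the
#' focal-plane pixels inside the pinhole (the same pixels
#' [guide_star_signal()] integrates over at the same `oversample`), so each
#' fitness evaluation is one complex matrix-vector product instead of a full
#' padded FFT. Agrees with the contract op to FFT round-off; tested to
#' < 1e-10 relative.
#'
#' @param grid a [pupil_grid()].
#' @param screen an [aberration_screen()] (or phase matrix).
#' @param star a [guide_star()].
#' @param noise_sd additive Gaussian noise sd on the normalized signal (drawn
#'   from the current RNG stream, so a seeded caller is reproducible).
#' @param oversample focal sampling matching [guide_star_signal()]'s.
#' @return function(correction) -> fitness, where `correction` is the phase
#'   at `grid$aperture` pixels only (vector) or a full matrix.
#' @export
guide_star_engine <- function(grid, screen, star = guide_star(),
                              noise_sd = 0, oversample = 4L) {
  scr <- if (inherits(screen, "aberration_screen")) screen$phase else screen
  n <- grid$n_pixels * oversample
  px_nm <- grid$wavelength_nm * grid$pupil_fill / (2 * grid$na * oversample)
  ctr <- n / 2 + 1
  cx <- ctr + star$position_nm[1] / px_nm
  cy <- ctr + star$position_nm[2] / px_nm
  r_px <- star_radius_nm(star, grid) / px_nm
  if (cx - r_px < 1 || cx + r_px > n || cy - r_px < 1 || cy + r_px > n)
    stop("guide star (plus pinhole) outside the simulated field")
  ix <- matrix(seq_len(n), n, n)
  iy <- matrix(seq_len(n), n, n, byrow = TRUE)
  inside <- (ix - cx)^2 + (iy - cy)^2 <= r_px^2
  x_nm <- (ix[inside] - ctr) * px_nm
  y_nm <- (iy[inside] - ctr) * px_nm
  # spatial frequency (cycles/nm) of each aperture pixel
  fx <- grid$na * grid$ux[grid$aperture] / grid$wavelength_nm
  fy <- grid$na * grid$uy[grid$aperture] / grid$wavelength_nm
  transfer <- exp(-2i * pi * (outer(x_nm, fx) + outer(y_nm, fy)))
  scr_ap <- scr[grid$aperture]
  n_ap <- length(scr_ap)
  ref <- sum(Mod(transfer %*% rep(1 + 0i, n_ap))^2)
  ap <- grid$aperture
  function(correction) {
    corr <- if (is.matrix(correction)) correction[ap] else correction
    val <- sum(Mod(transfer %*% exp(1i * (corr + scr_ap)))^2) / ref
    if (noise_sd > 0) val <- val + stats::rnorm(1, 0, noise_sd)
    val
  }
}

#' Effective STED point spread function
#'
#' Saturated-depletion model: h_eff = h_exc * exp(-ln2 * zeta * h_dep), with
#' the depletion PSF normalized to peak 1 before scaling. zeta is the
#' saturation factor (peak depletion intensity over saturation intensity);
#' zeta = 0 recovers the confocal PSF, zeta = 1 halves emission where the
#' donut peaks, and for a matched-wavelength vortex donut the FWHM follows
#' the textbook 1/sqrt(1+zeta) scaling.
#'
#' @param exc excitation [focal_psf()].
#' @param dep depletion (donut) [focal_psf()], same shape.
#' @param zeta saturation factor >= 0.
#' @return `intensity_psf` with the excitation pixel size.
#' @export
effective_sted_psf <- function(exc, dep, zeta) {
  if (!identical(dim(exc), dim(dep)))
    stop("excitation and depletion PSFs must have the same shape")
  px_e <- attr(exc, "pixel_size_nm"); px_d <- attr(dep, "pixel_size_nm")
  if (!is.null(px_e) && !is.null(px_d) &&
      abs(px_e - px_d) > 1e-3 * px_e)
    stop("excitation and depletion PSFs must share a pixel size; ",
         "use match_psf_grid() to resample one onto the other's grid")
  if (zeta < 0) stop("zeta must be >= 0")
  dpk <- max(dep)
  if (dpk <= 0) stop("depletion PSF is empty")
  h <- as.matrix(exc) * exp(-log(2) * zeta * as.matrix(dep) / dpk)
  structure(h, pixel_size_nm = attr(exc, "pixel_size_nm"),
            wavelength_nm = attr(exc, "wavelength_nm"),
            class = c("intensity_psf", "matrix"))
}

#' Resample a PSF onto another PSF's focal grid
#'
#' PSFs computed at different wavelengths share the pupil grid but not the
#' focal pixel pitch (pitch = lambda*fill/(2*NA*oversample)). This bilinearly
#' resamples `psf` onto `ref`'s centre-aligned pixel grid (zero outside the
#' source field) so the two can be combined pixelwise, e.g. in
#' [effective_sted_psf()].
#'
#' @param psf source `intensity_psf`.
#' @param ref reference `intensity_psf` whose grid is adopted.
#' @return `intensity_psf` with `ref`'s shape and pixel size.
#' @export
match_psf_grid <- function(psf, ref) {
  px_s <- attr(psf, "pixel_size_nm"); px_r <- attr(ref, "pixel_size_nm")
  if (is.null(px_s) || is.null(px_r)) stop("both PSFs need pixel_size_nm")
  m <- as.matrix(psf)
  n_s <- nrow(m); n_r <- nrow(ref)
  ctr_s <- n_s / 2 + 1; ctr_r <- n_r / 2 + 1
  pos <- ctr_s + (seq_len(n_r) - ctr_r) * px_r / px_s
  ok <- pos >= 1 & pos <= n_s
  out <- matrix(0, n_r, n_r)
  xi <- matrix(pos[ok], sum(ok), sum(ok))
  yi <- matrix(pos[ok], sum(ok), sum(ok), byrow = TRUE)
  out[ok, ok] <- bilinear_at(m, as.vector(xi), as.vector(yi))
  structure(out, pixel_size_nm = px_r,
            wavelength_nm = attr(psf, "wavelength_nm"),
            class = c("intensity_psf", "matrix"))
}

#' Simulated scanned image of a phantom
#'
#' Convolution of the emitter impulse field with the PSF (beam-scanning image
#' formation under the isoplanatic approximation), scaled by `photon_scale`,
#' with optional Poisson shot noise.
#'
#' @param phantom a [make_bead_field()] / [make_filaments()] result (class
#'   `phantom`).
#' @param psf an `intensity_psf`.
#' @param pixel_size_nm image pixel size; defaults to the PSF's. If it
#'   differs the PSF is bilinearly resampled.
#' @param photon_scale expected photons from a unit-brightness emitter at
#'   the PSF peak.
#' @param noise "none" or "poisson".
#' @param rng_seed integer seed for the Poisson draw; `NULL` uses the current
#'   RNG stream.
#' @return object of class `image_stack`: matrix with attributes
#'   `pixel_size_nm` and `channel`.
#' @export
scan_image <- function(phantom, psf, pixel_size_nm = NULL, photon_scale = 1,
                       noise = c("none", "poisson"), rng_seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(phantom, "phantom"))
  px <- if (is.null(pixel_size_nm)) attr(psf, "pixel_size_nm") else pixel_size_nm
  n_img <- max(2L, as.integer(round(phantom$field_size_nm / px)))
  h <- if (abs(px - attr(psf, "pixel_size_nm")) <
           1e-9 * attr(psf, "pixel_size_nm")) as.matrix(psf)
       else resample_bilinear(as.matrix(psf), attr(psf, "pixel_size_nm"), px)
  field <- matrix(0, n_img, n_img)
  if (nrow(phantom$emitters) > 0) {
    # bilinear splat of each emitter onto the image grid (1-based pixels)
    for (k in seq_len(nrow(phantom$emitters))) {
      x <- phantom$emitters$x_nm[k] / px + 0.5
      y <- phantom$emitters$y_nm[k] / px + 0.5
      b <- phantom$emitters$brightness[k]
      if (x < 1 || x > n_img || y < 1 || y > n_img)
        stop("emitter outside field in scan_image")
      i0 <- floor(x); j0 <- floor(y)
      fx <- x - i0; fy <- y - j0
      for (di in 0:1) for (dj in 0:1) {
        ii <- i0 + di; jj <- j0 + dj
        if (ii >= 1 && ii <= n_img && jj >= 1 && jj <= n_img) {
          w <- (if (di == 0) 1 - fx else fx) * (if (dj == 0) 1 - fy else fy)
          field[ii, jj] <- field[ii, jj] + b * w
        }
      }
    }
  }
  # the PSF is used as-is (flat-mask peak = 1 scale), so channels imaged
  # with different effective PSFs remain photometrically comparable
  img <- conv2_fft(field, h) * photon_scale
  img[img < 0] <- 0  # clip FFT round-off
  if (noise == "poisson") {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    img <- matrix(stats::rpois(length(img), img), n_img, n_img)
  }
  structure(img, pixel_size_nm = px,
            channel = attr(psf, "channel", exact = TRUE),
            class = c("image_stack", "matrix"))
}

# zero-padded FFT convolution, kernel centred at (N/2+1, N/2+1)
conv2_fft <- function(field, kernel) {
  nf <- dim(field); nk <- dim(kernel)
  n1 <- nf[1] + nk[1]; n2 <- nf[2] + nk[2]
  A <- matrix(0, n1, n2); B <- matrix(0, n1, n2)
  A[seq_len(nf[1]), seq_len(nf[2])] <- field
  B[seq_len(nk[1]), seq_len(nk[2])] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (n1 * n2)
  ci <- nk[1] / 2 + 1; cj <- nk[2] / 2 + 1   # kernel centre offset
  full[ci:(ci + nf[1] - 1), cj:(cj + nf[2] - 1)]
}

resample_bilinear <- function(m, px_from, px_to) {
  n_from <- nrow(m)
  extent <- n_from * px_from
  n_to <- max(2L, as.integer(round(extent / px_to)))
  # sample positions (centre-aligned)
  ctr_f <- n_from / 2 + 1
  ctr_t <- n_to / 2 + 1
  pos <- (seq_len(n_to) - ctr_t) * px_to / px_from + ctr_f
  pos[pos < 1] <- 1; pos[pos > n_from] <- n_from
  i0 <- pmin(floor(pos), n_from - 1); f <- pos - i0
  out <- matrix(0, n_to, n_to)
  for (j in seq_len(n_to)) {
    col0 <- m[, i0[j]] * (1 - f[j]) + m[, i0[j] + 1] * f[j]
    out[, j] <- col0[i0] * (1 - f) + col0[i0 + 1] * f
  }
  out
}
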