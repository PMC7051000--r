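# Independent oracles, kept free of the package's FFT path.

# Direct-DFT focal intensity at focal pixel offsets (mx, my) from the centre,
# brute-force double sum over aperture pixels. Matches focal_psf's grid
# convention: offsets in units of the oversampled focal pixel.
oracle_focal_intensity <- function(grid, mask, mx, my, oversample = 4L) {
  N <- grid$n_pixels * oversample
  ap <- grid$aperture
  # pupil pixel offsets from grid centre, in pixels
  n <- grid$n_pixels
  off <- seq_len(n) - 1 - n / 2
  tx <- matrix(off, n, n)[ap]
  ty <- matrix(off, n, n, byrow = TRUE)[ap]
  ph <- mask[ap]
  out <- matrix(0, length(mx), length(my))
  for (a in seq_along(mx)) for (b in seq_along(my)) {
    E <- sum(exp(1i * (ph - 2 * pi * (tx * mx[a] + ty * my[b]) / N)))
    out[a, b] <- Mod(E)^2
  }
  out / sum(ap)^2
}

# FWHM of the unaberrated scalar PSF from a dense 1-D direct-DFT radial cut,
# independent of focal_psf / psf_fwhm. Returns nm.
oracle_flat_fwhm <- function(grid, step_nm = 0.5, max_nm = 600) {
  ap <- grid$aperture
  fx <- grid$na * grid$ux[ap] / grid$wavelength_nm
  x <- seq(0, max_nm, by = step_nm)
  I <- vapply(x, function(xx) Mod(sum(exp(-2i * pi * fx * xx)))^2, numeric(1))
  I <- I / I[1]
  i <- which(I < 0.5)[1]
  x0 <- x[i - 1] + step_nm * (I[i - 1] - 0.5) / (I[i - 1] - I[i])
  2 * x0
}

grid32 <- function(...) pupil_grid(32, ...)

expect_rel <- function(x, y, tol) expect_lt(abs(x - y) / abs(y), tol)
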