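#' Discretized pupil plane
#'
#' Builds the square pupil-plane grid on which all phase masks and focal
#' fields are computed. The physical SLM control region (1080x1080 pixels in
#' a typical device) is modelled by an `n_pixels` grid; the method is
#' scale-free, so segment layouts are mapped proportionally.
#'
#' The aperture is the open unit disk (rho < 1) inscribed in
#' `pupil_fill` times the grid diameter, which makes the mask exactly
#' point-symmetric about the grid centre on even grids. The centre sits at
#' pixel `(n_pixels/2 + 1, n_pixels/2 + 1)` (1-based).
#'
#' @param n_pixels even integer >= 16, side of the square grid.
#' @param na numerical aperture of the objective (default 1.4, oil).
#' @param wavelength_nm vacuum wavelength in nm (default 760, depletion beam).
#' @param medium_index refractive index of the immersion medium (1.518, oil).
#' @param pupil_fill fraction of the grid diameter filled by the aperture.
#' @return object of class `pupil_grid`: a list with the constructor
#'   arguments plus precomputed unit-pupil coordinates `ux`, `uy` (matrices),
#'   radius `rho`, azimuth `theta`, and the logical `aperture` mask.
#' @examples
#' g <- pupil_grid(64)
#' sum(g$aperture) / 64^2   # ~ pi/4 fill factor
#' @export
pupil_grid <- function(n_pixels = 128L, na = 1.4, wavelength_nm = 760,
                       medium_index = 1.518, pupil_fill = 1.0) {
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 16L || n_pixels %% 2L != 0L)
    stop("n_pixels must be an even integer >= 16")
  if (!(na > 0 && na <= medium_index))
    stop("need 0 < na <= medium_index (NA cannot exceed the immersion index)")
  if (!(wavelength_nm > 0)) stop("wavelength_nm must be positive")
  if (!(pupil_fill > 0 && pupil_fill <= 1)) stop("pupil_fill must be in (0, 1]")

  # unit-disk coordinate of pixel i (1-based): (i - 1 - n/2) / (fill * n/2)
  u <- (seq_len(n_pixels) - 1 - n_pixels / 2) / (pupil_fill * n_pixels / 2)
  ux <- matrix(u, n_pixels, n_pixels)            # varies along rows (x)
  uy <- matrix(u, n_pixels, n_pixels, byrow = TRUE)
  rho <- sqrt(ux^2 + uy^2)
  theta <- atan2(uy, ux)
  aperture <- rho < 1

  structure(list(n_pixels = n_pixels, na = na, wavelength_nm = wavelength_nm,
                 medium_index = medium_index, pupil_fill = pupil_fill,
                 ux = ux, uy = uy, rho = rho, theta = theta,
                 aperture = aperture),
            class = "pupil_grid")
}

#' @export
print.pupil_grid <- function(x, ...) {
  cat(sprintf("pupil_grid: %dx%d, NA=%.2f, lambda=%g nm, n=%.3f, fill=%.2f\n",
              x$n_pixels, x$n_pixels, x$na, x$wavelength_nm,
              x$medium_index, x$pupil_fill))
  invisible(x)
}

#' Spherical-cap defocus phase
#'
#' Pupil phase for an axial displacement `z_um` of the focus in the immersion
#' medium: phi(rho) = (2*pi/lambda) * z * sqrt(n^2 - NA^2 rho^2). Exact
#' high-NA form; reduces to the paraxial quadratic at low NA. Odd in z, so
#' the +z and -z phases are exact negatives — the property that makes
#' corrections recovered for front/back focal planes inverses of each other.
#'
#' @param grid a [pupil_grid()].
#' @param z_um axial offset in micrometres (positive = away from objective).
#' @return numeric matrix of phase in radians (unwrapped), zero outside the
#'   aperture.
#' @export
defocus_phase <- function(grid, z_um) {
  stopifnot(inherits(grid, "pupil_grid"))
  z_nm <- z_um * 1000
  arg <- grid$medium_index^2 - (grid$na * grid$rho)^2
  arg[arg < 0] <- 0  # rho marginally outside NA cone (masked anyway)
  phi <- (2 * pi / grid$wavelength_nm) * z_nm * sqrt(arg)
  phi[!grid$aperture] <- 0
  phi
}

#' RMS of a phase mask over the aperture
#'
#' Root-mean-square about the aperture mean (piston removed), the standard
#' wavefront-error statistic.
#'
#' @param mask numeric matrix of phase in radians.
#' @param grid a [pupil_grid()].
#' @return RMS in radians.
#' @export
aperture_rms <- function(mask, grid) {
  v <- mask[grid$aperture]
  sqrt(mean((v - mean(v))^2))
}
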