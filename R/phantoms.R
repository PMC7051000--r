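#' Aberration-screen recipe
#'
#' Declarative description of a hidden aberration: a random Zernike mixture
#' (stand-in for system optics or thick tissue — sample aberration is
#' "complicated and unpredictable", so recipes are parameterized and seeded
#' rather than fitted), pure defocus (the artificial system aberration used
#' to test correction away from the focal plane), primary spherical, or a
#' Kolmogorov-like power-law screen.
#'
#' @param kind "zernike_random", "defocus", "spherical" or "turbulence".
#' @param total_rms_rad target piston-removed RMS over the aperture, radians
#'   (ignored by "defocus", which is set by `defocus_um`).
#' @param mode_range Noll indices for "zernike_random" (default 4:11).
#' @param defocus_um axial offset for "defocus" screens, micrometres.
#' @param power_law_exponent amplitude-spectrum exponent for "turbulence"
#'   (default -11/6, i.e. Kolmogorov phase PSD f^(-11/3)).
#' @param rng_seed integer seed; screens are bit-reproducible from
#'   (recipe, seed).
#' @return object of class `screen_recipe`.
#' @export
screen_recipe <- function(kind = c("zernike_random", "defocus", "spherical",
                                   "turbulence"),
                          total_rms_rad = 1.5, mode_range = 4:11,
                          defocus_um = 0.5, power_law_exponent = -11 / 6,
                          rng_seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "zernike_random" && length(mode_range) == 0)
    stop("empty mode range")
  if (total_rms_rad < 0) stop("total_rms_rad must be >= 0")
  structure(list(kind = kind, total_rms_rad = total_rms_rad,
                 mode_range = as.integer(mode_range),
                 defocus_um = defocus_um,
                 power_law_exponent = power_law_exponent,
                 rng_seed = as.integer(rng_seed)),
            class = "screen_recipe")
}

#' Realize an aberration screen from a recipe
#'
#' zernike_random draws coefficients c_j ~ Normal(0, 1/j) over `mode_range`
#' (lower orders dominate, as in real optics) and rescales the summed phase
#' to the exact target aperture RMS. defocus applies the spherical-cap phase
#' for `defocus_um` (odd in z, so +z/-z screens are exact negatives).
#' spherical puts the whole budget in Noll j=11. turbulence synthesizes a
#' power-law random screen by filtered white noise, removes piston, and
#' rescales.
#'
#' @param recipe a [screen_recipe()].
#' @param grid a [pupil_grid()].
#' @return an [aberration_screen()].
#' @export
make_screen <- function(recipe, grid) {
  stopifnot(inherits(recipe, "screen_recipe"), inherits(grid, "pupil_grid"))
  set.seed(recipe$rng_seed)
  phase <- switch(recipe$kind,
    zernike_random = {
      js <- recipe$mode_range
      cf <- stats::rnorm(length(js), 0, 1 / js)
      m <- zernike_phase(stats::setNames(cf, js), grid)
      rescale_rms(m, recipe$total_rms_rad, grid)
    },
    defocus = defocus_phase(grid, recipe$defocus_um),
    spherical = zernike_phase(c("11" = recipe$total_rms_rad), grid),
    turbulence = {
      n <- grid$n_pixels
      f <- sqrt(outer(fft_freqs(n)^2, fft_freqs(n)^2, `+`))
      f[1, 1] <- Inf  # kill the DC term
      spec_amp <- f^recipe$power_law_exponent
      noise <- matrix(stats::rnorm(n * n), n, n)
      scr <- Re(stats::fft(stats::fft(noise) * spec_amp, inverse = TRUE)) / n^2
      scr[!grid$aperture] <- 0
      rescale_rms(scr, recipe$total_rms_rad, grid)
    })
  src <- if (recipe$kind == "defocus") "artificial_defocus"
         else if (recipe$kind == "zernike_random") "sample" else "system"
  aberration_screen(phase, src,
                    sprintf("%s screen, seed %d", recipe$kind,
                            recipe$rng_seed))
}

fft_freqs <- function(n) c(0:(n / 2 - 1), -(n / 2):-1) / n

rescale_rms <- function(mask, target, grid) {
  if (target == 0) return(mask * 0)
  v <- mask[grid$aperture]
  v <- v - mean(v)
  r <- sqrt(mean(v^2))
  if (r == 0) stop("cannot rescale a flat screen to nonzero RMS")
  out <- mask * 0
  out[grid$aperture] <- v * (target / r)
  out
}

#' Random bead-field phantom
#'
#' Dart-throwing placement of point emitters (100 nm fluorescent
#' microspheres at this scale act as points) honouring a minimum
#' separation, plus optional sub-diffraction close pairs to probe
#' resolvability.
#'
#' @param n_beads number of isolated beads.
#' @param min_separation_nm minimum pairwise distance.
#' @param field_size_nm side of the square field.
#' @param rng_seed integer seed.
#' @param n_close_pairs number of additional bead pairs.
#' @param pair_separation_nm centre distance within a pair (default 150 nm,
#'   between typical STED and confocal FWHMs).
#' @param brightness_sd lognormal sd of emitter brightness (0 = uniform).
#' @return object of class `phantom`: list with `emitters` (data.frame
#'   x_nm, y_nm, brightness), `kind`, `field_size_nm`.
#' @export
make_bead_field <- function(n_beads, min_separation_nm = 400,
                            field_size_nm = 4000, rng_seed = 1L,
                            n_close_pairs = 0L, pair_separation_nm = 150,
                            brightness_sd = 0) {
  set.seed(rng_seed)
  margin <- 0.08 * field_size_nm
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n_beads) {
    cand <- stats::runif(2, margin, field_size_nm - margin)
    ok <- nrow(pts) == 0 ||
      min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
        min_separation_nm
    if (ok) pts <- rbind(pts, cand)
    tries <- tries + 1L
    if (tries > 1000L * max(1L, n_beads))
      stop("infeasible bead packing: ", n_beads, " beads at ",
           min_separation_nm, " nm in a ", field_size_nm, " nm field")
  }
  if (n_close_pairs > 0) {
    for (k in seq_len(n_close_pairs)) {
      repeat {
        c0 <- stats::runif(2, margin, field_size_nm - margin)
        ang <- stats::runif(1, 0, 2 * pi)
        d <- c(cos(ang), sin(ang)) * pair_separation_nm / 2
        p1 <- c0 + d; p2 <- c0 - d
        ok <- nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - p1[1])^2 + (pts[, 2] - p1[2])^2),
              sqrt((pts[, 1] - p2[1])^2 + (pts[, 2] - p2[2])^2)) >=
            min_separation_nm
        tries <- tries + 1L
        if (ok) { pts <- rbind(pts, p1, p2); break }
        if (tries > 2000L * (n_beads + n_close_pairs))
          stop("infeasible close-pair packing")
      }
    }
  }
  nb <- nrow(pts)
  br <- if (brightness_sd > 0) stats::rlnorm(nb, 0, brightness_sd)
        else rep(1, nb)
  structure(list(emitters = data.frame(x_nm = pts[, 1], y_nm = pts[, 2],
                                       brightness = br)[seq_len(nb), ],
                 kind = if (n_close_pairs > 0) "bead_pair" else "bead_field",
                 field_size_nm = field_size_nm),
            class = "phantom")
}

#' Filament-network phantom
#'
#' Smooth random-walk polylines densely sampled into emitters — a stand-in
#' for immunolabelled microtubule networks. Direction decorrelates over
#' `persistence_nm`; `width_nm` adds lateral Gaussian jitter (label/filament
#' width); crossings are allowed.
#'
#' @param n_filaments number of filaments.
#' @param persistence_nm directional persistence length.
#' @param width_nm filament width (Gaussian sd = width/2.355).
#' @param field_size_nm side of the square field.
#' @param rng_seed integer seed.
#' @param step_nm emitter spacing along the filament (default 25 nm, well
#'   under a quarter of any confocal FWHM).
#' @return a `phantom`.
#' @export
make_filaments <- function(n_filaments = 3L, persistence_nm = 2000,
                           width_nm = 0, field_size_nm = 4000,
                           rng_seed = 1L, step_nm = 25) {
  if (width_nm < 0) stop("width_nm must be >= 0")
  set.seed(rng_seed)
  margin <- 0.05 * field_size_nm
  xs <- numeric(0); ys <- numeric(0)
  for (f in seq_len(n_filaments)) {
    p <- stats::runif(2, margin, field_size_nm - margin)
    ang <- stats::runif(1, 0, 2 * pi)
    n_steps <- ceiling(1.5 * field_size_nm / step_nm)
    for (s in seq_len(n_steps)) {
      p <- p + step_nm * c(cos(ang), sin(ang))
      if (any(p < margin) || any(p > field_size_nm - margin)) break
      q <- p
      if (width_nm > 0)
        q <- q + stats::rnorm(2, 0, width_nm / (2 * sqrt(2 * log(2))))
      q <- pmin(pmax(q, margin), field_size_nm - margin)
      xs <- c(xs, q[1]); ys <- c(ys, q[2])
      ang <- ang + stats::rnorm(1, 0, sqrt(step_nm / persistence_nm))
    }
  }
  structure(list(emitters = data.frame(x_nm = xs, y_nm = ys,
                                       brightness = rep(1, length(xs))),
                 kind = "filaments", field_size_nm = field_size_nm),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom [%s]: %d emitters in a %g nm field\n", x$kind,
              nrow(x$emitters), x$field_size_nm))
  invisible(x)
}
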