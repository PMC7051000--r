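# sted_microscope: guide-star fitness, effective PSF, image formation

test_that("guide-star signal: ceiling, conjugate cancellation, aberration drop", {
  g <- pupil_grid(64)
  zero <- zero_mask(g)
  expect_equal(guide_star_signal(zero, aberration_screen(zero), g), 1.0,
               tolerance = 1e-12)
  scr <- make_screen(screen_recipe("zernike_random", 1.5, 4:11, rng_seed = 5), g)
  # exact conjugate restores the unaberrated value
  expect_equal(guide_star_signal(-scr$phase, scr, g), 1.0, tolerance = 1e-9)
  # 1.5 rad RMS screen: fitness well below 0.8 x ceiling (Strehl exp(-sigma^2)
  # ~ 0.105 predicts a large drop; the pinhole integral is less extreme)
  f <- guide_star_signal(zero, scr, g)
  expect_lt(f, 0.8)
  expect_gt(f, 0)
})

test_that("fitness is invariant to piston and blazed-grating tilt", {
  g <- pupil_grid(64)
  scr <- make_screen(screen_recipe("zernike_random", 1.0, 4:11, rng_seed = 2), g)
  corr <- zernike_phase(c("4" = 0.4, "7" = -0.3), g)
  f0 <- guide_star_signal(corr, scr, g)
  f_piston <- guide_star_signal(corr + 0.7, scr, g)
  expect_equal(f_piston, f0, tolerance = 1e-9)
  # a blazed-grating tilt rigidly translates the whole intensity pattern:
  # the PSF with tilt, shifted back by N/period pixels, equals the PSF
  # without tilt (so any pinhole signal is invariant once the shift is
  # tracked)
  period <- 32
  shift <- 64 * 4 / period   # 8 focal pixels
  p0 <- focal_psf(g, compose_masks(corr, scr$phase))
  p1 <- focal_psf(g, compose_masks(corr, scr$phase, blazed_grating(g, period)))
  rows <- 50:200
  expect_lt(max(abs(p1[rows + shift, ] - p0[rows, ])) / max(p0), 1e-9)
})

test_that("engine agrees with the contract op to FFT round-off", {
  g <- pupil_grid(64)
  scr <- make_screen(screen_recipe("zernike_random", 1.2, 4:11, rng_seed = 9), g)
  eng <- guide_star_engine(g, scr)
  set.seed(1)
  for (k in 1:3) {
    corr <- zernike_phase(setNames(rnorm(3, 0, 0.5), c("4", "6", "8")), g)
    expect_rel(eng(corr), guide_star_signal(corr, scr, g), 1e-10)
  }
})

test_that("guide-star noise and position validation", {
  g <- pupil_grid(64)
  scr <- aberration_screen(zero_mask(g))
  v1 <- guide_star_signal(zero_mask(g), scr, g, noise_sd = 0.05, rng_seed = 42)
  v2 <- guide_star_signal(zero_mask(g), scr, g, noise_sd = 0.05, rng_seed = 42)
  expect_equal(v1, v2)
  expect_false(isTRUE(all.equal(v1, 1.0)))
  far <- guide_star(position_nm = c(1e6, 0))
  expect_error(guide_star_signal(zero_mask(g), scr, g, star = far),
               "outside")
})

test_that("effective STED PSF: limits and donut null preservation", {
  g <- pupil_grid(64)
  exc <- focal_psf(g)
  dep <- focal_psf(g, spiral_phase(g))
  expect_equal(unclass(effective_sted_psf(exc, dep, 0)), unclass(exc),
               ignore_attr = TRUE)
  # suppression factor exactly 1/2 where the (normalized) donut peaks
  h1 <- effective_sted_psf(exc, dep, 1)
  i_pk <- which.max(as.matrix(dep))
  expect_equal(h1[i_pk] / exc[i_pk], 0.5, tolerance = 1e-12)
  # perfect donut: centre untouched for any zeta
  ctr <- 64 * 4 / 2 + 1
  h16 <- effective_sted_psf(exc, dep, 16)
  expect_rel(h16[ctr, ctr], exc[ctr, ctr], 1e-4)
  expect_error(effective_sted_psf(exc, dep, -1), "zeta")
  expect_error(effective_sted_psf(exc, focal_psf(g, oversample = 2), 1),
               "shape")
  # monotone FWHM shrinkage with zeta
  fw <- vapply(c(0, 1, 4, 16), function(z)
    psf_fwhm(effective_sted_psf(exc, dep, z)), numeric(1))
  expect_true(all(diff(fw) < 0))
})

test_that("scan_image: delta response, empty phantom, two-emitter separation", {
  g <- pupil_grid(64)
  psf <- focal_psf(g, oversample = 2)
  px <- attr(psf, "pixel_size_nm")
  field <- 64 * 2 * px
  x0 <- 63.5 * px   # centre of image pixel 64: no splat spreading
  # single pixel-centred emitter -> image proportional to the PSF
  ph1 <- structure(list(emitters = data.frame(x_nm = x0, y_nm = x0,
                                              brightness = 2),
                        kind = "bead_field", field_size_nm = field),
                   class = "phantom")
  img <- scan_image(ph1, psf, photon_scale = 10)
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_equal(max(img), 20, tolerance = 1e-6)
  expect_equal(as.numeric(pk), c(64, 64))
  ph0 <- structure(list(emitters = data.frame(x_nm = numeric(0),
                                              y_nm = numeric(0),
                                              brightness = numeric(0)),
                        kind = "bead_field", field_size_nm = field),
                   class = "phantom")
  expect_equal(max(scan_image(ph0, psf)), 0)
  # two emitters 3 FWHM apart -> two maxima at the emitter positions +/- 1 px
  fw <- psf_fwhm(psf)
  x1 <- x0 - 1.5 * fw; x2 <- x0 + 1.5 * fw
  ph2 <- structure(list(emitters = data.frame(x_nm = c(x1, x2),
                                              y_nm = x0,
                                              brightness = 1),
                        kind = "bead_field", field_size_nm = field),
                   class = "phantom")
  img2 <- scan_image(ph2, psf)
  row_prof <- img2[, 64]
  pks <- which(diff(sign(diff(row_prof))) == -2) + 1
  pks <- pks[row_prof[pks] > 0.5 * max(row_prof)]
  expect_equal(length(pks), 2)
  expect_equal(pks[1] * px - px / 2, x1, tolerance = 1.5 * px)
  expect_equal(pks[2] * px - px / 2, x2, tolerance = 1.5 * px)
  # emitter outside field errors
  ph_bad <- structure(list(emitters = data.frame(x_nm = 2 * field,
                                                 y_nm = 0, brightness = 1),
                           kind = "bead_field", field_size_nm = field),
                      class = "phantom")
  expect_error(scan_image(ph_bad, psf), "outside")
})

test_that("Poisson noise is unbiased (mean of replicates ~ noiseless image)", {
  g <- pupil_grid(32)
  psf <- focal_psf(g, oversample = 2)
  px <- attr(psf, "pixel_size_nm")
  field <- 64 * px
  ph <- structure(list(emitters = data.frame(x_nm = field / 2,
                                             y_nm = field / 2,
                                             brightness = 1),
                       kind = "bead_field", field_size_nm = field),
                  class = "phantom")
  clean <- scan_image(ph, psf, photon_scale = 50)
  n_rep <- 400
  acc <- matrix(0, nrow(clean), ncol(clean))
  for (k in seq_len(n_rep))
    acc <- acc + scan_image(ph, psf, photon_scale = 50, noise = "poisson",
                            rng_seed = 1000 + k)
  m <- acc / n_rep
  # restrict to pixels where the normal approximation holds
  sel <- clean * n_rep > 20
  se <- sqrt(clean[sel] / n_rep)
  frac_outside <- mean(abs(m[sel] - clean[sel]) > 3 * se)
  expect_lt(frac_outside, 0.015)   # ~0.3% expected by chance
})

test_that("null is filled by odd-order (coma) but not even-order (astigmatism) aberrations", {
  # companion to the donut-restoration acceptance test: parity argument
  g <- pupil_grid(128)
  sp <- spiral_phase(g)
  d_astig <- focal_psf(g, compose_masks(sp, zernike_phase(c("6" = 1), g)))
  d_coma <- focal_psf(g, compose_masks(sp, zernike_phase(c("8" = 1), g)))
  expect_lt(metric_null_depth(d_astig), 1e-6)
  expect_gt(metric_null_depth(d_coma), 0.05)
})
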