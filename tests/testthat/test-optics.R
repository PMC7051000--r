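# optics_core: pupil, Zernike, masks, segments, quantization

test_that("pupil grid validates inputs and is point-symmetric", {
  expect_error(pupil_grid(15), "even")
  expect_error(pupil_grid(64, na = 1.6, medium_index = 1.518), "na")
  expect_error(pupil_grid(64, pupil_fill = 0), "pupil_fill")
  g <- pupil_grid(64)
  ap <- g$aperture
  # point symmetry about the grid centre: pixel (i,j) <-> (2c-i, 2c-j)
  c0 <- 64 / 2 + 1
  idx <- which(ap, arr.ind = TRUE)
  mi <- 2 * c0 - idx[, 1]; mj <- 2 * c0 - idx[, 2]
  on_grid <- mi >= 1 & mi <= 64 & mj >= 1 & mj <= 64
  expect_true(all(on_grid))
  expect_true(all(ap[cbind(mi, mj)]))
})

test_that("Noll indexing matches the reference table", {
  ref <- data.frame(
    j = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15),
    n = c(0, 1, 1, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 4),
    m = c(0, 1, -1, 0, -2, 2, -1, 1, -3, 3, 0, 2, -2, 4, -4))
  got <- noll_to_nm(ref$j)
  expect_equal(got$n, ref$n)
  expect_equal(got$m, ref$m)
  expect_error(noll_to_nm(0), ">= 1")
})

test_that("zernike_phase: piston, empty map, unit-RMS defocus", {
  g <- pupil_grid(256)
  p <- zernike_phase(c("1" = 1.0), g)
  expect_true(all(p[g$aperture] == 1.0))
  expect_true(all(p[!g$aperture] == 0))
  expect_equal(zernike_phase(setNames(numeric(0), character(0)), g),
               matrix(0, 256, 256))
  # independent quadrature oracle: sqrt(3)(2 rho^2 - 1) RMS over the disk
  z4 <- zernike_phase(c("4" = 1.0), g)
  oracle <- sqrt(3) * (2 * g$rho[g$aperture]^2 - 1)
  expect_lt(max(abs(z4[g$aperture] - oracle)), 1e-12)
  expect_rel(sqrt(mean(oracle^2)), 1.0, 0.01)
  expect_rel(sqrt(mean(z4[g$aperture]^2)), 1.0, 0.01)
  expect_error(zernike_phase(c(x = 1), g), "unknown Zernike mode")
  expect_error(zernike_phase(1.0, g), "named")
})

test_that("Zernike modes 2..15 are orthonormal on a 256^2 aperture", {
  g <- pupil_grid(256)
  B <- zernike_basis(2:15, g)
  G <- crossprod(B) / sum(g$aperture)   # inner products, disk-normalized
  expect_true(all(abs(diag(G) - 1) < 0.01))
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 0.01)
})

test_that("spiral phase: axis values, charge wrap, zero-charge error", {
  g <- pupil_grid(64)
  c0 <- 64 / 2 + 1
  s1 <- spiral_phase(g, 1)
  expect_equal(s1[c0 + 10, c0], 0)            # +x axis: azimuth 0
  expect_equal(s1[c0, c0 + 10], pi / 2)       # +y axis
  s2 <- spiral_phase(g, 2)
  expect_equal(s2[c0 - 10, c0], 0)            # wrap(2*pi) on -x axis
  expect_error(spiral_phase(g, 0), "nonzero")
})

test_that("blazed grating: periodicity, degenerate inputs, PSF shift", {
  g <- pupil_grid(32)
  b <- blazed_grating(g, period_px = 8, direction = c(1, 0))
  # displacement by one period accumulates 2*pi -> wraps to the same value
  d <- abs(b[1:24, 5] - b[9:32, 5])
  expect_lt(max(pmin(d, 2 * pi - d)), 1e-9)
  expect_error(blazed_grating(g, 1.5), "period")
  expect_error(blazed_grating(g, 8, c(0, 0)), "nonzero 2-vector")

  # Fourier shift theorem: centroid shift = N/period focal pixels
  ov <- 4L
  for (period in c(8, 16)) {
    p0 <- focal_psf(g, oversample = ov)
    p1 <- focal_psf(g, blazed_grating(g, period), oversample = ov)
    pk0 <- which(p0 == max(p0), arr.ind = TRUE)[1, ]
    pk1 <- which(p1 == max(p1), arr.ind = TRUE)[1, ]
    expect_equal(unname(pk1[1] - pk0[1]), 32 * ov / period, tolerance = 0.1)
    expect_equal(unname(pk1[2] - pk0[2]), 0)
    # peak value invariant to the tilt
    expect_lt(abs(max(p1) - max(p0)) / max(p0), 1e-9)
  }
})

test_that("segment layout tiles exactly; 1080-pixel region gives 120x120 blocks", {
  lay <- segment_layout(3, 1080)
  expect_equal(lay$n_segments, 81L)
  sizes <- table(lay$index)
  expect_true(all(sizes == 120 * 120))
  # proportional mapping on a 128 grid still tiles with no gap/overlap
  g <- pupil_grid(128)
  lay2 <- segment_layout(3, g)
  expect_equal(sort(unique(as.vector(lay2$index))), 1:81)
  expect_equal(sum(table(lay2$index)), 128L * 128L)
  # blocks are contiguous rectangles: each row range x col range is exact
  for (s in c(1, 41, 81)) {
    px <- which(lay2$index == s, arr.ind = TRUE)
    expect_equal(nrow(px),
                 length(unique(px[, 1])) * length(unique(px[, 2])))
    expect_equal(sort(unique(px[, 1])),
                 seq(min(px[, 1]), max(px[, 1])))
  }
  expect_error(segment_layout(0), "positive")
})

test_that("segment phase maps levels to 2*pi*L/256 and validates", {
  g <- pupil_grid(36)
  lay <- segment_layout(1, g)   # 9 segments
  expect_equal(segment_phase(rep(0, 9), lay, g), matrix(0, 36, 36))
  m <- segment_phase(rep(128, 9), lay, g)
  expect_true(all(abs(m - pi) < 1e-12))
  # constant-pi mask leaves PSF intensity unchanged (pure piston)
  p0 <- focal_psf(g); p1 <- focal_psf(g, m)
  expect_lt(max(abs(p1 - p0)) / max(p0), 1e-9)
  expect_error(segment_phase(rep(0, 8), lay, g), "9 levels")
  expect_error(segment_phase(c(rep(0, 8), 300), lay, g), "255")
})

test_that("quantize/dequantize: exact levels and bounded round trip", {
  g <- pupil_grid(32)
  expect_equal(quantize_mask(matrix(0, 4, 4))[1, 1], 0L)
  expect_equal(quantize_mask(matrix(pi, 4, 4))[1, 1], 128L)
  # exhaustive: all 256 representable levels survive the round trip exactly
  lv <- matrix(0:255, 16, 16)
  expect_equal(unclass(quantize_mask(dequantize_mask(lv)))[seq_along(lv)],
               as.integer(lv), ignore_attr = TRUE)
  # random phases: round-trip error < 2*pi/256 per pixel
  set.seed(42)
  m <- matrix(runif(32 * 32, -10, 10), 32, 32)
  err <- abs(wrap_phase(m) - dequantize_mask(quantize_mask(m)))
  err <- pmin(err, 2 * pi - err)
  expect_lt(max(err), 2 * pi / 256 + 1e-12)
  # phase 2*pi - eps maps to level 255 (floor convention)
  expect_equal(quantize_mask(matrix(2 * pi - 1e-9, 1, 1))[1, 1], 255L)
})

test_that("compose: identity, cancellation, commutativity, shape errors", {
  g <- pupil_grid(32)
  s <- spiral_phase(g)
  expect_equal(compose_masks(s, zero_mask(g)), wrap_phase(s))
  z <- compose_masks(spiral_phase(g, 1), spiral_phase(g, -1))
  expect_true(all(pmin(z, 2 * pi - z) < 1e-9))
  set.seed(7)
  a <- matrix(runif(32^2, 0, 7), 32, 32); b <- matrix(runif(32^2, 0, 7), 32, 32)
  expect_equal(compose_masks(a, b), compose_masks(b, a))
  expect_error(compose_masks(a, matrix(0, 16, 16)), "shape mismatch")
  # wrap idempotence
  expect_equal(wrap_phase(wrap_phase(a)), wrap_phase(a))
})
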