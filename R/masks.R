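#' Wrap phase into [0, 2*pi)
#'
#' Half-open wrap; idempotent. Values exactly 2*pi map to 0.
#'
#' @param x numeric vector/matrix of phase in radians.
#' @return wrapped phase, same shape.
#' @export
wrap_phase <- function(x) x %% (2 * pi)

#' Compose phase masks
#'
#' Pixelwise sum followed by a wrap into [0, 2*pi) — the SLM combination rule
#' for blazed grating + spiral + correction phases. Commutative and
#' associative up to wrap.
#'
#' @param ... phase matrices (or a single list of them), all the same shape.
#' @return wrapped phase matrix.
#' @export
compose_masks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1 && is.list(masks[[1]]) && !is.matrix(masks[[1]]))
    masks <- masks[[1]]
  if (length(masks) == 0) stop("no masks to compose")
  d <- dim(masks[[1]])
  out <- matrix(0, d[1], d[2])
  for (m in masks) {
    if (!identical(dim(m), d))
      stop("mask shape mismatch in compose_masks: ",
           paste(dim(m), collapse = "x"), " vs ", paste(d, collapse = "x"))
    out <- out + m
  }
  wrap_phase(out)
}

#' Spiral (vortex) phase
#'
#' Azimuthal phase ramp wrap(charge * theta) about the grid centre; one full
#' 0..2*pi ramp per unit of topological charge. Loaded on the SLM to turn the
#' Gaussian depletion beam into a donut with an on-axis null.
#'
#' @param grid a [pupil_grid()].
#' @param charge nonzero integer topological charge (default 1).
#' @return wrapped phase matrix (defined on the whole grid).
#' @export
spiral_phase <- function(grid, charge = 1L) {
  stopifnot(inherits(grid, "pupil_grid"))
  if (charge == 0) stop("charge must be nonzero (use a zero mask instead)")
  if (charge != round(charge)) stop("charge must be an integer")
  wrap_phase(charge * grid$theta)
}

#' Blazed grating phase
#'
#' Linear sawtooth ramp wrap(2*pi * (r . direction) / period_px). On the real
#' instrument it diffracts the modulated beam into the first order, away from
#' stray reflections; in the scalar simulator it shifts the focal spot
#' without changing the PSF shape.
#'
#' @param grid a [pupil_grid()].
#' @param period_px grating period in grid pixels, >= 2 (Nyquist).
#' @param direction length-2 numeric, grating direction (normalized
#'   internally; the zero vector is an error).
#' @return wrapped phase matrix.
#' @export
blazed_grating <- function(grid, period_px, direction = c(1, 0)) {
  stopifnot(inherits(grid, "pupil_grid"))
  if (period_px < 2) stop("period_px must be >= 2 (Nyquist limit)")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a nonzero 2-vector")
  d <- direction / nrm
  n <- grid$n_pixels
  px <- matrix(seq_len(n) - 1 - n / 2, n, n)       # pixel offsets from centre
  py <- matrix(seq_len(n) - 1 - n / 2, n, n, byrow = TRUE)
  wrap_phase(2 * pi * (px * d[1] + py * d[2]) / period_px)
}

#' Segment layout for the SLM control region
#'
#' The control region is divided into (3n)^2 = n^2 * 9 square-ish segments;
#' every pixel inside a segment shares one phase level. Segment boundaries
#' are `round(i * n_pixels / segments_per_side)`, which tiles any grid
#' exactly (equal 120x120 blocks on the physical 1080-pixel region with the
#' default 9x9 layout).
#'
#' @param n positive integer; segments per side = 3*n (default n = 3, i.e.
#'   81 segments, the choice that balances accuracy against convergence
#'   speed).
#' @param grid a [pupil_grid()] (or an integer grid side).
#' @return object of class `segment_layout`: list with `n`,
#'   `segments_per_side`, `n_segments`, `n_pixels` and an integer matrix
#'   `index` assigning each grid pixel its segment (1-based, column-major
#'   over segment rows/cols).
#' @export
segment_layout <- function(n = 3L, grid = pupil_grid()) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be a positive integer")
  n_pixels <- if (inherits(grid, "pupil_grid")) grid$n_pixels
              else as.integer(grid)
  s <- 3L * n
  if (s > n_pixels) stop("more segments per side than grid pixels")
  bounds <- round(seq(0, n_pixels, length.out = s + 1))
  # cell id along one axis for each pixel
  axis_cell <- findInterval(seq_len(n_pixels) - 0.5, bounds,
                            rightmost.closed = TRUE)
  index <- matrix(axis_cell, n_pixels, n_pixels) +
    (matrix(axis_cell, n_pixels, n_pixels, byrow = TRUE) - 1L) * s
  structure(list(n = n, segments_per_side = s, n_segments = s * s,
                 n_pixels = n_pixels, index = index),
            class = "segment_layout")
}

#' @export
print.segment_layout <- function(x, ...) {
  cat(sprintf("segment_layout: %d segments (%dx%d) on a %d-pixel grid\n",
              x$n_segments, x$segments_per_side, x$segments_per_side,
              x$n_pixels))
  invisible(x)
}

#' Piecewise-constant phase from segment levels
#'
#' Maps 8-bit SLM levels to phase: level L -> 2*pi*L/256.
#'
#' @param levels integer vector in [0, 255], one per segment.
#' @param layout a [segment_layout()].
#' @param grid a [pupil_grid()] with matching `n_pixels`.
#' @return phase matrix in [0, 2*pi).
#' @export
segment_phase <- function(levels, layout, grid) {
  stopifnot(inherits(layout, "segment_layout"), inherits(grid, "pupil_grid"))
  if (grid$n_pixels != layout$n_pixels)
    stop("layout built for a ", layout$n_pixels, "-pixel grid, got ",
         grid$n_pixels)
  if (length(levels) != layout$n_segments)
    stop("need ", layout$n_segments, " levels, got ", length(levels))
  if (any(levels < 0 | levels > 255)) stop("levels must be in [0, 255]")
  matrix((2 * pi / 256) * levels[layout$index],
         layout$n_pixels, layout$n_pixels)
}

#' Quantize a phase mask to 8-bit SLM levels
#'
#' level = floor(wrap(phase)/(2*pi) * 256) mod 256 — the exact payload an
#' SLM driver consumes. Total function; round-trip error < 2*pi/256 per
#' pixel.
#'
#' @param mask phase matrix in radians.
#' @return object of class `quantized_mask`: integer matrix of levels in
#'   [0, 255] with attribute `levels_per_2pi = 256`.
#' @export
quantize_mask <- function(mask) {
  if (any(!is.finite(mask))) stop("non-finite phase in mask")
  # small epsilon absorbs FP error for exactly representable levels
  lv <- floor(wrap_phase(mask) / (2 * pi) * 256 + 1e-9) %% 256
  structure(matrix(as.integer(lv), nrow(mask), ncol(mask)),
            levels_per_2pi = 256L, class = c("quantized_mask", "matrix"))
}

#' Dequantize 8-bit levels back to phase
#'
#' @param q integer matrix of levels in [0, 255] (a `quantized_mask` or any
#'   integer matrix).
#' @return phase matrix, 2*pi*level/256.
#' @export
dequantize_mask <- function(q) {
  if (any(q < 0 | q > 255)) stop("levels must be in [0, 255]")
  matrix((2 * pi / 256) * as.numeric(q), nrow(q), ncol(q))
}

#' Zero phase mask matching a grid
#' @param grid a [pupil_grid()].
#' @return all-zero matrix.
#' @export
zero_mask <- function(grid) matrix(0, grid$n_pixels, grid$n_pixels)
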