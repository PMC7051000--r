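#' Noll index to (n, m) conversion
#'
#' Standard Noll single-index ordering of Zernike modes: j=1 piston,
#' 2/3 tip/tilt, 4 defocus, 5/6 oblique/vertical astigmatism, 7/8 coma,
#' 11 primary spherical, ... Even j carries the cosine (m > 0) term, odd j
#' the sine (m < 0) term.
#'
#' @param j Noll index (integer >= 1), vectorized.
#' @return data.frame with columns `j`, `n` (radial order), `m` (signed
#'   azimuthal frequency).
#' @export
noll_to_nm <- function(j) {
  j <- as.integer(j)
  if (any(j < 1L)) stop("Noll index must be >= 1, got: ",
                        paste(j[j < 1L], collapse = ", "))
  one <- function(jj) {
    n <- 0L; j1 <- jj - 1L
    while (j1 > n) { j1 <- j1 - (n + 1L); n <- n + 1L }
    # within radial order n, |m| ascends in pairs; parity of n fixes offsets
    am <- if (n %% 2L == 0L) 2L * ((j1 + 1L) %/% 2L) else 2L * (j1 %/% 2L) + 1L
    m <- if (am == 0L) 0L else if (jj %% 2L == 0L) am else -am
    c(n = n, m = m)
  }
  nm <- t(vapply(j, one, c(n = 0L, m = 0L)))
  data.frame(j = j, n = nm[, "n"], m = nm[, "m"])
}

# Zernike radial polynomial R_n^|m|(rho), explicit factorial sum.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  if ((n - m) %% 2 != 0) return(rho * 0)
  out <- rho * 0
  for (k in 0:((n - m) / 2)) {
    c_k <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
    out <- out + c_k * rho^(n - 2 * k)
  }
  out
}

#' Single Zernike mode on a pupil grid
#'
#' Noll-indexed, RMS-normalized (unit coefficient gives unit RMS over the
#' continuous unit disk): sqrt(n+1) R_n^0 for m = 0,
#' sqrt(2(n+1)) R_n^|m| cos(|m| theta) for even j,
#' sqrt(2(n+1)) R_n^|m| sin(|m| theta) for odd j.
#'
#' @param j Noll index.
#' @param grid a [pupil_grid()].
#' @return numeric matrix, zero outside the aperture.
#' @export
zernike_mode <- function(j, grid) {
  stopifnot(inherits(grid, "pupil_grid"))
  nm <- noll_to_nm(j)
  n <- nm$n[1]; m <- nm$m[1]
  r <- zernike_radial(n, m, grid$rho)
  z <- if (m == 0) sqrt(n + 1) * r
       else if (m > 0) sqrt(2 * (n + 1)) * r * cos(m * grid$theta)
       else sqrt(2 * (n + 1)) * r * sin(-m * grid$theta)
  z[!grid$aperture] <- 0
  z
}

#' Zernike phase mask from a coefficient vector
#'
#' Weighted sum of Noll modes; coefficients are in radians RMS, so the
#' (piston-free) aperture RMS of the result is close to the Euclidean norm of
#' the coefficient vector. Returned unwrapped (wrap happens at composition /
#' quantization); zero outside the aperture.
#'
#' @param coefficients named numeric vector; names are Noll indices
#'   (e.g. `c("4" = 0.5, "11" = -0.2)`). An unnamed vector is an error. An
#'   empty vector gives the zero mask.
#' @param grid a [pupil_grid()].
#' @return numeric matrix of phase in radians.
#' @examples
#' g <- pupil_grid(64)
#' m <- zernike_phase(c("4" = 1.0), g)   # 1 rad RMS of defocus
#' @export
zernike_phase <- function(coefficients, grid) {
  stopifnot(inherits(grid, "pupil_grid"))
  out <- matrix(0, grid$n_pixels, grid$n_pixels)
  if (length(coefficients) == 0) return(out)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be named by Noll index")
  js <- suppressWarnings(as.integer(names(coefficients)))
  if (any(is.na(js)) || any(js < 1))
    stop("unknown Zernike mode index: ",
         paste(names(coefficients)[is.na(js) | js < 1], collapse = ", "))
  for (i in seq_along(js))
    out <- out + coefficients[[i]] * zernike_mode(js[i], grid)
  out
}

#' Zernike basis matrix over the aperture
#'
#' Columns are RMS-normalized modes evaluated at the aperture pixels, in the
#' order of `modes`. Precomputed once per GA run so genome decoding is a
#' matrix-vector product.
#'
#' @param modes integer vector of Noll indices.
#' @param grid a [pupil_grid()].
#' @return numeric matrix, `sum(grid$aperture)` rows x `length(modes)` cols.
#' @export
zernike_basis <- function(modes, grid) {
  stopifnot(inherits(grid, "pupil_grid"))
  vapply(modes, function(j) zernike_mode(j, grid)[grid$aperture],
         numeric(sum(grid$aperture)))
}
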