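# Mask and image I/O. No PNG/TIFF codec ships with the pre-installed R
# stack, so the package carries minimal writers/readers for the three plain
# formats it needs: 8-bit BMP and binary PGM for SLM mask payloads, and
# uncompressed 32-bit-float baseline TIFF for PSFs/images. The TIFF writer
# is cross-checked against Python tifffile in the test suite.

#' Write a quantized mask as an 8-bit grayscale BMP
#'
#' Uncompressed BMP with a 256-entry grayscale palette; level 0-255 = phase
#' 0-2*pi, the exact payload an SLM driver consumes. Matrix row 1 is the top
#' image row.
#'
#' @param q a [quantize_mask()] result (or integer matrix in [0, 255]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_bmp <- function(q, path) {
  lv <- as.matrix(q)
  if (any(lv < 0 | lv > 255)) stop("levels must be in [0, 255]")
  h <- nrow(lv); w <- ncol(lv)
  pad <- (4 - w %% 4) %% 4
  data_size <- (w + pad) * h
  off <- 14L + 40L + 256L * 4L
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(off + data_size), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(off), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")   # bottom-up
  writeBin(c(1L), con, size = 2, endian = "little")            # planes
  writeBin(c(8L), con, size = 2, endian = "little")            # bpp
  writeBin(as.integer(c(0, data_size, 2835, 2835, 256, 0)), con,
           size = 4, endian = "little")
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))          # B,G,R,0
  writeBin(pal, con)
  for (r in h:1)   # bottom-up rows
    writeBin(as.raw(c(lv[r, ], rep(0L, pad))), con)
  invisible(path)
}

#' Read an 8-bit grayscale BMP back into levels
#' @param path a BMP written by [write_mask_bmp()] (any uncompressed 8-bit
#'   BMP with a grayscale palette).
#' @return integer matrix of levels in [0, 255].
#' @export
read_mask_bmp <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file")
  le4 <- function(i) sum(as.integer(raw[i:(i + 3)]) * 256^(0:3))
  off <- le4(11); w <- le4(19); h <- le4(23)
  bpp <- as.integer(raw[29]) + 256L * as.integer(raw[30])
  if (bpp != 8) stop("only 8-bit BMP supported")
  pad <- (4 - w %% 4) %% 4
  out <- matrix(0L, h, w)
  p <- off + 1
  for (r in h:1) {
    out[r, ] <- as.integer(raw[p:(p + w - 1)])
    p <- p + w + pad
  }
  out
}

#' Write a quantized mask as binary PGM (P5)
#' @param q integer matrix of levels in [0, 255].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(q, path) {
  lv <- as.matrix(q)
  if (any(lv < 0 | lv > 255)) stop("levels must be in [0, 255]")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(lv), nrow(lv))), con)
  writeBin(as.raw(t(lv)), con)   # row-major scan
  invisible(path)
}

#' Read a binary PGM (P5) mask
#' @param path file written by [write_mask_pgm()].
#' @return integer matrix of levels.
#' @export
read_mask_pgm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # scan the header byte-wise: "P5", width, height, maxval, one whitespace
  ws <- as.raw(c(9, 10, 13, 32))
  tokens <- character(0); i <- 1L; cur <- raw(0)
  while (length(tokens) < 4L && i <= length(raw)) {
    b <- raw[i]
    if (b %in% ws) {
      if (length(cur) > 0) { tokens <- c(tokens, rawToChar(cur)); cur <- raw(0) }
    } else cur <- c(cur, b)
    i <- i + 1L
  }
  if (length(tokens) < 4L || tokens[1] != "P5") stop("not a binary PGM")
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  matrix(as.integer(raw[i:(i + w * h - 1L)]), h, w, byrow = TRUE)
}

#' Write a float32 TIFF (single image or z-stack)
#'
#' Minimal baseline TIFF, little-endian, uncompressed, one strip per page;
#' SampleFormat = IEEE float. Pixel size is stored both as X/YResolution
#' (pixels per cm) and as a JSON ImageDescription
#' `{"pixel_size_nm": ...}` readable by ImageJ/tifffile.
#'
#' @param x matrix or 3-D array (x, y, plane) with a `pixel_size_nm`
#'   attribute, or pass `pixel_size_nm` explicitly.
#' @param path output file.
#' @param pixel_size_nm overrides the attribute.
#' @return `path`, invisibly.
#' @export
write_tiff_float <- function(x, path, pixel_size_nm = NULL) {
  px <- if (!is.null(pixel_size_nm)) pixel_size_nm
        else attr(x, "pixel_size_nm")
  if (is.null(px)) stop("pixel_size_nm not given and not an attribute")
  planes <- if (length(dim(x)) == 3) lapply(seq_len(dim(x)[3]),
                                            function(k) x[, , k])
            else list(as.matrix(x))
  con <- file(path, "wb"); on.exit(close(con))
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con); w2(42); w4(8)   # header; first IFD at 8
  pos <- 8
  desc <- sprintf('{"pixel_size_nm": %.15g}', px)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  ppcm <- 1e7 / px   # pixels per centimetre
  res_den <- if (ppcm * 1000 < 2^31) 1000L else 1L
  res_num <- as.integer(min(2147483647, round(ppcm * res_den)))
  n_tags <- 13L
  for (k in seq_along(planes)) {
    m <- planes[[k]]
    h <- nrow(m); wd <- ncol(m)
    data_bytes <- 4L * h * wd
    ifd_size <- 2L + n_tags * 12L + 4L
    desc_off <- pos + ifd_size
    res_off <- desc_off + length(desc_raw)
    strip_off <- res_off + 16L
    next_ifd <- if (k < length(planes)) strip_off + data_bytes else 0L
    tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
    w2(n_tags)
    tag(256, 4, 1, wd)                 # ImageWidth
    tag(257, 4, 1, h)                  # ImageLength
    tag(258, 3, 1, 32)                 # BitsPerSample
    tag(259, 3, 1, 1)                  # Compression: none
    tag(262, 3, 1, 1)                  # Photometric: BlackIsZero
    tag(270, 2, length(desc_raw), desc_off)   # ImageDescription
    tag(273, 4, 1, strip_off)          # StripOffsets
    tag(277, 3, 1, 1)                  # SamplesPerPixel
    tag(278, 4, 1, h)                  # RowsPerStrip
    tag(279, 4, 1, data_bytes)         # StripByteCounts
    tag(282, 5, 1, res_off)            # XResolution
    tag(283, 5, 1, res_off + 8L)       # YResolution
    tag(339, 3, 1, 3)                  # SampleFormat: IEEE float
    w4(next_ifd)
    writeBin(desc_raw, con)
    w4(c(res_num, res_den, res_num, res_den))
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    pos <- strip_off + data_bytes
  }
  # patch ResolutionUnit? omitted: default (2, inch) unused by our reader;
  # pixel size travels in the description.
  invisible(path)
}

#' Read a float32 TIFF written by [write_tiff_float()]
#' @param path file path.
#' @return matrix or 3-D array with `pixel_size_nm` attribute.
#' @export
read_tiff_float <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II") stop("only little-endian TIFF supported")
  le <- function(i, n) sum(as.numeric(raw[i:(i + n - 1)]) * 256^(0:(n - 1)))
  ifd <- le(5, 4)
  planes <- list(); px <- NA_real_
  while (ifd != 0) {
    nt <- le(ifd + 1, 2)
    tags <- list()
    for (t in seq_len(nt)) {
      base <- ifd + 2 + (t - 1) * 12 + 1
      tags[[as.character(le(base, 2))]] <-
        list(type = le(base + 2, 2), count = le(base + 4, 4),
             value = le(base + 8, 4))
    }
    wd <- tags[["256"]]$value; h <- tags[["257"]]$value
    so <- tags[["273"]]$value; sb <- tags[["279"]]$value
    if (!is.null(tags[["270"]])) {
      dr <- raw[(tags[["270"]]$value + 1):
                  (tags[["270"]]$value + tags[["270"]]$count)]
      d <- rawToChar(dr[dr != as.raw(0)])
      s <- sub(".*pixel_size_nm[^0-9.]*", "", d)
      mm <- regmatches(s, regexpr("[0-9.eE+-]+", s))
      if (length(mm)) px <- as.numeric(mm)
    }
    vals <- readBin(raw[(so + 1):(so + sb)], "numeric", n = sb / 4,
                    size = 4, endian = "little")
    planes[[length(planes) + 1]] <- matrix(vals, h, wd, byrow = TRUE)
    ifd <- le(ifd + 2 + nt * 12 + 1, 4)
  }
  out <- if (length(planes) == 1) planes[[1]]
         else array(unlist(planes), c(dim(planes[[1]]), length(planes)))
  attr(out, "pixel_size_nm") <- px
  out
}

#' Write a GA fitness trace to CSV
#'
#' Columns generation, best, mean, sd, evaluations; a comment header embeds
#' the package version and (optionally) the scenario hash so every artifact
#' is traceable to its exact config.
#'
#' @param trace data.frame from [run_ga()].
#' @param path output file.
#' @param scenario_hash optional hash string.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, scenario_hash = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# stedao %s%s",
                     as.character(utils::packageVersion("stedao")),
                     if (is.null(scenario_hash)) ""
                     else paste0(" scenario ", scenario_hash)), con)
  utils::write.csv(trace, con, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_trace_csv <- function(path)
  utils::read.csv(path, comment.char = "#")

#' Serialize a phantom's emitters to CSV
#' @param phantom a `phantom`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phantom_csv <- function(phantom, path) {
  utils::write.csv(phantom$emitters, path, row.names = FALSE)
  invisible(path)
}
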