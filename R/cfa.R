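#' Colour-filter-array pattern of an SRDA
#'
#' Describes the filter deposition pattern `P(x, y)`: an `L x L` super-pixel
#' tile of band indices `1..L^2` repeated across the sensor.  The reference
#' sensor uses `L = 3` (eight narrow bands plus one broad band).
#'
#' @param L super-pixel side length.
#' @param tile `L x L` integer matrix containing each band index exactly
#'   once; default is row-major `1..L^2`.
#' @param offset integer `(x, y)` phase of the tiling relative to pixel
#'   (1, 1); the super-pixel origin is anchored at the image origin by
#'   default, and the offset exists to probe phase sensitivity.
#' @param band_meta optional per-band metadata, e.g. [srda_band_meta()].
#' @return object of class `cfa_pattern`.
#' @export
cfa_pattern <- function(L = 3, tile = NULL, offset = c(0, 0),
                        band_meta = NULL) {
  if (is.null(tile)) tile <- matrix(seq_len(L^2), L, L, byrow = TRUE)
  tile <- matrix(as.integer(tile), L, L)
  if (!setequal(tile, seq_len(L^2)))
    stop("tile must contain every band index 1..L^2 exactly once")
  if (is.null(band_meta) && L == 3) band_meta <- srda_band_meta()
  structure(list(L = L, tile = tile, offset = as.integer(offset),
                 band_meta = band_meta),
            class = "cfa_pattern")
}

# full-size band-index map P for an nr x nc image
expand_pattern <- function(pattern, nr, nc) {
  L <- pattern$L
  pr <- ((seq_len(nr) - 1 + pattern$offset[2]) %% L) + 1
  pc <- ((seq_len(nc) - 1 + pattern$offset[1]) %% L) + 1
  pattern$tile[pr, pc]
}

#' Read and write a CFA pattern as JSON
#'
#' The serialisation stores the super-pixel side `L`, the tile (row-major),
#' the phase offset and the band metadata.  Band indices are 1-based in the
#' file, matching the deposition-pattern convention `P(x, y) = 1, 2, ...`.
#'
#' @param pattern a [cfa_pattern()].
#' @param path JSON file path.
#' @return `write_cfa_pattern` returns `path` invisibly;
#'   `read_cfa_pattern` returns a [cfa_pattern()].
#' @export
write_cfa_pattern <- function(pattern, path) {
  jsonlite::write_json(list(L = pattern$L,
                            tile = as.vector(t(pattern$tile)),
                            offset = pattern$offset,
                            band_meta = pattern$band_meta),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cfa_pattern
#' @export
read_cfa_pattern <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfa_pattern(L = x$L, tile = matrix(x$tile, x$L, x$L, byrow = TRUE),
              offset = x$offset, band_meta = x$band_meta)
}

#' Sampling-ratio criterion for centre-based demosaicking
#'
#' The fibre-centre-based method is valid for any mosaic size as long as the
#' super-pixel is smaller than the fibrelet image: `T = L / D < 1`.  When
#' `T >= 1` a fibrelet need not cover a complete super-pixel and spectral
#' completeness is no longer guaranteed.
#'
#' @param pattern a [cfa_pattern()].
#' @param D fibrelet diameter on the sensor, in pixels.
#' @return the ratio `T = L / D`, with attribute `"valid"`; warns when
#'   `T >= 1`.
#' @export
check_sampling_ratio <- function(pattern, D) {
  Tr <- pattern$L / D
  if (Tr >= 1)
    warning("sampling ratio T = L/D = ", signif(Tr, 3),
            " >= 1: super-pixel larger than the fibrelet; spectral ",
            "completeness is not guaranteed")
  structure(Tr, valid = Tr < 1)
}

#' Split a raw mosaic frame into sparse per-band images
#'
#' Band `k`'s image holds the raw values at pixels where `P = k` and `NA`
#' elsewhere (the mask is carried by the `NA`s).  Reassembling the defined
#' pixels of all bands reconstructs the raw frame exactly.
#'
#' @param raw raw mosaic image matrix.
#' @param pattern a [cfa_pattern()].
#' @return list of `L^2` matrices with `NA` at undefined pixels.
#' @export
split_mosaic <- function(raw, pattern) {
  stop_if_not_image(raw)
  P <- expand_pattern(pattern, nrow(raw), ncol(raw))
  lapply(seq_len(pattern$L^2), function(k) {
    m <- raw
    m[P != k] <- NA
    m
  })
}

# 1-D regridding along rows: linear interpolation between the lattice rows
# `pos`, clamped to the outermost defined rows at the edges
regrid_rows <- function(mat, pos, n_out) {
  if (length(pos) == 1) return(matrix(mat[1, ], n_out, ncol(mat), byrow = TRUE))
  f <- stats::approx(pos, seq_along(pos), xout = seq_len(n_out), rule = 2)$y
  lo <- pmin(floor(f), length(pos) - 1)
  fr <- f - lo
  mat[lo, , drop = FALSE] * (1 - fr) + mat[lo + 1, , drop = FALSE] * fr
}

#' Simple demosaicking
#'
#' Splits the raw frame according to the filter deposition pattern and fills
#' each band's sparse regular lattice out to the full grid by bilinear
#' interpolation (edge pixels clamp to the outermost defined lattice sites).
#'
#' @param raw raw mosaic image matrix.
#' @param pattern a [cfa_pattern()].
#' @return object of class `spectral_cube`: list with `bands` (list of
#'   `L^2` full-grid matrices) and `band_meta`.
#' @export
simple_demosaick <- function(raw, pattern) {
  stop_if_not_image(raw)
  L <- pattern$L
  nr <- nrow(raw); nc <- ncol(raw)
  bands <- lapply(seq_len(L^2), function(k) {
    ph <- which(pattern$tile == k, arr.ind = TRUE)[1, ]
    rows <- seq(((ph[1] - 1 - pattern$offset[2]) %% L) + 1, nr, by = L)
    cols <- seq(((ph[2] - 1 - pattern$offset[1]) %% L) + 1, nc, by = L)
    sub <- raw[rows, cols, drop = FALSE]
    full_rows <- regrid_rows(sub, rows, nr)
    t(regrid_rows(t(full_rows), cols, nc))
  })
  spectral_cube(bands, band_meta = pattern$band_meta)
}

#' Spectral cube container
#'
#' @param bands list of same-shaped per-band image matrices, in the band
#'   order of the CFA pattern.
#' @param band_meta optional per-band metadata.
#' @return object of class `spectral_cube`.
#' @export
spectral_cube <- function(bands, band_meta = NULL) {
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1) stop("all bands must share one shape")
  if (any(!vapply(bands, function(b) all(is.finite(b)), logical(1))))
    stop("band values must be finite")
  structure(list(bands = bands, band_meta = band_meta),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat("Spectral cube:", length(x$bands), "bands of", d[1], "x", d[2],
      "pixels\n")
  invisible(x)
}

#' Write a spectral cube as a multi-page TIFF with JSON band metadata
#'
#' @param cube a [spectral_cube()].
#' @param path output TIFF path (metadata sidecar at `<path>.json`).
#' @return invisibly, `path`.
#' @export
write_cube <- function(cube, path) {
  rng <- range(unlist(lapply(cube$bands, range)))
  scaled <- lapply(cube$bands, function(b)
    if (diff(rng) > 0) (b - rng[1]) / diff(rng) else b * 0)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  jsonlite::write_json(list(intensity_min = rng[1], intensity_max = rng[2],
                            band_meta = cube$band_meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
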