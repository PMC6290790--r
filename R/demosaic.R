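#' Demosaick, then decomb each band
#'
#' The demosaick-then-filter pathway: simple demosaicking according to the
#' filter deposition pattern, followed by the selected decombing filter
#' applied independently to each band image.  Filtering must occur after
#' demosaicking -- mixing adjacent pixels on the raw mosaic would corrupt
#' the recorded spectra.  For `method = "physical"` the decombing happened
#' optically at the point of capture, so no further filtering takes place
#' after demosaicking.
#'
#' @param raw raw mosaic image matrix.
#' @param pattern a [cfa_pattern()].
#' @param method `"gaussian"`, `"median"`, `"fourier"` or `"physical"`.
#' @param r characteristic filter size (ignored for `"physical"`).
#' @return a [spectral_cube()].
#' @export
demosaick_then_filter <- function(raw, pattern,
                                  method = c("gaussian", "median", "fourier",
                                             "physical"),
                                  r = NULL) {
  method <- match.arg(method)
  cube <- simple_demosaick(raw, pattern)
  if (method == "physical") return(cube)
  cube$bands <- lapply(cube$bands, decomb, method = method, r = r)
  cube
}

#' Fibre-centre-based demosaicking
#'
#' Simultaneous decombing and demosaicking: at each fibre centre the
#' intensity of every spectral band `k` is read from the Euclidean-nearest
#' raw pixel whose pattern index is `k` (`I^k(x_m, y_m) = I(x_NN, y_NN)`
#' with `P(x_NN, y_NN) = k`); the centre's own pixel supplies its own band.
#' Equidistant nearest neighbours (possible for even `L`) are averaged.
#' Requires the sampling ratio `T = L/D < 1` so that every band is found
#' within a fibrelet of every centre.
#'
#' @param raw raw mosaic image matrix.
#' @param pattern a [cfa_pattern()].
#' @param centre_map a [find_centres()] result built from the Gaussian
#'   pre-blurred bright-field calibration frame; its `D` is used for the
#'   sampling-ratio check.
#' @return object of class `centre_spectra`: list with `spectra` (m x L^2
#'   matrix), `centres`, and the pattern's `L`.
#' @export
centre_based_demosaick <- function(raw, pattern, centre_map) {
  stop_if_not_image(raw)
  stopifnot(inherits(centre_map, "centre_map"))
  Tr <- check_sampling_ratio(pattern, centre_map$D)
  if (Tr >= 1)
    stop("sampling ratio T = L/D must be < 1 for centre-based demosaicking")
  L <- pattern$L
  nr <- nrow(raw); nc <- ncol(raw)
  xi <- pmin(pmax(round(centre_map$centres[, 1]), 1), nc)
  yi <- pmin(pmax(round(centre_map$centres[, 2]), 1), nr)
  m <- length(xi)
  offs <- expand.grid(dy = -L:L, dx = -L:L)
  offs$d2 <- offs$dy^2 + offs$dx^2
  offs <- offs[order(offs$d2), ]
  spectra <- matrix(NA_real_, m, L^2)
  phase_r <- ((yi - 1 + pattern$offset[2]) %% L)
  phase_c <- ((xi - 1 + pattern$offset[1]) %% L)
  grp <- phase_r * L + phase_c
  for (g in unique(grp)) {
    sel <- which(grp == g)
    pr <- g %/% L; pc <- g %% L
    band_of <- pattern$tile[cbind(((pr + offs$dy) %% L) + 1,
                                  ((pc + offs$dx) %% L) + 1)]
    for (k in seq_len(L^2)) {
      ok <- which(band_of == k)
      remaining <- sel
      for (lev in unique(offs$d2[ok])) {
        if (length(remaining) == 0) break
        members <- ok[offs$d2[ok] == lev]
        acc <- cnt <- numeric(length(remaining))
        for (t in members) {
          y <- yi[remaining] + offs$dy[t]
          x <- xi[remaining] + offs$dx[t]
          good <- y >= 1 & y <= nr & x >= 1 & x <= nc
          acc[good] <- acc[good] + raw[cbind(y[good], x[good])]
          cnt[good] <- cnt[good] + 1
        }
        found <- cnt > 0
        spectra[remaining[found], k] <- acc[found] / cnt[found]
        remaining <- remaining[!found]
      }
    }
  }
  if (anyNA(spectra))
    stop("incomplete centre spectra despite T < 1; centres may lie ",
         "outside the image")
  structure(list(spectra = spectra,
                 centres = cbind(x = centre_map$centres[, 1],
                                 y = centre_map$centres[, 2]),
                 L = L),
            class = "centre_spectra")
}

#' @export
print.centre_spectra <- function(x, ...) {
  cat("Centre spectra:", nrow(x$spectra), "fibre centres x",
      ncol(x$spectra), "bands\n")
  invisible(x)
}

#' Interpolate centre spectra to a full spectral cube
#'
#' One interpolation table is built from the shared centre map and applied
#' to every band (in every band and every image the interpolation is between
#' the same centre points), yielding a comb-free image per spectral band.
#'
#' @param spectra a [centre_based_demosaick()] result.
#' @param dim output image dimensions `c(nrow, ncol)`.
#' @param lut optional precomputed [interp_lut()] for these centres.
#' @param band_meta optional band metadata for the cube.
#' @return a [spectral_cube()].
#' @export
interpolate_centre_spectra <- function(spectra, dim, lut = NULL,
                                       band_meta = NULL) {
  stopifnot(inherits(spectra, "centre_spectra"))
  if (is.null(lut)) lut <- interp_lut(spectra$centres, dim)
  bands <- lapply(seq_len(ncol(spectra$spectra)), function(k)
    interp_apply(lut, spectra$spectra[, k]))
  spectral_cube(lapply(bands, function(b) { attributes(b) <- attributes(b)["dim"]; b }),
                band_meta = band_meta)
}

#' Write centre spectra as CSV
#'
#' Columns: `x`, `y`, then one column per band.
#'
#' @param spectra a [centre_based_demosaick()] result.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_centre_spectra <- function(spectra, path) {
  tab <- data.frame(x = spectra$centres[, 1], y = spectra$centres[, 2])
  sp <- as.data.frame(spectra$spectra)
  names(sp) <- paste0("band", seq_len(ncol(sp)))
  utils::write.csv(cbind(tab, sp), path, row.names = FALSE)
  invisible(path)
}
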