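#' Spectral calibration of an SRDA fibrescope
#'
#' Combines a source spectrum `G(lambda)` with the per-band responses
#' `R^k(lambda)` of the sensor to predict the ground-truth recorded spectrum
#' `E^k = sum_lambda G(lambda) R^k(lambda)`.  Both tables must share the
#' wavelength grid.
#'
#' @param lambda wavelength grid (nm).
#' @param source source spectrum `G(lambda)` on that grid (>= 0).
#' @param responses matrix of band responses, one column per band, rows
#'   matching `lambda`.
#' @param band_meta optional data frame of band metadata (centre wavelength,
#'   FWHM) carried through for reporting.
#' @return object of class `spectral_calibration` with fields `lambda`,
#'   `source`, `responses`, `E` (length-L^2 predicted spectrum), `band_meta`.
#' @export
spectral_calibration <- function(lambda, source, responses, band_meta = NULL) {
  stopifnot(length(lambda) == length(source),
            nrow(responses) == length(lambda))
  if (any(source < 0) || any(responses < 0))
    stop("source spectrum and band responses must be non-negative")
  E <- as.numeric(colSums(source * responses))
  structure(list(lambda = lambda, source = source, responses = responses,
                 E = E, band_meta = band_meta),
            class = "spectral_calibration")
}

#' Band metadata of the reference 3x3 SRDA
#'
#' Eight narrow bands (average FWHM 30 nm) plus one broad band covering
#' 500-850 nm, matching a commercial 9-band mosaic sensor.
#'
#' @return data frame with columns `band`, `centre_nm`, `fwhm_nm`, `type`.
#' @export
srda_band_meta <- function() {
  data.frame(band = 1:9,
             centre_nm = c(553, 587, 629, 665, 714, 749, 791, 829, 675),
             fwhm_nm = c(30, 30, 30, 27, 26, 30, 30, 30, 350),
             type = c(rep("narrow", 8), "broad"))
}

#' Default synthetic spectral calibration
#'
#' A narrow-band LED source (Gaussian line) seen through Gaussian narrow-band
#' responses and one broad flat-top response, emulating the reference
#' 9-band sensor under 630 nm illumination.  Useful as a fully known ground
#' truth for the accuracy-of-spectral-reconstruction metric.
#'
#' @param source_centre_nm,source_fwhm_nm LED line centre and width.
#' @return a [spectral_calibration()].
#' @export
default_calibration <- function(source_centre_nm = 630,
                                source_fwhm_nm = 20) {
  lambda <- seq(450, 900, by = 1)
  meta <- srda_band_meta()
  g_sd <- source_fwhm_nm / (2 * sqrt(2 * log(2)))
  source <- exp(-(lambda - source_centre_nm)^2 / (2 * g_sd^2))
  responses <- sapply(seq_len(nrow(meta)), function(k) {
    if (meta$type[k] == "narrow") {
      sdk <- meta$fwhm_nm[k] / (2 * sqrt(2 * log(2)))
      exp(-(lambda - meta$centre_nm[k])^2 / (2 * sdk^2))
    } else {
      # broad band: flat 500-850 nm with soft logistic shoulders
      1 / (1 + exp(-(lambda - 500) / 5)) / (1 + exp((lambda - 850) / 5))
    }
  })
  spectral_calibration(lambda, source, responses, band_meta = meta)
}

#' Read a wavelength-value table from CSV
#'
#' Expects a header and a first column of wavelengths; remaining columns are
#' values (a single source spectrum, or one column per band response).
#'
#' @param path CSV file path.
#' @return list with `lambda` and `values` (matrix, one column per series).
#' @export
read_spectrum_csv <- function(path) {
  tab <- utils::read.csv(path)
  list(lambda = tab[[1]], values = as.matrix(tab[, -1, drop = FALSE]))
}

#' Per-band intensities of an ideal scene
#'
#' Either supplied directly or derived from a spectral calibration, in which
#' case the scene's band intensities are proportional to the predicted
#' recorded spectrum `E^k`, scaled so the brightest band equals `peak`.
#'
#' @param band_intensities non-negative numeric vector (one entry per band).
#' @param calibration a [spectral_calibration()] used when
#'   `band_intensities` is missing.
#' @param peak intensity of the brightest band when deriving from a
#'   calibration.
#' @return numeric vector of class `scene_spectrum`.
#' @export
scene_spectrum <- function(band_intensities = NULL, calibration = NULL,
                           peak = 150) {
  if (is.null(band_intensities)) {
    if (is.null(calibration)) stop("supply band_intensities or calibration")
    band_intensities <- calibration$E / max(calibration$E) * peak
  }
  if (any(band_intensities < 0))
    stop("band intensities must be non-negative")
  structure(as.numeric(band_intensities), class = "scene_spectrum")
}
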