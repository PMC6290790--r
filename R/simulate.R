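#' Image a test target through a comb mask
#'
#' Emulates fibre-bundle sampling: each fibrelet mask is binarised at the
#' fixed threshold 0.1 (strictly greater), the mean `M_i` of the target over
#' the binarised support is taken, and the graded mask times `M_i` is summed
#' over fibrelets, `I_sim(x, y) = sum_i C_i(x, y) M_i`.  Gaussian noise is
#' added last.
#'
#' @param target a [make_target()] result or an image matrix on the comb's
#'   pixel grid.
#' @param comb a [generate_comb()] result.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @return image matrix, with the per-fibrelet means attached as attribute
#'   `"fibrelet_means"`.
#' @export
apply_comb <- function(target, comb, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(comb, "comb_mask"))
  T <- if (inherits(target, "test_target")) target$T else target
  stop_if_not_image(T)
  if (!all(dim(T) == dim(comb$C)))
    stop("target and comb must share the pixel grid")
  out <- matrix(0, nrow(T), ncol(T))
  means <- numeric(length(comb$fibrelets))
  for (i in seq_along(comb$fibrelets)) {
    f <- comb$fibrelets[[i]]
    ys <- f$y0 + seq_len(nrow(f$m)) - 1
    xs <- f$x0 + seq_len(ncol(f$m)) - 1
    B <- f$m > 0.1
    if (!any(B))
      stop("degenerate fibrelet ", i, ": empty binarised support")
    means[i] <- mean(T[ys, xs][B])
    out[ys, xs] <- out[ys, xs] + f$m * means[i]
  }
  if (noise_sigma > 0)
    out <- with_seed(seed,
      out + matrix(rnorm(length(out), 0, noise_sigma), nrow(out)))
  attr(out, "fibrelet_means") <- means
  out
}

#' Sample a multispectral scene through a colour filter array
#'
#' Builds the raw mosaic frame an SRDA would record: at each pixel the value
#' of the band selected by the filter deposition pattern `P(x, y)`, plus
#' Gaussian noise.  Composes with [apply_comb()] (comb first, then CFA
#' sampling) to emulate a multispectral fibrescope.
#'
#' @param band_images list of per-band image matrices (a spectral cube), all
#'   on the same grid, in the pattern's band order.
#' @param pattern a [cfa_pattern()].
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @return raw mosaic image matrix.
#' @export
apply_cfa <- function(band_images, pattern, noise_sigma = 0, seed = NULL) {
  if (inherits(band_images, "spectral_cube")) band_images <- band_images$bands
  stopifnot(is.list(band_images), inherits(pattern, "cfa_pattern"))
  dims <- unique(lapply(band_images, dim))
  if (length(dims) != 1) stop("all band images must share one pixel grid")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  if (length(band_images) != pattern$L^2)
    stop("need one band image per pattern band")
  P <- expand_pattern(pattern, nr, nc)
  out <- matrix(0, nr, nc)
  for (k in seq_along(band_images)) {
    sel <- P == k
    out[sel] <- band_images[[k]][sel]
  }
  if (noise_sigma > 0)
    out <- with_seed(seed,
      out + matrix(rnorm(length(out), 0, noise_sigma), nr))
  out
}

#' Per-band images of a multispectral fibre-bundle scene
#'
#' Composes the per-band images an SRDA fibrescope would see before CFA
#' sampling: the comb-sampled scene scaled by each band's scene intensity,
#' plus a stray-light background in the cladding regions.  Real bundles leak
#' scattered light between and around the fibrelets; this background is
#' spectrally different from the transmitted scene (flat by default), and it
#' is exactly the "erroneous" cladding spectrum that comb corrections can
#' mix with the true fibrelet spectra.  Set `cladding_stray = 0` for an
#' idealised perfectly dark cladding.
#'
#' @param target a [make_target()] result or image matrix.
#' @param comb a [generate_comb()] result.
#' @param spectrum per-band scene intensities as fractions of the target
#'   intensity (a [scene_spectrum()] or plain vector).
#' @param cladding_stray stray-light luminance in the cladding as a fraction
#'   of the mean scene intensity (default 0.1).
#' @param stray_spectrum per-band intensities of the stray light; default is
#'   spectrally flat at the scene's mean band intensity.
#' @return list of per-band image matrices (pass to [apply_cfa()]).
#' @export
ms_scene_bands <- function(target, comb, spectrum, cladding_stray = 0.1,
                           stray_spectrum = NULL) {
  s <- as.numeric(spectrum)
  combed <- apply_comb(target, comb)
  T <- if (inherits(target, "test_target")) target$T else target
  if (is.null(stray_spectrum)) stray_spectrum <- rep(mean(s), length(s))
  stray <- cladding_stray * mean(T) * pmax(1 - comb$C, 0)
  lapply(seq_along(s), function(k) combed * s[k] + stray * stray_spectrum[k])
}

#' Physical decombing by defocus
#'
#' Emulates defocusing the image of the fibrescope face: the post-comb
#' (pre-CFA) image is blurred with a Gaussian point-spread function whose
#' width grows with the axial displacement.  The equivalent characteristic
#' filter size is `abs(displacement / 0.5 um)`, so a 5 um displacement maps
#' to r = 10.
#'
#' @param comb_image image matrix (after comb sampling, before any CFA).
#' @param displacement_um axial displacement in micrometres (either sign).
#' @param blur_per_um PSF sigma in pixels per micrometre of displacement;
#'   the defocus PSF of a real system is not characterised here, so the
#'   proportionality constant is configurable.
#' @return list with the blurred `image` and the characteristic size `r`.
#' @export
simulate_defocus <- function(comb_image, displacement_um, blur_per_um = 1) {
  stop_if_not_image(comb_image)
  sigma <- abs(displacement_um) * blur_per_um
  img <- if (sigma > 0) gauss_filter(comb_image, sigma) else comb_image
  list(image = img, r = abs(displacement_um / 0.5))
}

#' Write a simulated frame with its ground-truth sidecar
#'
#' The image goes to a 16-bit single-channel TIFF; the comb specification,
#' seed, true centres, CFA pattern and scene spectrum go to a JSON sidecar
#' next to it, providing the fixture's ground truth.
#'
#' @param image image matrix (any range; rescaled to 16-bit).
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @param comb optional [generate_comb()] result.
#' @param pattern optional [cfa_pattern()].
#' @param spectrum optional [scene_spectrum()].
#' @return invisibly, the sidecar path.
#' @export
write_simulation <- function(image, path, comb = NULL, pattern = NULL,
                             spectrum = NULL) {
  rng <- range(image)
  scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  side <- list(intensity_min = rng[1], intensity_max = rng[2])
  if (!is.null(comb)) {
    side$comb_spec <- unclass(comb$spec)
    side$true_centres <- unname(comb$centres)
  }
  if (!is.null(pattern))
    side$cfa <- list(L = pattern$L, tile = pattern$tile,
                     offset = pattern$offset)
  if (!is.null(spectrum)) side$scene_spectrum <- as.numeric(spectrum)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(path, ".json"))
}

#' Read a frame written by [write_simulation()]
#'
#' @param path TIFF path.
#' @return list with the `image` matrix (restored to its original intensity
#'   range) and the parsed `sidecar` (or `NULL` if absent).
#' @export
read_simulation <- function(path) {
  img <- tiff::readTIFF(path)
  sidecar <- NULL
  if (file.exists(paste0(path, ".json"))) {
    sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                   simplifyVector = TRUE)
    img <- img * (sidecar$intensity_max - sidecar$intensity_min) +
      sidecar$intensity_min
  }
  list(image = img, sidecar = sidecar)
}
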