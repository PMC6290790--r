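# Banded convolution matrix for 1-D Gaussian filtering with mirror
# (symmetric) boundary handling: row i of the result maps input index j to
# the total kernel weight folded onto j by reflection.
gauss_conv_matrix <- function(n, sigma) {
  h <- max(1L, ceiling(3.5 * sigma))
  k <- (-h):h
  w <- exp(-k^2 / (2 * sigma^2))
  w <- w / sum(w)
  A <- matrix(0, n, n)
  i <- seq_len(n)
  for (t in seq_along(k)) {
    j <- i + k[t]
    # fold out-of-range indices back (symmetric reflection, repeated)
    repeat {
      bad_lo <- j < 1
      bad_hi <- j > n
      if (!any(bad_lo) && !any(bad_hi)) break
      j[bad_lo] <- 1 - j[bad_lo]
      j[bad_hi] <- 2 * n + 1 - j[bad_hi]
    }
    idx <- cbind(i, j)
    A[idx] <- A[idx] + w[t]
  }
  A
}

# Separable Gaussian convolution, mirror boundary, any sigma > 0.
gauss_filter <- function(img, sigma) {
  stop_if_not_image(img)
  if (sigma <= 0) return(img)
  Ar <- gauss_conv_matrix(nrow(img), sigma)
  Ac <- if (ncol(img) == nrow(img)) Ar else gauss_conv_matrix(ncol(img), sigma)
  Ar %*% img %*% t(Ac)
}

check_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1 || r <= 1 || r >= 50)
    stop("characteristic filter size r must satisfy 1 < r < 50 pixels",
         call. = FALSE)
  r
}

#' Gaussian decombing
#'
#' Convolves the image with a 2-D Gaussian smoothing kernel of standard
#' deviation `r` pixels (mirror boundary), averaging the comb structure away
#' at the cost of resolution and signal dilution into the cladding.
#'
#' @param image single-channel image matrix.
#' @param r characteristic filter size in pixels, `1 < r < 50`.
#' @return filtered image of the same shape.
#' @export
gaussian_decomb <- function(image, r) {
  gauss_filter(image, check_r(r))
}

#' Median decombing
#'
#' Replaces each pixel by the median of its 2r-by-2r neighbourhood.  The
#' even-sided window has no centre pixel; it is anchored so that its top-left
#' r-by-r quadrant covers the output pixel, and the median of the even sample
#' is the mean of the two central order statistics.  Borders are mirrored.
#'
#' @inheritParams gaussian_decomb
#' @return filtered image of the same shape.
#' @export
median_decomb <- function(image, r) {
  stop_if_not_image(image)
  check_r(r)
  cpp_median_filter(image, as.integer(round(r)))
}

#' Fourier decombing
#'
#' Low-pass filtering in the frequency domain: the discrete Fourier transform
#' is cropped to remove every spatial frequency above the cut-off
#' `f0 = 1 / (2 r)` cycles/pixel (so `r` is the smallest resolvable feature
#' size, by Nyquist), then inverted and the real part taken.  The crop is
#' radial (circular) by default for isotropy; a square crop is available for
#' fidelity testing.
#'
#' @inheritParams gaussian_decomb
#' @param shape `"circular"` (default) or `"square"` support of the retained
#'   low-frequency region.
#' @return filtered image of the same shape.
#' @export
fourier_decomb <- function(image, r, shape = c("circular", "square")) {
  stop_if_not_image(image)
  check_r(r)
  shape <- match.arg(shape)
  f0 <- 1 / (2 * r)
  nr <- nrow(image); nc <- ncol(image)
  fy <- (seq_len(nr) - 1) / nr; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  fx <- (seq_len(nc) - 1) / nc; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  keep <- if (shape == "circular") {
    outer(fy^2, fx^2, "+") <= f0^2
  } else {
    outer(abs(fy), abs(fx), pmax) <= f0
  }
  F <- stats::fft(image)
  Re(stats::fft(F * keep, inverse = TRUE)) / (nr * nc)
}

#' Cut-off frequency of the Fourier decombing filter
#'
#' @param r characteristic filter size in pixels.
#' @return `f0 = 1 / (2 r)` in cycles/pixel.
#' @export
fourier_cutoff <- function(r) 1 / (2 * r)

#' Correction configuration and dispatch
#'
#' Applies one of the five decombing methods.  `"interpolation"` requires a
#' centre map and has no characteristic filter size (interpolation between
#' irregularly spaced points is a spatially variant filter); `"physical"`
#' expects a capture already blurred at the point of imaging (see
#' [simulate_defocus()]) and is therefore the identity here.
#'
#' @param image single-channel image matrix.
#' @param method one of `"gaussian"`, `"median"`, `"fourier"`,
#'   `"interpolation"`, `"physical"`.
#' @param r characteristic filter size (filter methods only).
#' @param centre_map a [find_centres()] result (interpolation only).
#' @param lut optional precomputed interpolation table from
#'   [interp_lut()]; built from the centre map when absent.
#' @return corrected image matrix.
#' @export
decomb <- function(image, method = c("gaussian", "median", "fourier",
                                     "interpolation", "physical"),
                   r = NULL, centre_map = NULL, lut = NULL) {
  method <- match.arg(method)
  switch(method,
    gaussian = gaussian_decomb(image, r),
    median = median_decomb(image, r),
    fourier = fourier_decomb(image, r),
    physical = image,
    interpolation = {
      if (is.null(centre_map) && is.null(lut))
        stop("interpolation decombing requires a centre_map or lut")
      interpolation_decomb(image, centre_map, lut = lut)
    })
}
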