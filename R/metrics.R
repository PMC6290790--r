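#' Michelson contrast of one bar-target element
#'
#' `(I_max - I_min) / (I_max + I_min)`, with the bar and space levels
#' estimated from the element's profile: the image is averaged along the bar
#' direction (over the element's rows), and `I_max` / `I_min` are the means
#' of the profile over the central thirds of the bars and of the spaces.
#' Averaging over many bars makes the estimate robust to residual comb
#' ripple; the contrast is signed, so aliased elements fluctuate around zero
#' instead of accumulating spurious positive contrast.
#'
#' @param image image matrix.
#' @param element one element of a bar target's `geometry$elements`: list
#'   with `rows`, `x0`, `spacing`, `n_periods`.
#' @return signed Michelson contrast (1 for a full-modulation square wave,
#'   0 for a constant image).
#' @export
michelson_contrast <- function(image, element) {
  stop_if_not_image(image)
  prof <- colMeans(image[element$rows, , drop = FALSE])
  s <- element$spacing
  bar_cols <- space_cols <- integer(0)
  for (m in seq_len(element$n_periods) - 1) {
    b0 <- element$x0 + m * 2 * s
    bar_cols <- c(bar_cols, centre_third(b0, s))
    space_cols <- c(space_cols, centre_third(b0 + s, s))
  }
  bar_cols <- bar_cols[bar_cols <= length(prof)]
  space_cols <- space_cols[space_cols <= length(prof)]
  I_max <- mean(prof[bar_cols])
  I_min <- mean(prof[space_cols])
  if (I_max + I_min == 0) return(0)
  (I_max - I_min) / (I_max + I_min)
}

# central third of a bar/space starting at x0 with width s
centre_third <- function(x0, s) {
  lo <- x0 + floor(s / 3)
  hi <- x0 + ceiling(2 * s / 3) - 1
  lo:max(hi, lo)
}

#' Resolution from contrast-versus-spacing measurements
#'
#' Fits a smoothing spline to Michelson contrast versus line spacing and
#' reports the spacing at which the fitted contrast drops below 5% (the
#' threshold is 5%, not the 1% sometimes used, to avoid noise effects at
#' very low contrast).  The fit is only attempted when contrast exceeds 1%
#' at more than 3 distinct line spacings; otherwise the resolution is
#' undefined (`NA`), which [normalise_scores()] maps to the worst score.
#' When the fitted contrast never drops below 5%, resolution is limited by
#' the target and the smallest measured spacing is returned.
#'
#' @param spacings line spacings in pixels.
#' @param contrasts Michelson contrasts at those spacings.
#' @param threshold contrast threshold defining the resolution (default
#'   0.05).
#' @param spar fallback smoothing parameter when cross-validation fails.
#' @return resolution `R` in pixels, or `NA` when undefined.
#' @export
resolution <- function(spacings, contrasts, threshold = 0.05, spar = 0.6) {
  ok <- is.finite(contrasts)
  spacings <- spacings[ok]; contrasts <- contrasts[ok]
  if (length(unique(spacings[contrasts > 0.01])) <= 3) return(NA_real_)
  fit <- tryCatch(stats::smooth.spline(spacings, contrasts, cv = FALSE),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit))
    fit <- tryCatch(stats::smooth.spline(spacings, contrasts, spar = spar),
                    error = function(e) NULL)
  grid <- seq(min(spacings), max(spacings), length.out = 512)
  pred <- if (is.null(fit)) {
    stats::approx(spacings, contrasts, xout = grid, rule = 2)$y
  } else {
    stats::predict(fit, grid)$y
  }
  below <- which(pred < threshold)
  if (length(below) == 0) return(min(spacings))
  grid[max(below)]
}

#' Smoothness (spatial standard deviation)
#'
#' Population standard deviation of a flat-field image (or a designated
#' rectangular region of it); for a spectral cube, the average of the
#' per-band standard deviations.  Smaller is smoother.
#'
#' @param x image matrix or [spectral_cube()].
#' @param region optional rectangle `c(x0, y0, w, h)`.
#' @return spatial standard deviation `sigma`.
#' @export
smoothness <- function(x, region = NULL) {
  if (inherits(x, "spectral_cube"))
    return(mean(vapply(x$bands, smoothness, numeric(1), region = region)))
  v <- as.numeric(crop_region(x, region))
  sqrt(mean((v - mean(v))^2))
}

crop_region <- function(img, region) {
  if (is.null(region)) return(img)
  img[region[2]:(region[2] + region[4] - 1),
      region[1]:(region[1] + region[3] - 1), drop = FALSE]
}

#' Signal (mean intensity in a region of interest)
#'
#' Mean pixel intensity over the ROI; for a spectral cube, averaged over the
#' bands that overlap the emission spectrum of interest (default: the bands
#' centred at 665 and 714 nm plus the broad band, matching a far-red
#' fluorophore such as AF647 on the reference 9-band sensor).
#'
#' @param x image matrix or [spectral_cube()].
#' @param roi rectangle `c(x0, y0, w, h)`.
#' @param bands band indices used for cubes.
#' @return mean signal `S`.
#' @export
signal_roi <- function(x, roi, bands = c(4, 5, 9)) {
  if (inherits(x, "spectral_cube"))
    return(mean(vapply(x$bands[bands], signal_roi, numeric(1), roi = roi)))
  mean(crop_region(x, roi))
}

#' Processing speed of a correction
#'
#' Median wall-clock seconds per corrected frame over repeated runs.  Speed
#' is reported for information but never enters the overall-performance
#' score, since it can be optimised independently of image quality.
#'
#' @param fun correction callable taking the frame.
#' @param frame input image (or raw mosaic) passed to `fun`.
#' @param reps number of repeats (>= 5 recommended).
#' @return median elapsed seconds per frame.
#' @export
speed_metric <- function(fun, frame, reps = 5) {
  t <- vapply(seq_len(reps), function(i)
    unname(system.time(fun(frame))["elapsed"]), numeric(1))
  stats::median(t)
}

#' Accuracy of spectral reconstruction
#'
#' Mean squared difference `Q` between the cube's spatially averaged
#' spectrum and the predicted ground-truth recorded spectrum `E^k`, both
#' normalised to unit area (AUC = 1).  The spectra are averaged over all
#' pixels *before* normalisation, so image non-smoothness (already captured
#' by the smoothness metric) does not leak into `Q`.  Smaller `Q` means a
#' more faithful spectrum; `Q = 0` whenever the mean spectrum is
#' proportional to `E`.
#'
#' @param cube a [spectral_cube()].
#' @param E predicted recorded spectrum: numeric vector of band values, or a
#'   [spectral_calibration()].
#' @return mean squared spectral difference `Q`.
#' @export
asr <- function(cube, E) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (inherits(E, "spectral_calibration")) E <- E$E
  if (length(E) != length(cube$bands))
    stop("cube and calibration must share the band count")
  mean_spec <- vapply(cube$bands, mean, numeric(1))
  if (sum(mean_spec) == 0 || sum(E) == 0)
    stop("zero-sum spectrum: ASR undefined")
  sum((mean_spec / sum(mean_spec) - E / sum(E))^2)
}

#' Min-max score normalisation across a comparison set
#'
#' Converts raw metric values measured for every correction method (and
#' filter size) of one benchmark run into scores in `[0, 1]`:
#' `S_res = 1 - (R - R_min)/(R_max - R_min)` and likewise for smoothness and
#' ASR (smaller raw value is better), while `S_signal = (S - S_min)/(S_max -
#' S_min)` (larger raw value is better).  The extrema are taken across all
#' correction methods of the set, so 1 is the best and 0 the worst method in
#' this comparison; scores from different runs are not comparable.  An
#' undefined resolution (validity condition failed) is assigned `R_max`, so
#' its score is 0.  If a metric is constant across the set, every score is
#' defined as 1 and a message is emitted.
#'
#' @param raw data frame with columns `method`, `r`, and any of `R`,
#'   `sigma`, `S`, `Q` (plus optional `t`, carried through).
#' @return the input with score columns `S_res`, `S_smooth`, `S_signal`,
#'   `S_ASR` appended (those whose raw metric is present), and the reference
#'   extrema stored in attribute `"extrema"`.
#' @export
normalise_scores <- function(raw) {
  out <- raw
  extrema <- list()
  minmax <- function(v, larger_better = FALSE) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      message("degenerate comparison set: metric constant; score set to 1")
      return(list(score = rep(1, length(v)), lo = lo, hi = hi))
    }
    s <- (v - lo) / (hi - lo)
    list(score = if (larger_better) s else 1 - s, lo = lo, hi = hi)
  }
  if ("R" %in% names(raw)) {
    R <- raw$R
    if (all(is.na(R))) {
      out$S_res <- rep(0, length(R))
      extrema$R <- c(NA, NA)
    } else {
      R[is.na(R)] <- max(R, na.rm = TRUE)  # undefined resolution -> worst
      nm <- minmax(R)
      out$S_res <- nm$score
      extrema$R <- c(min = nm$lo, max = nm$hi)
    }
  }
  if ("sigma" %in% names(raw)) {
    nm <- minmax(raw$sigma)
    out$S_smooth <- nm$score
    extrema$sigma <- c(min = nm$lo, max = nm$hi)
  }
  if ("S" %in% names(raw)) {
    nm <- minmax(raw$S, larger_better = TRUE)
    out$S_signal <- nm$score
    extrema$S <- c(min = nm$lo, max = nm$hi)
  }
  if ("Q" %in% names(raw)) {
    nm <- minmax(raw$Q)
    out$S_ASR <- nm$score
    extrema$Q <- c(min = nm$lo, max = nm$hi)
  }
  attr(out, "extrema") <- extrema
  out
}
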