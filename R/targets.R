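#' Generate an ideal test target
#'
#' Builds the ideal scenes used by the benchmark: a multi-element bar target
#' (USAF-style, vertical bars at several line spacings) for the resolution
#' metric, a uniform field for the smoothness metric, and a bright region on
#' a darker background for the signal metric.  The ideal scene is Gaussian
#' blurred (imperfections of a real target) and Gaussian noise is added.
#'
#' @param kind one of `"bar_target"`, `"uniform"`, `"bright_region"`.
#' @param side image side in pixels.
#' @param spacings bar target only: vector of line spacings (bar widths) in
#'   pixels; at least 3 distinct spacings are required so that the resolution
#'   metric's validity condition can be assessed.
#' @param bar_value,space_value bar target intensities (full modulation by
#'   default).
#' @param value uniform target intensity.
#' @param background,region_value,region bright-region target: background
#'   intensity, region intensity and region rectangle `c(x0, y0, w, h)`
#'   (`NULL` centres a `side/4` square).
#' @param blur_sigma Gaussian blur of the ideal scene in pixels.
#' @param noise_sigma additive Gaussian noise standard deviation in intensity
#'   units.
#' @param seed RNG seed for the noise.
#' @return an object of class `test_target`: list with the final image `T`,
#'   the noise-free image `clean`, `kind`, `geometry`, `blur_sigma`,
#'   `noise_sigma` and `seed`.  For bar targets, `geometry$elements` lists
#'   per element the row range, left edge `x0`, `spacing` and number of
#'   bar/space periods.
#' @export
make_target <- function(kind = c("bar_target", "uniform", "bright_region"),
                        side = 512,
                        spacings = c(4, 6, 8, 10, 14, 20, 28, 40, 56),
                        bar_value = 150, space_value = 0,
                        value = 150,
                        background = 117, region_value = 156, region = NULL,
                        blur_sigma = 1, noise_sigma = 0, seed = NULL) {
  kind <- match.arg(kind)
  T <- matrix(0, side, side)
  geometry <- list()
  if (kind == "uniform") {
    T[] <- value
    geometry$value <- value
  } else if (kind == "bright_region") {
    if (is.null(region)) {
      w <- round(side / 4)
      region <- c(round((side - w) / 2) + 1, round((side - w) / 2) + 1, w, w)
    }
    T[] <- background
    T[region[2]:(region[2] + region[4] - 1),
      region[1]:(region[1] + region[3] - 1)] <- region_value
    geometry <- list(background = background, region_value = region_value,
                     region = region)
  } else {
    if (length(unique(spacings)) < 3)
      stop("bar_target needs at least 3 distinct line spacings")
    k <- length(spacings)
    margin <- 16L
    gap <- 8L
    h <- floor((side - 2 * margin - (k - 1) * gap) / k)
    if (h < 8) stop("too many elements for this image size")
    T[] <- space_value
    elements <- vector("list", k)
    for (e in seq_len(k)) {
      s <- spacings[e]
      n_per <- floor((side - 2 * margin) / (2 * s))
      if (n_per < 3)
        stop("spacing ", s, " px leaves fewer than 3 bar periods; ",
             "reduce the spacing or enlarge the image")
      y0 <- margin + (e - 1) * (h + gap) + 1
      rows <- y0:(y0 + h - 1)
      width <- n_per * 2 * s
      x0 <- floor((side - width) / 2) + 1
      for (m in seq_len(n_per) - 1) {
        xs <- (x0 + m * 2 * s):(x0 + m * 2 * s + s - 1)
        T[rows, xs] <- bar_value
      }
      elements[[e]] <- list(rows = rows, x0 = x0, spacing = s,
                            n_periods = n_per)
    }
    geometry <- list(elements = elements, bar_value = bar_value,
                     space_value = space_value, spacings = spacings)
  }
  clean <- if (blur_sigma > 0) gauss_filter(T, blur_sigma) else T
  out <- clean
  if (noise_sigma > 0)
    out <- with_seed(seed,
      out + matrix(rnorm(length(out), 0, noise_sigma), nrow(out)))
  structure(list(T = out, clean = clean, kind = kind, geometry = geometry,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 seed = seed),
            class = "test_target")
}

#' @export
print.test_target <- function(x, ...) {
  cat("Test target:", x$kind, "(", nrow(x$T), "x", ncol(x$T), "px ), blur",
      x$blur_sigma, "px, noise sd", x$noise_sigma, "\n")
  invisible(x)
}
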