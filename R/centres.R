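#' Candidate fibre-centre pixels
#'
#' A pixel is a candidate centre iff the intensity range of its
#' `D x D` neighbourhood exceeds `I_min`, i.e. `max(N) - min(N) > I_min`,
#' where `D = 2 d + 1` is roughly the fibrelet diameter and `I_min` is the
#' user's expected minimum intensity difference between fibrelets and
#' cladding.  Pixels whose neighbourhood exits the image are discarded
#' (partial neighbourhoods would bias the subsequent fit score).
#'
#' @param image bright-field calibration image (matrix).
#' @param D neighbourhood side in pixels; odd, >= 3.
#' @param I_min minimal fibrelet/cladding intensity difference (> 0).
#' @return data frame with columns `x`, `y` (1-based pixel coordinates).
#' @export
find_candidates <- function(image, D, I_min) {
  stop_if_not_image(image)
  if (D %% 2 != 1 || D < 3) stop("D must be odd and >= 3")
  if (I_min <= 0) stop("I_min must be > 0")
  d <- (D - 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  if (nr < D || nc < D) stop("image smaller than the neighbourhood")
  rows <- (d + 1):(nr - d)
  cols <- (d + 1):(nc - d)
  # separable running max/min over the (2d+1)^2 window, interior only
  mx <- mn <- image[rows, , drop = FALSE] * NA
  mx[] <- -Inf; mn[] <- Inf
  for (t in -d:d) {
    sub <- image[rows + t, , drop = FALSE]
    mx <- pmax(mx, sub); mn <- pmin(mn, sub)
  }
  MX <- MN <- matrix(0, length(rows), length(cols))
  MX[] <- -Inf; MN[] <- Inf
  for (t in -d:d) {
    MX <- pmax(MX, mx[, cols + t, drop = FALSE])
    MN <- pmin(MN, mn[, cols + t, drop = FALSE])
  }
  hit <- which(MX - MN > I_min, arr.ind = TRUE)
  data.frame(x = cols[hit[, 2]], y = rows[hit[, 1]])
}

#' Quasi-Gaussian fit score of candidate centres
#'
#' For each candidate `(x_c, y_c)` the score
#' `s_c = sum_N (G - I)^2` measures how well the quasi-Gaussian surface
#' `G = H exp(-l^4 / (2 D^2))` fits the `D x D` neighbourhood, with
#' `H = I(x_c, y_c)` and `l` the Euclidean distance from the candidate.
#' `D` in the exponent is the full neighbourhood side `2 d + 1` (not the
#' half-width `d`).  Lower scores are better fits.
#'
#' @param image calibration image.
#' @param candidates data frame with `x`, `y` columns (full neighbourhood
#'   inside the image).
#' @inheritParams find_candidates
#' @return the candidates with a `score` column appended.
#' @export
score_candidates <- function(image, candidates, D) {
  stop_if_not_image(image)
  if (D %% 2 != 1 || D < 3) stop("D must be odd and >= 3")
  d <- (D - 1) / 2
  n <- nrow(candidates)
  if (n == 0) return(cbind(candidates, score = numeric(0)))
  if (any(candidates$x <= d) || any(candidates$x > ncol(image) - d) ||
      any(candidates$y <= d) || any(candidates$y > nrow(image) - d))
    stop("candidate neighbourhood truncated by the image border")
  offs <- expand.grid(dy = -d:d, dx = -d:d)
  w <- exp(-(offs$dx^2 + offs$dy^2)^2 / (2 * D^2))
  # s = H^2 sum(w^2) - 2 H sum(w I) + sum(I^2) over the neighbourhood
  A <- sum(w^2)
  B <- Csum <- numeric(n)
  for (t in seq_len(nrow(offs))) {
    v <- image[cbind(candidates$y + offs$dy[t], candidates$x + offs$dx[t])]
    B <- B + w[t] * v
    Csum <- Csum + v^2
  }
  H <- image[cbind(candidates$y, candidates$x)]
  cbind(candidates, score = H^2 * A - 2 * H * B + Csum)
}

#' Greedy construction of the centre map
#'
#' Candidates are ordered by ascending score (ties broken by raster order,
#' row-major) and accepted if and only if they lie strictly more than one
#' fibre diameter `D` from every centre already on the map; the sweep
#' continues until every candidate has been added or rejected.
#'
#' @param scored data frame with `x`, `y`, `score` columns.
#' @param D fibre diameter used as the exclusion radius (strict `> D`).
#' @return object of class `centre_map`: list with `centres` (m x 2 matrix
#'   of `(x, y)`), `scores` (ascending, in acceptance order), `D` and the
#'   number of candidates examined.
#' @export
build_centre_map <- function(scored, D) {
  if (nrow(scored) == 0)
    return(structure(list(centres = matrix(numeric(0), 0, 2,
                                           dimnames = list(NULL, c("x", "y"))),
                          scores = numeric(0), D = D, n_candidates = 0L),
                     class = "centre_map"))
  ord <- order(scored$score, scored$y, scored$x)
  s <- scored[ord, ]
  acc <- cpp_greedy_exclusion(as.numeric(s$x), as.numeric(s$y), as.numeric(D))
  structure(list(centres = cbind(x = s$x[acc], y = s$y[acc]),
                 scores = s$score[acc], D = D,
                 n_candidates = nrow(scored)),
            class = "centre_map")
}

#' Locate fibrelet centres in a bright-field calibration image
#'
#' Composition of the centre-finding pipeline: optional Gaussian pre-blur
#' (used for mosaic-sensor calibration images, where the CFA pattern must be
#' smoothed out before fibrelets can be scored), candidate selection,
#' quasi-Gaussian scoring, and greedy exclusion-radius map building.  The
#' map built from one calibration frame is reused for all subsequent frames.
#'
#' @param calibration_image bright-field frame (matrix).
#' @inheritParams find_candidates
#' @param pre_blur_sigma Gaussian pre-blur in pixels; 0 for monochrome
#'   sensors, about half the super-pixel side `L` for mosaic sensors.
#' @return a [build_centre_map()] result.
#' @export
find_centres <- function(calibration_image, D, I_min, pre_blur_sigma = 0) {
  img <- if (pre_blur_sigma > 0) {
    gauss_filter(calibration_image, pre_blur_sigma)
  } else calibration_image
  cand <- find_candidates(img, D, I_min)
  if (nrow(cand) == 0) {
    warning("no candidate centres found: check I_min (expected ",
            "fibrelet/cladding contrast) and D (fibre diameter)")
    return(build_centre_map(cbind(cand, score = numeric(0)), D))
  }
  build_centre_map(score_candidates(img, cand, D), D)
}

#' @export
print.centre_map <- function(x, ...) {
  cat("Fibre centre map:", nrow(x$centres), "centres (from", x$n_candidates,
      "candidates), exclusion diameter D =", x$D, "px\n")
  invisible(x)
}

#' @export
plot.centre_map <- function(x, image = NULL, ...) {
  if (!is.null(image)) {
    image_show(image, main = "centre map")
    points(x$centres[, "x"], x$centres[, "y"], col = "red", pch = 3, cex = 0.5)
  } else {
    plot(x$centres[, "x"], x$centres[, "y"], pch = 3, cex = 0.5,
         xlab = "x [px]", ylab = "y [px]", asp = 1, ...)
  }
  invisible(x)
}

# base-graphics display of an image matrix in (x right, y down) convention;
# the y axis is reversed so overlaid points share the pixel coordinates
image_show <- function(img, ...) {
  graphics::image(x = seq_len(ncol(img)), y = seq_len(nrow(img)),
                  z = t(img),
                  col = grDevices::hcl.colors(64, "Grays", rev = TRUE),
                  asp = 1, xlab = "x [px]", ylab = "y [px]", useRaster = TRUE,
                  ylim = c(nrow(img) + 0.5, 0.5), ...)
}
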