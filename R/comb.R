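#' Specification of a synthetic fibre-bundle comb
#'
#' Describes the geometry of a simulated imaging fibre bundle: fibrelets are
#' discs sitting on a jittered hexagonal lattice, separated by opaque
#' cladding.  Scaling by the magnification `M` multiplies both the fibrelet
#' diameter and the lattice pitch, i.e. it magnifies cores and cladding alike
#' while the sensor size stays fixed.
#'
#' @param image_side sensor side length in pixels (images are square).
#' @param n_fibrelets number of fibrelets, or `NULL` to fill the sensor with
#'   every lattice site that fits.
#' @param diameter mean fibrelet diameter D in pixels (before magnification).
#' @param diameter_jitter per-fibrelet fractional radius jitter in `[0, 0.5)`.
#' @param position_jitter per-axis centre jitter as a fraction of the lattice
#'   pitch, in `[0, 0.5)`.
#' @param cladding_gap gap in pixels between the edges of adjacent fibrelets
#'   (so the centre-to-centre pitch is `diameter + cladding_gap`).
#' @param mask_blur_sigma Gaussian softening of the disc edges in pixels
#'   (0 gives binary discs); represents imperfections in the fibrelets.
#' @param magnification scale factor M applied to both diameter and pitch.
#' @param seed integer seed making the comb reproducible, or `NULL`.
#' @return an object of class `comb_spec`.
#' @export
comb_spec <- function(image_side = 512, n_fibrelets = NULL, diameter = 8,
                      diameter_jitter = 0.05, position_jitter = 0.03,
                      cladding_gap = 2, mask_blur_sigma = 0.9,
                      magnification = 1, seed = NULL) {
  if (!is.null(n_fibrelets) && n_fibrelets < 1)
    stop("n_fibrelets must be >= 1")
  if (diameter <= 0) stop("diameter must be > 0")
  if (diameter_jitter < 0 || diameter_jitter >= 0.5 ||
      position_jitter < 0 || position_jitter >= 0.5)
    stop("jitters must lie in [0, 0.5)")
  if (cladding_gap < 0) stop("cladding_gap must be >= 0")
  if (magnification <= 0) stop("magnification must be > 0")
  if ((diameter + cladding_gap) * magnification <= 0)
    stop("infeasible geometry: lattice pitch is not positive")
  structure(list(image_side = image_side, n_fibrelets = n_fibrelets,
                 diameter = diameter, diameter_jitter = diameter_jitter,
                 position_jitter = position_jitter,
                 cladding_gap = cladding_gap,
                 mask_blur_sigma = mask_blur_sigma,
                 magnification = magnification, seed = seed),
            class = "comb_spec")
}

#' Generate a synthetic comb mask
#'
#' Builds the per-pixel fractional transmission map `C(x, y)` of a fibre
#' bundle (0 = opaque cladding, ~1 = fibrelet core) together with its
#' decomposition into individual fibrelet masks and the true sub-pixel centre
#' of every fibrelet.  Fibrelets are soft-edged discs on a jittered hexagonal
#' lattice; each disc's profile is clipped at half the distance to its
#' nearest neighbour so that the supports of the masks binarised at 0.1 are
#' guaranteed pairwise disjoint.
#'
#' @param spec a [comb_spec()].
#' @return an object of class `comb_mask`: a list with elements
#'   `C` (image matrix in `[0, 1]`), `fibrelets` (list of sparse patches,
#'   each with top-left corner `x0`, `y0` and matrix `m`), `centres`
#'   (n x 2 matrix of `(x, y)` sub-pixel coordinates) and `spec`.
#' @export
generate_comb <- function(spec) {
  stopifnot(inherits(spec, "comb_spec"))
  side <- spec$image_side
  M <- spec$magnification
  pitch <- (spec$diameter + spec$cladding_gap) * M
  rad <- spec$diameter * M / 2
  blur <- spec$mask_blur_sigma

  # hexagonal lattice covering the sensor, with a margin keeping every
  # fibrelet (including its blurred skirt) fully inside the image
  margin <- rad * (1 + spec$diameter_jitter) + 3 * blur + 1
  dy <- pitch * sqrt(3) / 2
  rows <- seq(margin, side - margin + 1, by = dy)
  sites <- do.call(rbind, lapply(seq_along(rows), function(i) {
    x0 <- margin + if (i %% 2 == 0) pitch / 2 else 0
    xs <- seq(x0, side - margin + 1, by = pitch)
    cbind(x = xs, y = rows[i])
  }))
  if (is.null(sites) || nrow(sites) == 0)
    stop("infeasible geometry: no fibrelet fits inside the image")

  # deterministic ordering: distance from the image centre, ties raster-wise
  ctr <- (side + 1) / 2
  d2 <- (sites[, 1] - ctr)^2 + (sites[, 2] - ctr)^2
  ord <- order(d2, sites[, 2], sites[, 1])
  sites <- sites[ord, , drop = FALSE]

  n <- if (is.null(spec$n_fibrelets)) nrow(sites) else spec$n_fibrelets
  if (n > nrow(sites))
    stop("infeasible geometry: only ", nrow(sites),
         " fibrelets fit but ", n, " were requested")
  sites <- sites[seq_len(n), , drop = FALSE]

  with_seed(spec$seed, {
    centres <- sites +
      matrix(runif(2 * n, -1, 1), n, 2) * spec$position_jitter * pitch
    radii <- rad * (1 + runif(n, -1, 1) * spec$diameter_jitter)

    # nearest-neighbour distance per fibrelet (chunked brute force)
    nn <- rep(Inf, n)
    if (n > 1) {
      chunk <- 512L
      for (s in seq(1, n, by = chunk)) {
        idx <- s:min(s + chunk - 1, n)
        dmat <- outer(centres[idx, 1], centres[, 1], "-")^2 +
                outer(centres[idx, 2], centres[, 2], "-")^2
        dmat[cbind(seq_along(idx), idx)] <- Inf
        nn[idx] <- sqrt(apply(dmat, 1, min))
      }
    }

    fibrelets <- vector("list", n)
    C <- matrix(0, side, side)
    for (i in seq_len(n)) {
      cx <- centres[i, 1]; cy <- centres[i, 2]
      rmax <- min(radii[i] + 3.5 * blur + 0.5, nn[i] / 2 - 0.05)
      xs <- max(1L, floor(cx - rmax)):min(side, ceiling(cx + rmax))
      ys <- max(1L, floor(cy - rmax)):min(side, ceiling(cy + rmax))
      dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
      m <- if (blur > 0) {
        stats::pnorm((radii[i] - dist) / blur)
      } else {
        (dist < radii[i]) * 1
      }
      m[dist > rmax] <- 0
      m[m < 1e-8] <- 0
      fibrelets[[i]] <- list(x0 = xs[1], y0 = ys[1], m = m)
      C[ys, xs] <- C[ys, xs] + m
    }
    structure(list(C = C, fibrelets = fibrelets, centres = centres,
                   spec = spec),
              class = "comb_mask")
  })
}

#' Reassemble the full transmission map from the individual fibrelet masks
#'
#' @param comb a [generate_comb()] result.
#' @return image matrix equal (to floating tolerance) to `comb$C`.
#' @export
comb_sum_masks <- function(comb) {
  stopifnot(inherits(comb, "comb_mask"))
  side <- comb$spec$image_side
  C <- matrix(0, side, side)
  for (f in comb$fibrelets) {
    ys <- f$y0 + seq_len(nrow(f$m)) - 1
    xs <- f$x0 + seq_len(ncol(f$m)) - 1
    C[ys, xs] <- C[ys, xs] + f$m
  }
  C
}

#' @export
print.comb_mask <- function(x, ...) {
  cat("Synthetic comb mask:", nrow(x$centres), "fibrelets on a",
      x$spec$image_side, "x", x$spec$image_side, "sensor\n")
  cat("  fibrelet diameter:", x$spec$diameter * x$spec$magnification,
      "px, pitch:",
      (x$spec$diameter + x$spec$cladding_gap) * x$spec$magnification,
      "px, fill factor:", round(mean(x$C), 3), "\n")
  invisible(x)
}
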