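#' Delaunay triangulation of scattered points
#'
#' Incremental Bowyer-Watson triangulation.  Input coordinates receive a
#' deterministic symbolic perturbation of order 1e-7 px to break exact
#' collinearity/cocircularity ties (fibre centres rounded to a pixel grid
#' are full of them); the perturbation is far below any imaging tolerance.
#'
#' @param pts n x 2 matrix of `(x, y)` coordinates, n >= 3.
#' @return integer matrix with one triangle per row (vertex indices into
#'   `pts`, counter-clockwise not guaranteed).
#' @export
delaunay_triangulate <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to triangulate")
  # deterministic tie-breaking jitter (Weyl sequence on the point index)
  jit <- cbind(((seq_len(n) * 0.7548776662) %% 1) - 0.5,
               ((seq_len(n) * 0.5698402910) %% 1) - 0.5) * 1e-7
  P <- pts + jit
  rng <- max(diff(range(P[, 1])), diff(range(P[, 2])), 1)
  cx <- mean(range(P[, 1])); cy <- mean(range(P[, 2]))
  super <- rbind(c(cx - 30 * rng, cy - 10 * rng),
                 c(cx + 30 * rng, cy - 10 * rng),
                 c(cx, cy + 30 * rng))
  P <- rbind(super, P)

  cap <- 8L * n + 64L
  V <- matrix(0L, cap, 3)
  CC <- matrix(0, cap, 2)
  R2 <- rep(-1, cap)          # dead slots keep R2 < 0 (never "bad")
  nt <- 0L

  circum <- function(a, b, c) {
    ax <- P[a, 1]; ay <- P[a, 2]; bx <- P[b, 1]; by <- P[b, 2]
    ccx <- P[c, 1]; ccy <- P[c, 2]
    d <- 2 * (ax * (by - ccy) + bx * (ccy - ay) + ccx * (ay - by))
    if (abs(d) < 1e-300) return(c(NA, NA, -1))
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- ccx^2 + ccy^2
    ux <- (a2 * (by - ccy) + b2 * (ccy - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (ccx - bx) + b2 * (ax - ccx) + c2 * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }

  add_tri <- function(a, b, c) {
    cc <- circum(a, b, c)
    if (cc[3] < 0) return(invisible(NULL))  # degenerate sliver: drop
    nt <<- nt + 1L
    if (nt > nrow(V)) {       # grow storage
      V <<- rbind(V, matrix(0L, cap, 3))
      CC <<- rbind(CC, matrix(0, cap, 2))
      R2 <<- c(R2, rep(-1, cap))
    }
    V[nt, ] <<- c(a, b, c)
    CC[nt, ] <<- cc[1:2]
    R2[nt] <<- cc[3]
    invisible(NULL)
  }

  add_tri(1L, 2L, 3L)
  for (i in 4:(n + 3)) {
    px <- P[i, 1]; py <- P[i, 2]
    live <- seq_len(nt)
    bad <- live[(px - CC[live, 1])^2 + (py - CC[live, 2])^2 <= R2[live]]
    if (length(bad) == 0) {
      # numerical fall-through: force the nearest triangle (should not occur
      # for points inside the super-triangle, kept as a safety net)
      d2 <- (px - CC[live, 1])^2 + (py - CC[live, 2])^2 - R2[live]
      d2[R2[live] < 0] <- Inf
      bad <- live[which.min(d2)]
    }
    e <- rbind(V[bad, c(1, 2), drop = FALSE], V[bad, c(2, 3), drop = FALSE],
               V[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- !(key %in% key[duplicated(key)])
    R2[bad] <- -1             # retire the bad triangles
    eb <- e[once, , drop = FALSE]
    for (j in seq_len(nrow(eb))) add_tri(eb[j, 1], eb[j, 2], i)
  }
  keep <- which(R2[seq_len(nt)] >= 0 & apply(V[seq_len(nt), , drop = FALSE] > 3, 1, all))
  tri <- V[keep, , drop = FALSE] - 3L
  if (nrow(tri) == 0)
    stop("cannot triangulate: points are collinear")
  tri
}

#' Scattered bilinear interpolation table
#'
#' Precomputes, for every pixel of the target grid, the enclosing Delaunay
#' triangle of the centre set and its barycentric weights -- the "single
#' look-up table" that makes multispectral interpolation cheap, since every
#' band interpolates between the same centre points.  Pixels outside the
#' convex hull of the centres are filled with the nearest centre's value and
#' flagged invalid.
#'
#' @param centres m x 2 matrix of `(x, y)` interpolation nodes.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return object of class `interp_lut`: list with `dim`, `idx` (npix x 3
#'   node indices), `w` (npix x 3 weights), `inside` (logical vector, hull
#'   membership) and `centres`.
#' @export
interp_lut <- function(centres, dim) {
  centres <- as.matrix(centres)
  if (nrow(centres) < 3) stop("need at least 3 non-collinear centres")
  tri <- delaunay_triangulate(centres)
  nr <- dim[1]; nc <- dim[2]
  npix <- nr * nc
  idx <- matrix(1L, npix, 3)
  w <- matrix(0, npix, 3)
  w[, 1] <- 1
  inside <- rep(FALSE, npix)
  tol <- 1e-9
  for (t in seq_len(nrow(tri))) {
    a <- tri[t, 1]; b <- tri[t, 2]; c <- tri[t, 3]
    x1 <- centres[a, 1]; y1 <- centres[a, 2]
    x2 <- centres[b, 1]; y2 <- centres[b, 2]
    x3 <- centres[c, 1]; y3 <- centres[c, 2]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-12) next
    xs <- max(1L, ceiling(min(x1, x2, x3) - tol)):
          min(nc, floor(max(x1, x2, x3) + tol))
    ys <- max(1L, ceiling(min(y1, y2, y3) - tol)):
          min(nr, floor(max(y1, y2, y3) + tol))
    if (length(xs) == 0 || length(ys) == 0) next
    X <- rep(xs, each = length(ys))
    Y <- rep(ys, times = length(xs))
    w1 <- ((y2 - y3) * (X - x3) + (x3 - x2) * (Y - y3)) / det
    w2 <- ((y3 - y1) * (X - x3) + (x1 - x3) * (Y - y3)) / det
    w3 <- 1 - w1 - w2
    ok <- w1 >= -tol & w2 >= -tol & w3 >= -tol
    if (!any(ok)) next
    lin <- (X[ok] - 1L) * nr + Y[ok]
    idx[lin, ] <- rep(c(a, b, c), each = length(lin))
    w[lin, ] <- cbind(w1[ok], w2[ok], w3[ok])
    inside[lin] <- TRUE
  }
  out <- which(!inside)
  if (length(out) > 0) {
    ox <- ((out - 1L) %/% nr) + 1L
    oy <- ((out - 1L) %% nr) + 1L
    chunk <- 4096L
    for (s in seq(1, length(out), by = chunk)) {
      ii <- s:min(s + chunk - 1, length(out))
      d2 <- outer(ox[ii], centres[, 1], "-")^2 +
            outer(oy[ii], centres[, 2], "-")^2
      idx[out[ii], 1] <- max.col(-d2, ties.method = "first")
    }
    w[out, ] <- rep(c(1, 0, 0), each = length(out))
  }
  structure(list(dim = dim, idx = idx, w = w, inside = inside,
                 centres = centres),
            class = "interp_lut")
}

#' Apply an interpolation table to node values
#'
#' @param lut an [interp_lut()].
#' @param values numeric vector, one value per centre.
#' @return interpolated image matrix with a logical attribute `"validity"`
#'   marking pixels inside the convex hull of the centres.
#' @export
interp_apply <- function(lut, values) {
  stopifnot(inherits(lut, "interp_lut"),
            length(values) == nrow(lut$centres))
  v <- values[lut$idx[, 1]] * lut$w[, 1] +
       values[lut$idx[, 2]] * lut$w[, 2] +
       values[lut$idx[, 3]] * lut$w[, 3]
  out <- matrix(v, lut$dim[1], lut$dim[2])
  attr(out, "validity") <- matrix(lut$inside, lut$dim[1], lut$dim[2])
  out
}

#' Interpolation decombing
#'
#' Samples the image at the fibre centres (a single nearest-pixel read per
#' fibrelet by default) and reconstructs a comb-free image by piecewise
#' linear (bilinear) interpolation over the scattered centres.  Outside the
#' convex hull the nearest centre's value is used and the validity mask
#' attribute flags those pixels.
#'
#' @param image image matrix.
#' @param centre_map a [find_centres()] result (>= 3 non-collinear centres).
#' @param lut optional precomputed [interp_lut()] for this centre map and
#'   image size; when supplied, `centre_map` may be `NULL`.
#' @param sample `"pixel"` (single pixel per fibrelet, the default) or
#'   `"disc"` (mean over a small disc of radius `disc_radius`).
#' @param disc_radius radius of the optional disc mean, in pixels.
#' @return decombed image matrix with a `"validity"` attribute.
#' @export
interpolation_decomb <- function(image, centre_map = NULL, lut = NULL,
                                 sample = c("pixel", "disc"),
                                 disc_radius = 1.5) {
  stop_if_not_image(image)
  sample <- match.arg(sample)
  if (is.null(lut)) {
    if (is.null(centre_map)) stop("supply a centre_map or a lut")
    ctr <- if (inherits(centre_map, "centre_map")) centre_map$centres
           else as.matrix(centre_map)
    if (nrow(ctr) < 3) stop("need at least 3 centres to triangulate")
    lut <- interp_lut(ctr, dim(image))
  }
  vals <- sample_centre_values(image, lut$centres, sample, disc_radius)
  interp_apply(lut, vals)
}

# nearest-pixel (or small-disc mean) image read at each centre
sample_centre_values <- function(image, centres, sample = "pixel",
                                 disc_radius = 1.5) {
  xi <- pmin(pmax(round(centres[, 1]), 1), ncol(image))
  yi <- pmin(pmax(round(centres[, 2]), 1), nrow(image))
  if (sample == "pixel") return(image[cbind(yi, xi)])
  rr <- ceiling(disc_radius)
  offs <- expand.grid(dy = -rr:rr, dx = -rr:rr)
  offs <- offs[offs$dx^2 + offs$dy^2 <= disc_radius^2, ]
  acc <- cnt <- numeric(length(xi))
  for (t in seq_len(nrow(offs))) {
    y <- yi + offs$dy[t]; x <- xi + offs$dx[t]
    ok <- y >= 1 & y <= nrow(image) & x >= 1 & x <= ncol(image)
    acc[ok] <- acc[ok] + image[cbind(y[ok], x[ok])]
    cnt[ok] <- cnt[ok] + 1
  }
  acc / cnt
}
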