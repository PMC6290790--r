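# Shared fixtures, memoised across test files (one R session per run).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# a ~200-fibrelet comb that fills its sensor, as a bright-field frame does
recovery_comb <- function() {
  memo("recovery_comb",
       generate_comb(comb_spec(image_side = 146, n_fibrelets = 200,
                               seed = 42)))
}

# small full-fill comb for interpolation/demosaicking tests
small_comb <- function() {
  memo("small_comb", generate_comb(comb_spec(image_side = 128, seed = 7)))
}

# the full monochrome benchmark at the reference conditions (512 px)
mono_bench <- function() {
  memo("mono_bench",
       run_benchmark(benchmark_config(mode = "monochrome", seed = 1),
                     verbose = FALSE))
}

# the full multispectral benchmark at the reference conditions (512 px)
ms_bench <- function() {
  memo("ms_bench",
       run_benchmark(benchmark_config(mode = "multispectral", seed = 1),
                     verbose = FALSE))
}

# brute-force O(n^2) greedy exclusion reference (ascending score, raster
# tie-break), returning indices into the input order
greedy_reference <- function(x, y, score, D) {
  ord <- order(score, y, x)
  acc <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in acc) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= D^2) { ok <- FALSE; break }
    }
    if (ok) acc <- c(acc, i)
  }
  acc
}

# exhaustive nearest band-k neighbour over the whole image (ties averaged)
nn_band_reference <- function(raw, P, cx, cy, k) {
  idx <- which(P == k, arr.ind = TRUE)
  d2 <- (idx[, 2] - cx)^2 + (idx[, 1] - cy)^2
  sel <- idx[d2 == min(d2), , drop = FALSE]
  mean(raw[sel])
}

# fraction of planted centres matched by an accepted centre within tol px
recovery_rate <- function(centre_map, true_centres, tol) {
  d <- sqrt(outer(centre_map$centres[, 1], true_centres[, 1], "-")^2 +
            outer(centre_map$centres[, 2], true_centres[, 2], "-")^2)
  mean(apply(d, 2, min) <= tol)
}

min_pair_dist <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  min(d)
}
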