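#' Overall performance score
#'
#' Weighted sum of the normalised metric scores,
#' `OP = w_res S_res + w_smooth S_smooth + w_signal S_signal + w_ASR S_ASR`,
#' with application-dependent weights on the simplex
#' `w_res + w_smooth + w_signal + w_ASR = 1` (monochrome imaging sets
#' `w_ASR = 0`).  Speed is excluded by construction.
#'
#' @param scores named list or one-row data frame with `S_res`, `S_smooth`,
#'   `S_signal` and (for multispectral) `S_ASR`.
#' @param w weight vector `c(w_res, w_smooth, w_signal, w_ASR)` (the last
#'   element may be omitted for monochrome).
#' @return the scalar OP.
#' @export
overall_performance <- function(scores, w) {
  if (length(w) == 3) w <- c(w, 0)
  if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
    stop("weights must be non-negative and sum to 1")
  s <- c(scores$S_res, scores$S_smooth, scores$S_signal,
         if (!is.null(scores$S_ASR)) scores$S_ASR else 0)
  sum(w * s)
}

# enumerate the weight simplex at the given step; `active` names the weights
# allowed to be non-zero (the rest are fixed at 0)
weight_grid <- function(step, n_active) {
  m <- round(1 / step)
  if (n_active == 3) {
    g <- expand.grid(i = 0:m, j = 0:m)
    g <- g[g$i + g$j <= m, ]
    cbind(g$i, g$j, m - g$i - g$j) / m
  } else {
    g <- expand.grid(i = 0:m, j = 0:m, k = 0:m)
    g <- g[g$i + g$j + g$k <= m, ]
    cbind(g$i, g$j, g$k, m - g$i - g$j - g$k) / m
  }
}

#' Sweep the weight simplex and map the winning method
#'
#' Evaluates OP for every correction method of a score table at every
#' weighting on a regular simplex grid, recording the winner (maximal OP) at
#' each grid point so that the optimum method for any application priority
#' can be read off.  Ties are broken by the fixed method order
#' interpolation, fourier, gaussian, median, physical, then by smaller `r`.
#'
#' @param scores a [normalise_scores()] result (columns `method`, `r`, score
#'   columns).
#' @param step simplex grid step; defaults to 0.01 when only resolution,
#'   smoothness and signal are active (monochrome) and 0.05 when the ASR
#'   weight is active too.
#' @return data frame of class `performance_map`: weights, winning `method`,
#'   winning `r` and the winning `OP` at each grid point.
#' @export
sweep_weights <- function(scores, step = NULL) {
  if (nrow(scores) == 0) stop("empty score table")
  has_asr <- "S_ASR" %in% names(scores)
  n_active <- if (has_asr) 4 else 3
  if (is.null(step)) step <- if (has_asr) 0.05 else 0.01
  W <- weight_grid(step, n_active)
  S <- cbind(scores$S_res, scores$S_smooth, scores$S_signal,
             if (has_asr) scores$S_ASR)
  # tie-break priority: method order, then ascending r (NA r, i.e.
  # interpolation's undefined filter size, sorts first as 0)
  meth_rank <- match(scores$method, c("interpolation", "fourier", "gaussian",
                                      "median", "physical"))
  r_rank <- ifelse(is.na(scores$r), 0, scores$r)
  prio <- order(meth_rank, r_rank)
  OP <- S[prio, , drop = FALSE] %*% t(W)    # methods x weights
  win <- max.col(t(OP), ties.method = "first")
  out <- data.frame(w_res = W[, 1], w_smooth = W[, 2], w_signal = W[, 3],
                    w_ASR = if (has_asr) W[, 4] else 0,
                    method = scores$method[prio][win],
                    r = scores$r[prio][win],
                    OP = OP[cbind(win, seq_len(ncol(OP)))])
  attr(out, "step") <- step
  class(out) <- c("performance_map", class(out))
  out
}

#' Benchmark configuration
#'
#' Bundles every knob of the end-to-end benchmark.  Defaults reproduce the
#' benchmark's reference conditions at desk scale: a 512 px square sensor filled
#' with ~2500 fibrelets of diameter 8 px at pitch 10 px, 1% dynamic-range
#' noise, filter sizes spanning the valid range `1 < r < 50`, and (for
#' multispectral mode) the 3x3 nine-band mosaic with broadband calibration
#' illumination and a narrow-band LED scene for the spectral-accuracy
#' metric.
#'
#' @param mode `"monochrome"` or `"multispectral"`.
#' @param image_side sensor side in pixels.
#' @param magnification comb scale factor M.
#' @param fibre_diameter,cladding_gap comb geometry in pixels.
#' @param noise_sigma additive Gaussian noise sd, in intensity units of the
#'   0-255 range (default 1% of dynamic range).
#' @param r_grid characteristic filter sizes to test.
#' @param methods correction methods to compare.
#' @param spacings bar-target line spacings in pixels.
#' @param cf_D,cf_I_min centre-finder neighbourhood size (odd) and minimal
#'   fibrelet/cladding intensity difference; `cf_I_min = NULL` picks the
#'   mode default (50 for monochrome, 12 for the dimmer mosaic bright-field,
#'   whose narrow-band pixels carry only a fraction of the broad band's
#'   intensity).
#' @param cladding_stray multispectral only: stray-light luminance in the
#'   cladding as a fraction of the mean scene intensity (see
#'   [ms_scene_bands()]).
#' @param weight_step simplex grid step (`NULL` for the mode default).
#' @param seed master seed; every random stage derives from it.
#' @return list of class `decomb_config`.
#' @export
benchmark_config <- function(mode = c("monochrome", "multispectral"),
                             image_side = 512, magnification = 1,
                             fibre_diameter = 8, cladding_gap = 2,
                             noise_sigma = 2.55,
                             r_grid = NULL, methods = NULL,
                             spacings = c(20, 24, 29, 35, 42, 50, 60, 72, 80),
                             cf_D = 7, cf_I_min = NULL, cladding_stray = 0.1,
                             weight_step = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(r_grid))
    r_grid <- if (mode == "monochrome") c(2, 3, 5, 8, 12, 18, 25, 35, 48)
              else c(2, 5, 10, 25)
  if (is.null(cf_I_min)) cf_I_min <- if (mode == "monochrome") 50 else 12
  if (is.null(methods))
    methods <- if (mode == "monochrome") {
      c("interpolation", "fourier", "gaussian", "median")
    } else {
      c("interpolation", "fourier", "gaussian", "median", "physical")
    }
  structure(list(mode = mode, image_side = image_side,
                 magnification = magnification,
                 fibre_diameter = fibre_diameter,
                 cladding_gap = cladding_gap, noise_sigma = noise_sigma,
                 r_grid = r_grid, methods = methods, spacings = spacings,
                 cf_D = cf_D, cf_I_min = cf_I_min,
                 cladding_stray = cladding_stray,
                 weight_step = weight_step, seed = seed),
            class = "decomb_config")
}

#' Run the end-to-end correction benchmark
#'
#' Generates the synthetic fixtures (comb, bar target, uniform field, bright
#' region, and for multispectral mode their CFA mosaics), builds the fibre
#' centre map once from a bright-field calibration frame, applies every
#' correction method at every configured filter size, computes the
#' performance metrics, min-max normalises them across the whole comparison
#' set, and sweeps the application weight simplex for the winner map.
#'
#' @param config a [benchmark_config()].
#' @param verbose emit per-stage progress messages.
#' @return object of class `decomb_benchmark`: list with the score table
#'   (`scores`, raw metrics + normalised scores + per-frame time `t`), the
#'   winner map (`map`), normalisation `extrema`, the `centre_map`, the
#'   `config` and per-stage timings.
#' @export
run_benchmark <- function(config = benchmark_config(), verbose = TRUE) {
  stopifnot(inherits(config, "decomb_config"))
  t0 <- proc.time()["elapsed"]
  say <- function(...) if (verbose) message(sprintf("[%7.1fs] ",
    proc.time()["elapsed"] - t0), ...)
  res <- if (config$mode == "monochrome") {
    benchmark_mono(config, say)
  } else {
    benchmark_ms(config, say)
  }
  say("normalising scores and sweeping the weight simplex")
  scores <- normalise_scores(res$raw)
  map <- sweep_weights(scores, step = config$weight_step)
  say("done")
  structure(list(mode = config$mode, scores = scores, map = map,
                 extrema = attr(scores, "extrema"),
                 centre_map = res$centre_map, config = config,
                 elapsed = proc.time()["elapsed"] - t0),
            class = "decomb_benchmark")
}

# --- internal drivers -------------------------------------------------------

bench_fixtures <- function(config) {
  side <- config$image_side
  spec <- comb_spec(image_side = side, n_fibrelets = NULL,
                    diameter = config$fibre_diameter,
                    cladding_gap = config$cladding_gap,
                    magnification = config$magnification,
                    seed = config$seed + 1L)
  comb <- generate_comb(spec)
  ns <- config$noise_sigma
  list(comb = comb,
       bar = make_target("bar_target", side = side,
                         spacings = config$spacings,
                         noise_sigma = ns, seed = config$seed + 11L),
       uniform = make_target("uniform", side = side, noise_sigma = ns,
                             seed = config$seed + 12L),
       bright = make_target("bright_region", side = side, noise_sigma = ns,
                            seed = config$seed + 13L),
       flat_region = NULL,
       roi = c(round(side / 2) - 31, round(side / 2) - 31, 64, 64))
}

# metric evaluation shared by both modes; `imgs` is a named list with the
# corrected bar/uniform/bright frames (matrices or spectral cubes)
bench_metrics <- function(imgs, config, bar_geom, cal = NULL) {
  els <- bar_geom$elements
  res_of <- function(img) {
    ct <- vapply(els, function(e) michelson_contrast(img, e), numeric(1))
    resolution(vapply(els, function(e) e$spacing, numeric(1)), ct)
  }
  R <- if (inherits(imgs$bar, "spectral_cube")) {
    mean(vapply(imgs$bar$bands, res_of, numeric(1)))
  } else res_of(imgs$bar)
  out <- list(R = R,
              sigma = smoothness(imgs$uniform, region = config$flat_region),
              S = signal_roi(imgs$bright, roi = config$roi))
  if (!is.null(cal)) out$Q <- asr(imgs$asr, cal)
  out
}

benchmark_mono <- function(config, say) {
  say("generating comb and test targets (", config$image_side, "px square)")
  fx <- bench_fixtures(config)
  config$flat_region <- fx$flat_region; config$roi <- fx$roi
  ns <- config$noise_sigma
  say("imaging targets through the comb (", nrow(fx$comb$centres),
      " fibrelets)")
  combed <- list(
    bar = apply_comb(fx$bar, fx$comb, ns, config$seed + 21L),
    uniform = apply_comb(fx$uniform, fx$comb, ns, config$seed + 22L),
    bright = apply_comb(fx$bright, fx$comb, ns, config$seed + 23L))
  calib <- apply_comb(make_target("uniform", side = config$image_side),
                      fx$comb, ns, config$seed + 24L)
  say("finding fibre centres in the calibration frame")
  cmap <- find_centres(calib, D = config$cf_D, I_min = config$cf_I_min)
  say("  ", nrow(cmap$centres), " centres accepted")
  lut <- interp_lut(cmap$centres, dim(calib))

  rows <- list()
  for (method in config$methods) {
    rs <- if (method == "interpolation") NA_real_ else config$r_grid
    for (r in rs) {
      tic <- proc.time()["elapsed"]
      imgs <- if (method == "physical") {
        lapply(combed, function(img)
          simulate_defocus(img, displacement_um = r * 0.5,
                           blur_per_um = 1)$image)
      } else {
        lapply(combed, decomb, method = method, r = r, lut = lut)
      }
      t_frame <- (proc.time()["elapsed"] - tic) / length(combed)
      m <- bench_metrics(imgs, config, fx$bar$geometry)
      rows[[length(rows) + 1]] <- data.frame(method = method, r = r,
                                             R = m$R, sigma = m$sigma,
                                             S = m$S, t = t_frame)
    }
    say("  ", method, " done")
  }
  list(raw = do.call(rbind, rows), centre_map = cmap)
}

benchmark_ms <- function(config, say) {
  say("generating comb, targets and CFA mosaics (",
      config$image_side, "px square)")
  fx <- bench_fixtures(config)
  config$flat_region <- fx$flat_region; config$roi <- fx$roi
  side <- config$image_side
  ns <- config$noise_sigma
  pattern <- cfa_pattern(3)
  # broadband (flat) illumination for the spatial fixtures and calibration;
  # narrow-band LED illumination for the spectral-accuracy fixture
  cal_led <- default_calibration()
  cal_flat <- spectral_calibration(cal_led$lambda,
                                   rep(1, length(cal_led$lambda)),
                                   cal_led$responses, cal_led$band_meta)
  s_flat <- cal_flat$E / max(cal_flat$E)
  s_led <- cal_led$E / max(cal_led$E)

  say("imaging targets through the comb (", nrow(fx$comb$centres),
      " fibrelets)")
  bands_of <- list(
    bar = ms_scene_bands(fx$bar, fx$comb, s_flat, config$cladding_stray),
    uniform = ms_scene_bands(fx$uniform, fx$comb, s_flat,
                             config$cladding_stray),
    asr = ms_scene_bands(fx$uniform, fx$comb, s_led, config$cladding_stray),
    bright = ms_scene_bands(fx$bright, fx$comb, s_flat,
                            config$cladding_stray))
  raws <- list(bar = apply_cfa(bands_of$bar, pattern, ns, config$seed + 31L),
               uniform = apply_cfa(bands_of$uniform, pattern, ns,
                                   config$seed + 32L),
               asr = apply_cfa(bands_of$asr, pattern, ns, config$seed + 33L),
               bright = apply_cfa(bands_of$bright, pattern, ns,
                                  config$seed + 34L))
  calib <- apply_cfa(ms_scene_bands(make_target("uniform", side = side),
                                    fx$comb, s_flat, config$cladding_stray),
                     pattern, ns, config$seed + 36L)
  say("finding fibre centres (pre-blur sigma = L/2)")
  cmap <- find_centres(calib, D = config$cf_D, I_min = config$cf_I_min,
                       pre_blur_sigma = pattern$L / 2)
  say("  ", nrow(cmap$centres), " centres accepted")
  lut <- interp_lut(cmap$centres, dim(calib))

  correct_ms <- function(method, r) {
    if (method == "interpolation") {
      lapply(raws, function(raw)
        interpolate_centre_spectra(
          centre_based_demosaick(raw, pattern, cmap), dim(raw), lut = lut))
    } else if (method == "physical") {
      # defocus happens before the CFA: blur every band image (true scene
      # and stray cladding light alike), re-mosaic, then demosaick with no
      # further filtering
      braws <- lapply(seq_along(bands_of), function(i)
        apply_cfa(lapply(bands_of[[i]], function(b)
                    simulate_defocus(b, r * 0.5, 1)$image),
                  pattern, ns, config$seed + 40L + i))
      names(braws) <- names(bands_of)
      lapply(braws, demosaick_then_filter, pattern = pattern,
             method = "physical")
    } else {
      lapply(raws, demosaick_then_filter, pattern = pattern,
             method = method, r = r)
    }
  }

  rows <- list()
  for (method in config$methods) {
    rs <- if (method == "interpolation") NA_real_ else config$r_grid
    for (r in rs) {
      tic <- proc.time()["elapsed"]
      cubes <- correct_ms(method, r)
      t_frame <- (proc.time()["elapsed"] - tic) / length(cubes)
      m <- bench_metrics(cubes, config, fx$bar$geometry, cal = cal_led)
      rows[[length(rows) + 1]] <- data.frame(method = method, r = r,
                                             R = m$R, sigma = m$sigma,
                                             S = m$S, Q = m$Q, t = t_frame)
    }
    say("  ", method, " done")
  }
  list(raw = do.call(rbind, rows), centre_map = cmap)
}

# --- S3 methods -------------------------------------------------------------

#' @export
print.decomb_benchmark <- function(x, ...) {
  cat("Decombing benchmark (", x$mode, " mode, ",
      x$config$image_side, "px square, ",
      nrow(x$centre_map$centres), " fibre centres)\n", sep = "")
  cat("Methods x filter sizes evaluated:", nrow(x$scores), "\n")
  best <- x$scores[which.max(rowMeans(
    x$scores[, grep("^S_", names(x$scores)), drop = FALSE])), ]
  cat("Best mean score:", as.character(best$method),
      if (!is.na(best$r)) paste0("(r = ", best$r, ")") else "", "\n")
  tab <- table(x$map$method)
  cat("Share of the weight simplex won:\n")
  for (m in names(sort(tab, decreasing = TRUE)))
    cat(sprintf("  %-14s %5.1f%%\n", m, 100 * tab[[m]] / nrow(x$map)))
  invisible(x)
}

#' @export
summary.decomb_benchmark <- function(object, ...) {
  cat("Raw metrics and normalised scores:\n")
  print(object$scores, digits = 3, row.names = FALSE)
  cat("\nNormalisation extrema (min/max across the comparison set):\n")
  str(object$extrema, give.head = FALSE)
  invisible(object$scores)
}

#' Plot a benchmark: score curves or the winner map
#'
#' `type = "scores"` draws each normalised score against the characteristic
#' filter size per method (interpolation, which has no defined filter size,
#' appears as a horizontal line).  `type = "map"` draws the winner over the
#' weight simplex as a ternary plot of the three active weights (any fourth
#' weight fixed at zero).
#'
#' @param x a [run_benchmark()] result.
#' @param type `"scores"` or `"map"`.
#' @param score which score to draw for `type = "scores"`.
#' @param ... unused.
#' @export
plot.decomb_benchmark <- function(x, type = c("scores", "map"),
                                  score = "S_res", ...) {
  type <- match.arg(type)
  if (type == "scores") {
    sc <- x$scores
    methods <- unique(sc$method)
    cols <- grDevices::hcl.colors(max(3, length(methods)), "Dark 3")
    plot(NULL, xlim = range(sc$r, na.rm = TRUE), ylim = c(0, 1),
         xlab = "characteristic filter size r [px]", ylab = score,
         main = paste(x$mode, "benchmark"))
    for (i in seq_along(methods)) {
      rows <- sc[sc$method == methods[i], ]
      if (all(is.na(rows$r))) {
        graphics::abline(h = rows[[score]], col = cols[i], lty = 2, lwd = 2)
      } else {
        lines(rows$r, rows[[score]], col = cols[i], lwd = 2, type = "b",
              pch = 16)
      }
    }
    legend("topright", legend = methods, col = cols[seq_along(methods)],
           lwd = 2, bty = "n")
  } else {
    plot_ternary_map(x$map, ...)
  }
  invisible(x)
}

# ternary winner map over (w_res, w_smooth, w_signal) with w_ASR = 0
plot_ternary_map <- function(map, ...) {
  sub <- map[map$w_ASR == 0, ]
  tx <- sub$w_smooth + sub$w_signal / 2
  ty <- sub$w_signal * sqrt(3) / 2
  methods <- sort(unique(as.character(sub$method)))
  cols <- grDevices::hcl.colors(max(3, length(methods)), "Dark 3")
  plot(NULL, xlim = c(-0.05, 1.05), ylim = c(-0.1, 1), asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = "optimum method over the weight simplex")
  points(tx, ty, col = cols[match(sub$method, methods)], pch = 15, cex = 0.6)
  polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  text(c(0, 1, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.05),
       c("w_res = 1", "w_smooth = 1", "w_signal = 1"))
  legend("topright", legend = methods, col = cols[seq_along(methods)],
         pch = 15, bty = "n")
  invisible(map)
}

#' Write benchmark outputs to a directory
#'
#' Writes the score table and winner map as CSV, a JSON run manifest
#' (configuration, extrema, centre count, timings), and a PNG winner map.
#'
#' @param bench a [run_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bench$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(bench$map, file.path(dir, "winner_map.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(mode = bench$mode,
                            config = unclass(bench$config),
                            extrema = bench$extrema,
                            n_centres = nrow(bench$centre_map$centres),
                            elapsed_s = unname(bench$elapsed)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  grDevices::png(file.path(dir, "winner_map.png"), width = 800, height = 700)
  plot_ternary_map(bench$map)
  grDevices::dev.off()
  invisible(dir)
}
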