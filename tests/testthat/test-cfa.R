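test_that("the sampling-ratio criterion is T = L/D, strictly below one", {
  expect_equal(as.numeric(check_sampling_ratio(cfa_pattern(3), 5)), 0.6)
  expect_true(attr(check_sampling_ratio(cfa_pattern(3), 5), "valid"))
  expect_warning(Tr <- check_sampling_ratio(cfa_pattern(3), 3), ">= 1")
  expect_false(attr(Tr, "valid"))
  expect_equal(as.numeric(suppressWarnings(
    check_sampling_ratio(cfa_pattern(2), 10))), 0.2)
})

test_that("splitting a mosaic yields disjoint sparse bands that round-trip", {
  pat <- cfa_pattern(3)
  # constant raw: every defined pixel of every band equals the constant
  sp <- split_mosaic(matrix(4, 18, 18), pat)
  expect_true(all(vapply(sp, function(b) all(b[!is.na(b)] == 4), logical(1))))
  # each band holds exactly 1/9 of the pixels; reassembly is exact
  set.seed(41)
  raw <- matrix(runif(18 * 18), 18, 18)
  sp <- split_mosaic(raw, pat)
  counts <- vapply(sp, function(b) sum(!is.na(b)), numeric(1))
  expect_equal(counts, rep(18 * 18 / 9, 9))
  rec <- matrix(NA_real_, 18, 18)
  for (b in sp) rec[!is.na(b)] <- b[!is.na(b)]
  expect_equal(rec, raw)
})

test_that("simple demosaicking interpolates each band's regular lattice", {
  pat <- cfa_pattern(3)
  cube <- simple_demosaick(matrix(4, 27, 27), pat)
  for (b in cube$bands) expect_equal(b, matrix(4, 27, 27))
  # a planar scene sampled by the CFA is recovered exactly on the interior
  plane <- outer(seq_len(27), seq_len(27), function(y, x) 2 * x + y + 5)
  cube2 <- simple_demosaick(plane, pat)
  i <- 4:24
  for (b in cube2$bands) expect_equal(b[i, i], plane[i, i], tolerance = 1e-12)
})

test_that("demosaicked band means recover the generator's scene spectrum", {
  cb <- small_comb()
  s <- c(0.9, 0.5, 0.2, 1, 0.7, 0.3, 0.8, 0.6, 0.4)
  pat <- cfa_pattern(3)
  raw <- apply_cfa(ms_scene_bands(matrix(100, 128, 128), cb, s,
                                  cladding_stray = 0), pat,
                   noise_sigma = 1, seed = 6)
  cube <- simple_demosaick(raw, pat)
  got <- vapply(cube$bands, mean, numeric(1))
  # band means are the scene spectrum scaled by the comb's mean transmission
  expect_equal(got / sum(got), s / sum(s), tolerance = 0.02)
})

test_that("filtering before demosaicking corrupts the recorded spectra", {
  cb <- small_comb()
  cal <- default_calibration()
  s <- cal$E / max(cal$E)
  pat <- cfa_pattern(3)
  raw <- apply_cfa(ms_scene_bands(matrix(150, 128, 128), cb, s), pat,
                   noise_sigma = 2.55, seed = 16)
  right <- demosaick_then_filter(raw, pat, "gaussian", r = 3)
  wrong <- simple_demosaick(gaussian_decomb(raw, 3), pat)
  expect_gt(asr(wrong, cal), asr(right, cal) * 5)
  # physical: no further filtering after demosaicking
  expect_equal(demosaick_then_filter(raw, pat, "physical"),
               simple_demosaick(raw, pat))
  # constant raw stays constant through every path
  const <- demosaick_then_filter(matrix(8, 36, 36), pat, "gaussian", r = 2)
  for (b in const$bands) expect_equal(b, matrix(8, 36, 36), tolerance = 1e-12)
})

test_that("centre-based demosaicking reads the nearest same-band pixel", {
  pat <- cfa_pattern(3)
  # every centre phase finds any band within Chebyshev distance L - 1 = 2
  offs <- expand.grid(dy = -2:2, dx = -2:2)
  for (pr in 0:2) for (pc in 0:2) {
    bands_seen <- unique(pat$tile[cbind((pr + offs$dy) %% 3 + 1,
                                        (pc + offs$dx) %% 3 + 1)])
    expect_setequal(bands_seen, 1:9)
  }
  # the centre pixel supplies its own band verbatim
  set.seed(43)
  raw <- matrix(runif(30 * 30), 30, 30)
  cm <- build_centre_map(data.frame(x = c(11, 17, 23), y = c(11, 17, 23),
                                    score = 1:3), D = 5)
  cs <- centre_based_demosaick(raw, pat, cm)
  P <- decombench:::expand_pattern(pat, 30, 30)
  for (i in 1:3) {
    xi <- cs$centres[i, "x"]; yi <- cs$centres[i, "y"]
    expect_equal(cs$spectra[i, P[yi, xi]], raw[yi, xi])
  }
  # constant raw: every centre spectrum is flat
  csc <- centre_based_demosaick(matrix(3, 30, 30), pat, cm)
  expect_equal(csc$spectra, matrix(3, 3, 9))
  # sampling ratio T >= 1 is refused
  cm_small <- build_centre_map(data.frame(x = c(11, 17, 23),
                                          y = c(11, 17, 23), score = 1:3),
                               D = 3)
  expect_error(suppressWarnings(centre_based_demosaick(raw, pat, cm_small)),
               "T = L/D")
})

test_that("nearest-band search equals exhaustive search for random centres", {
  set.seed(44)
  raw <- matrix(runif(60 * 60), 60, 60)
  pat <- cfa_pattern(3)
  P <- decombench:::expand_pattern(pat, 60, 60)
  xs <- round(runif(100, 6, 55)); ys <- round(runif(100, 6, 55))
  sc <- data.frame(x = xs, y = ys, score = seq_len(100))
  cm <- structure(list(centres = cbind(x = xs, y = ys),
                       scores = seq_len(100), D = 7, n_candidates = 100L),
                  class = "centre_map")
  cs <- centre_based_demosaick(raw, pat, cm)
  for (i in seq(1, 100, by = 7)) for (k in c(1, 5, 9)) {
    expect_equal(cs$spectra[i, k],
                 nn_band_reference(raw, P, xs[i], ys[i], k))
  }
  # completeness whenever T < 1
  expect_false(anyNA(cs$spectra))
})

test_that("centre spectra interpolate through one shared look-up table", {
  set.seed(45)
  pts <- cbind(x = runif(40, 3, 45), y = runif(40, 3, 45))
  spectra <- structure(list(spectra = matrix(runif(40 * 9), 40, 9),
                            centres = pts, L = 3), class = "centre_spectra")
  lut <- interp_lut(pts, c(48, 48))
  shared <- interpolate_centre_spectra(spectra, c(48, 48), lut = lut)
  per_band <- lapply(1:9, function(k) {
    lut_k <- interp_lut(pts, c(48, 48))   # independently rebuilt per band
    interp_apply(lut_k, spectra$spectra[, k])
  })
  for (k in 1:9)
    expect_identical(shared$bands[[k]], matrix(per_band[[k]], 48, 48))
  # per-band planar spectra come back as exact planes inside the hull
  v <- outer(pts[, 1], 1:9) + outer(pts[, 2], rep(1, 9))   # a x + y per band
  spectra$spectra <- v
  cube <- interpolate_centre_spectra(spectra, c(48, 48), lut = lut)
  inside <- attr(interp_apply(lut, v[, 1]), "validity")
  for (k in c(2, 6)) {
    plane <- outer(seq_len(48), seq_len(48), function(y, x) k * x + y)
    expect_lt(max(abs(cube$bands[[k]] - plane)[inside]), 1e-9)
  }
})

test_that("a CFA pattern round-trips through its JSON serialisation", {
  dir <- withr::local_tempdir()
  pat <- cfa_pattern(3, tile = matrix(c(5, 1, 9, 2, 7, 3, 8, 4, 6), 3, 3),
                     offset = c(1, 2))
  p <- file.path(dir, "pattern.json")
  write_cfa_pattern(pat, p)
  back <- read_cfa_pattern(p)
  expect_equal(back$tile, pat$tile)
  expect_equal(back$offset, pat$offset)
  expect_equal(back$L, 3)
  expect_equal(decombench:::expand_pattern(back, 9, 9),
               decombench:::expand_pattern(pat, 9, 9))
})

test_that("cube serialisation writes pages plus band metadata", {
  dir <- withr::local_tempdir()
  cube <- spectral_cube(lapply(1:9, function(k) matrix(k, 12, 12)),
                        band_meta = srda_band_meta())
  p <- file.path(dir, "cube.tif")
  write_cube(cube, p)
  expect_equal(length(tiff::readTIFF(p, all = TRUE)), 9)
  meta <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(nrow(meta$band_meta), 9)
  # centre spectra CSV round trip
  cs <- structure(list(spectra = matrix(1:18, 2, 9),
                       centres = cbind(x = c(1, 2), y = c(3, 4)), L = 3),
                  class = "centre_spectra")
  f <- file.path(dir, "spectra.csv")
  write_centre_spectra(cs, f)
  back <- read.csv(f)
  expect_equal(back$band1, c(1, 2))
  expect_equal(names(back), c("x", "y", paste0("band", 1:9)))
})
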