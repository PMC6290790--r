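test_that("Michelson contrast evaluates the printed ratio", {
  tg <- make_target("bar_target", side = 320, spacings = c(20, 28, 40),
                    bar_value = 150, space_value = 50, blur_sigma = 0,
                    noise_sigma = 0)
  el <- tg$geometry$elements[[1]]
  expect_equal(michelson_contrast(tg$T, el), (150 - 50) / (150 + 50))
  expect_equal(michelson_contrast(matrix(80, 256, 256), el), 0)
  # affine intensity maps with positive gain leave the ratio's zero alone
  # and full modulation (space level 0) gives contrast one
  tg1 <- make_target("bar_target", side = 320, spacings = c(20, 28, 40),
                     blur_sigma = 0)
  expect_equal(michelson_contrast(tg1$T, tg1$geometry$elements[[2]]), 1)
  expect_equal(michelson_contrast(0.5 * tg$T, el), 0.5)  # gain-invariant
})

test_that("resolution is the 5% crossing of the fitted contrast curve", {
  sp <- c(20, 24, 29, 35, 42, 50, 60, 72, 80)
  # analytic curve crossing 5% between 20 and 24 px
  ct <- 1 - exp(-(sp - 19) / 8)
  ct[1] <- 0.03; ct[2] <- 0.08
  R <- resolution(sp, ct)
  expect_gt(R, 20); expect_lt(R, 24)
  # contrast high everywhere: resolution is limited by the target
  expect_equal(resolution(sp, rep(0.6, 9)), 20)
  # validity condition: contrast above 1% at more than 3 distinct spacings
  expect_true(is.na(resolution(sp, c(0.2, 0.3, 0.4, rep(0.005, 6)))))
  expect_false(is.na(resolution(sp, c(0.2, 0.3, 0.4, 0.2, rep(0.005, 5)))))
  # the threshold is 5%, not 1%: a 3% plateau counts as unresolved under
  # the 5% rule but fully resolved under a 1% rule
  ct3 <- c(0.03, 0.03, 0.03, 0.5, 0.6, 0.7, 0.8, 0.9, 0.9)
  expect_gt(resolution(sp, ct3), resolution(sp, ct3, threshold = 0.01))
})

test_that("smoothness is the population standard deviation", {
  expect_equal(smoothness(matrix(6, 20, 20)), 0)
  two <- matrix(c(0, 2), 20, 20)          # equal halves of 0 and 2
  expect_equal(smoothness(two), 1)
  checker <- outer(1:16, 1:16, function(i, j) (i + j) %% 2) * 4
  expect_equal(smoothness(checker), 2)    # half 0, half 4: sd = 2
  cube <- spectral_cube(list(two, matrix(6, 20, 20), two * 2))
  expect_equal(smoothness(cube), mean(c(1, 0, 2)))
  # region argument restricts the statistic
  m <- matrix(0, 20, 20); m[1:10, ] <- 100
  expect_equal(smoothness(m, region = c(1, 1, 20, 10)), 0)
})

test_that("signal is the ROI mean, band-averaged for cubes", {
  img <- matrix(156, 32, 32)
  expect_equal(signal_roi(img, roi = c(5, 5, 10, 10)), 156)
  cube <- spectral_cube(rep(list(matrix(10, 32, 32), matrix(30, 32, 32)), 5)[1:9])
  expect_equal(signal_roi(cube, roi = c(5, 5, 10, 10), bands = c(1, 2)), 20)
})

test_that("spectral accuracy Q follows the normalised mean-square formula", {
  mk <- function(v) spectral_cube(lapply(v, function(x) matrix(x, 4, 4)))
  # two-band toy: (0.8, 0.2) vs E = (0.6, 0.4) after AUC normalisation
  expect_equal(asr(mk(c(0.8, 0.2)), c(0.6, 0.4)), 0.08)
  # proportional spectra score exactly zero at any global scale
  E <- c(1, 5, 2, 8, 3, 7, 4, 6, 9)
  expect_equal(asr(mk(E * 3.7), E), 0)
  expect_equal(asr(mk(E * 0.01), E), asr(mk(E * 100), E))
  # spectra are spatially averaged before normalisation: a cube whose two
  # halves hold different spectra scores by its mean spectrum
  half <- function(a, b) { m <- matrix(a, 4, 4); m[, 3:4] <- b; m }
  cube <- spectral_cube(list(half(0.9, 0.7), half(0.1, 0.3)))
  expect_equal(asr(cube, c(0.6, 0.4)), 0.08)  # mean spectrum is (0.8, 0.2)
  expect_error(asr(mk(c(1, 2)), 1:9), "band count")
  expect_error(asr(mk(c(0, 0)), c(1, 1)), "zero-sum")
})

test_that("per-frame speed scales roughly with the number of bands", {
  img <- matrix(runif(384^2), 384, 384)
  t1 <- speed_metric(function(f) gaussian_decomb(f, 5), img, reps = 5)
  t9 <- speed_metric(function(f) lapply(rep(list(f), 9), gaussian_decomb,
                                        r = 5), img, reps = 5)
  expect_gte(t1, 0)
  expect_gt(t9 / t1, 4.5)   # nine images to correct rather than one,
  expect_lt(t9 / t1, 18)    # within a loose factor of L^2
})

test_that("score normalisation maps extrema to 0 and 1 with the right polarity", {
  raw <- data.frame(method = c("a", "b", "c"), r = 1:3,
                    R = c(228, 364, 500), sigma = c(4, 10, 32),
                    S = c(114, 130, 157))
  sc <- normalise_scores(raw)
  expect_equal(sc$S_res, c(1, 0.5, 0))        # a realistic resolution span
  expect_equal(sc$S_smooth[c(1, 3)], c(1, 0))
  expect_equal(sc$S_signal[c(1, 3)], c(0, 1)) # signal polarity is reversed
  expect_true(all(sc$S_res >= 0 & sc$S_res <= 1))
  # undefined resolution gets the worst score
  raw$R[2] <- NA
  expect_equal(normalise_scores(raw)$S_res[2], 0)
  # degenerate comparison set: scores defined as 1, with a message
  expect_message(sc2 <- normalise_scores(
    data.frame(method = "a", r = 1:2, sigma = c(3, 3))), "degenerate")
  expect_equal(sc2$S_smooth, c(1, 1))
})
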