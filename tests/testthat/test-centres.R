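test_that("candidate selection equals the brute-force neighbourhood range", {
  set.seed(21)
  img <- matrix(runif(30 * 30, 0, 100), 30, 30)
  D <- 5; I_min <- 60
  cand <- find_candidates(img, D, I_min)
  d <- (D - 1) / 2
  ref <- NULL
  for (y in (d + 1):(30 - d)) for (x in (d + 1):(30 - d)) {
    N <- img[(y - d):(y + d), (x - d):(x + d)]
    if (max(N) - min(N) > I_min) ref <- rbind(ref, c(x, y))
  }
  expect_equal(nrow(cand), nrow(ref))
  expect_equal(as.matrix(cand[order(cand$y, cand$x), ]),
               ref[order(ref[, 2], ref[, 1]), ], ignore_attr = TRUE)
  # a constant image has range zero everywhere: no candidates
  expect_equal(nrow(find_candidates(matrix(7, 30, 30), D, I_min)), 0)
  expect_error(find_candidates(img, 4, I_min), "odd")
  expect_error(find_candidates(matrix(0, 3, 3), 5, 10), "smaller")
})

test_that("quasi-Gaussian scoring matches the printed surface formula", {
  # flat image of height 8 with a 3x3 neighbourhood, D = 3:
  # s_c = sum over the 8 off-centre pixels of (8 exp(-l^4/18) - 8)^2
  img <- matrix(8, 9, 9)
  sc <- score_candidates(img, data.frame(x = 5, y = 5), D = 3)
  expected <- 4 * (8 * exp(-1 / 18) - 8)^2 + 4 * (8 * exp(-4 / 18) - 8)^2
  expect_equal(sc$score, expected)
  # an image exactly equal to the quasi-Gaussian scores zero, and the
  # surface equals H at the candidate itself (exponent 0)
  D <- 7; d <- 3; H <- 42
  G <- outer(-d:d, -d:d, function(dy, dx)
    H * exp(-(dx^2 + dy^2)^2 / (2 * D^2)))
  img2 <- matrix(0, 15, 15)
  img2[(8 - d):(8 + d), (8 - d):(8 + d)] <- G
  sc2 <- score_candidates(img2, data.frame(x = 8, y = 8), D = D)
  expect_equal(sc2$score, 0)
  expect_equal(img2[8, 8], H)
  expect_error(score_candidates(img2, data.frame(x = 2, y = 8), D = D),
               "border")
})

test_that("greedy centre map enforces the strict exclusion radius", {
  # two candidates half a diameter apart: only the better score survives
  sc <- data.frame(x = c(10, 13), y = c(10, 10), score = c(1, 2))
  cm <- build_centre_map(sc, D = 6)
  expect_equal(nrow(cm$centres), 1)
  expect_equal(unname(cm$centres[1, ]), c(10, 10))
  # candidates all farther than D apart are accepted regardless of score
  sc2 <- data.frame(x = c(0, 20, 40), y = c(0, 0, 0), score = c(9, 1, 5))
  cm2 <- build_centre_map(sc2, D = 6)
  expect_equal(nrow(cm2$centres), 3)
  # scores ascend in acceptance order
  expect_false(is.unsorted(cm2$scores))
  # empty input gives an empty map
  expect_equal(nrow(build_centre_map(sc2[0, ], D = 6)$centres), 0)
})

test_that("greedy acceptance equals the O(n^2) brute-force oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 500
    sc <- data.frame(x = round(runif(n, 1, 80)), y = round(runif(n, 1, 80)),
                     score = round(runif(n, 0, 20)))  # rounded: forces ties
    cm <- build_centre_map(sc, D = 7)
    ref <- greedy_reference(sc$x, sc$y, sc$score, D = 7)
    expect_equal(nrow(cm$centres), length(ref))
    got <- cm$centres[order(cm$centres[, "x"], cm$centres[, "y"]), ]
    want <- cbind(x = sc$x[ref], y = sc$y[ref])
    want <- want[order(want[, "x"], want[, "y"]), ]
    expect_equal(got, want, ignore_attr = TRUE)
    # exclusion invariant on every output
    expect_gt(min_pair_dist(cm$centres), 7)
  }
})

test_that("centre finding is deterministic and flags misconfiguration", {
  cb <- small_comb()
  cal <- apply_comb(matrix(150, 128, 128), cb, noise_sigma = 2.55, seed = 5)
  m1 <- find_centres(cal, D = 7, I_min = 50)
  m2 <- find_centres(cal, D = 7, I_min = 50)
  expect_identical(m1, m2)
  expect_warning(cm <- find_centres(matrix(0, 64, 64), D = 7, I_min = 50),
                 "I_min")
  expect_equal(nrow(cm$centres), 0)
})

test_that("mosaic calibration with pre-blur finds the same comb", {
  cb <- generate_comb(comb_spec(image_side = 192, seed = 13))
  plain <- apply_comb(matrix(150, 192, 192), cb, noise_sigma = 2.55, seed = 1)
  n_plain <- nrow(find_centres(plain, D = 7, I_min = 50)$centres)
  # same comb seen through the 3x3 mosaic under broadband illumination
  cal <- default_calibration()
  flat <- spectral_calibration(cal$lambda, rep(1, length(cal$lambda)),
                               cal$responses)
  s <- flat$E / max(flat$E)
  raw <- apply_cfa(ms_scene_bands(matrix(150, 192, 192), cb, s),
                   cfa_pattern(3), noise_sigma = 2.55, seed = 1)
  n_mosaic <- nrow(find_centres(raw, D = 7, I_min = 12,
                                pre_blur_sigma = 1.5)$centres)
  expect_lt(abs(n_mosaic - n_plain) / n_plain, 0.05)
  # pre_blur_sigma = 0 is exactly the direct pipeline
  expect_identical(find_centres(plain, D = 7, I_min = 50),
                   find_centres(plain, D = 7, I_min = 50,
                                pre_blur_sigma = 0))
})

test_that("centre recovery degrades gracefully with noise", {
  cb <- recovery_comb()
  rates <- vapply(c(0, 2.55, 12.75), function(ns) {
    cal <- apply_comb(make_target("uniform", side = 146, value = 150), cb,
                      noise_sigma = ns, seed = 77)
    recovery_rate(find_centres(cal, D = 7, I_min = 50), cb$centres, tol = 2)
  }, numeric(1))
  expect_equal(rates[1], 1)          # sigma = 0: every centre found
  expect_gte(rates[2], 0.95)         # sigma = 1% of dynamic range
  expect_gte(rates[3], 0.6)          # sigma = 5%: degraded but not collapsed
  expect_true(all(diff(rates) <= 0.02 + 1e-9))
})
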