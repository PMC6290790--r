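test_that("overall performance is the weighted score sum on the simplex", {
  sc <- list(S_res = 0.5, S_smooth = 1.0, S_signal = 0.0, S_ASR = 0.8)
  expect_equal(overall_performance(sc, c(0.25, 0.25, 0.25, 0.25)), 0.575)
  expect_equal(overall_performance(sc, c(1, 0, 0, 0)), sc$S_res)
  ones <- list(S_res = 1, S_smooth = 1, S_signal = 1, S_ASR = 1)
  expect_equal(overall_performance(ones, c(0.1, 0.2, 0.3, 0.4)), 1)
  # linearity in the weights for fixed scores
  w1 <- c(0.6, 0.2, 0.1, 0.1); w2 <- c(0.1, 0.3, 0.4, 0.2); a <- 0.3
  expect_equal(overall_performance(sc, a * w1 + (1 - a) * w2),
               a * overall_performance(sc, w1) +
               (1 - a) * overall_performance(sc, w2))
  expect_error(overall_performance(sc, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(overall_performance(sc, c(1.2, -0.2, 0, 0)), "sum to 1")
})

test_that("the weight sweep finds winners, corners and crossovers", {
  # a single method wins everywhere
  solo <- data.frame(method = "gaussian", r = 5, S_res = 0.4,
                     S_smooth = 0.6, S_signal = 0.5)
  map <- sweep_weights(solo, step = 0.25)
  expect_true(all(map$method == "gaussian"))
  # two complementary methods flip across the w_res = w_smooth diagonal
  two <- data.frame(method = c("gaussian", "median"), r = c(5, 5),
                    S_res = c(1, 0), S_smooth = c(0, 1),
                    S_signal = c(0.5, 0.5))
  map2 <- sweep_weights(two, step = 0.1)
  expect_true(all(map2$method[map2$w_res > map2$w_smooth] == "gaussian"))
  expect_true(all(map2$method[map2$w_res < map2$w_smooth] == "median"))
  # corner winners equal the single-metric argmax
  set.seed(51)
  tab <- data.frame(method = c("interpolation", "fourier", "gaussian"),
                    r = c(NA, 3, 3), S_res = runif(3), S_smooth = runif(3),
                    S_signal = runif(3))
  map3 <- sweep_weights(tab, step = 0.2)
  corner <- function(w) map3[map3[[w]] == 1, "method"]
  expect_equal(as.character(corner("w_res")),
               as.character(tab$method[which.max(tab$S_res)]))
  expect_equal(as.character(corner("w_smooth")),
               as.character(tab$method[which.max(tab$S_smooth)]))
  expect_equal(as.character(corner("w_signal")),
               as.character(tab$method[which.max(tab$S_signal)]))
  expect_error(sweep_weights(tab[0, ]), "empty")
})

test_that("refining the weight grid never changes coarse-grid winners", {
  set.seed(52)
  tab <- data.frame(method = c("interpolation", "fourier", "gaussian",
                               "median"),
                    r = c(NA, 2, 2, 2), S_res = runif(4),
                    S_smooth = runif(4), S_signal = runif(4))
  coarse <- sweep_weights(tab, step = 0.2)
  fine <- sweep_weights(tab, step = 0.05)
  key <- function(m) paste(round(m$w_res, 6), round(m$w_smooth, 6),
                           round(m$w_signal, 6))
  idx <- match(key(coarse), key(fine))
  expect_false(anyNA(idx))
  expect_equal(as.character(coarse$method), as.character(fine$method[idx]))
  expect_equal(coarse$OP, fine$OP[idx])
})

test_that("exact ties go to the fixed method order, then to smaller r", {
  tied <- data.frame(method = c("median", "fourier", "interpolation"),
                     r = c(2, 2, NA), S_res = 1, S_smooth = 1, S_signal = 1)
  map <- sweep_weights(tied, step = 0.5)
  expect_true(all(map$method == "interpolation"))
  tied2 <- data.frame(method = "gaussian", r = c(8, 2), S_res = 1,
                      S_smooth = 1, S_signal = 1)
  expect_true(all(sweep_weights(tied2, step = 0.5)$r == 2))
})

test_that("a small end-to-end benchmark is deterministic and writable", {
  cfg <- benchmark_config(mode = "monochrome", image_side = 192,
                          spacings = c(10, 12, 16, 20, 24),
                          r_grid = c(2, 5),
                          methods = c("interpolation", "gaussian"),
                          seed = 9)
  b1 <- run_benchmark(cfg, verbose = FALSE)
  b2 <- run_benchmark(cfg, verbose = FALSE)
  keep <- setdiff(names(b1$scores), "t")   # timing is not deterministic
  expect_equal(b1$scores[keep], b2$scores[keep])
  expect_equal(b1$map, b2$map)
  expect_s3_class(b1, "decomb_benchmark")
  expect_output(print(b1), "Decombing benchmark")
  dir <- withr::local_tempdir()
  write_benchmark(b1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("scores.csv", "winner_map.csv", "manifest.json", "winner_map.png")))))
  got <- read.csv(file.path(dir, "scores.csv"))
  expect_equal(nrow(got), nrow(b1$scores))
})
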