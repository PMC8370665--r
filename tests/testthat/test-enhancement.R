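test_that("extract_green selects channel 2", {
  img <- array(0, c(2, 2, 3))
  img[, , 1] <- 10; img[, , 2] <- 200; img[, , 3] <- 30
  expect_true(all(extract_green(img) == 200))

  img2 <- array(c(0, 255, 0, 255, 0, 255), c(1, 2, 3))
  expect_equal(as.vector(extract_green(img2)), c(0, 255))

  expect_error(extract_green(matrix(0, 2, 2)), "RGB")
})

test_that("clip limit follows the tile-average formula", {
  r <- clahe_clip_limit(clahe_config(64, 64, 256, 4))
  expect_equal(r$n_avg, 16)
  expect_equal(r$n_cl, 64)

  r <- clahe_clip_limit(clahe_config(8, 8, 64, 1))
  expect_equal(r$n_avg, 1)
  expect_equal(r$n_cl, 1)

  r <- clahe_clip_limit(clahe_config(100, 50, 256, 2))
  expect_equal(r$n_avg, 19.53125)
  expect_equal(r$n_cl, 39.0625)

  # scaling both tile dims by k scales n_avg by k^2 exactly
  for (k in 2:4) {
    base <- clahe_clip_limit(clahe_config(10, 14, 128, 3))
    scaled <- clahe_clip_limit(clahe_config(10 * k, 14 * k, 128, 3))
    expect_equal(scaled$n_avg, k^2 * base$n_avg)
  }
  expect_error(clahe_config(gray_levels = 0), "gray_levels")
})

test_that("clahe output stays in range with monotone per-tile mappings", {
  set.seed(4)
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  cfg <- clahe_config(16, 16, 256, 2)
  out <- clahe(img, cfg)
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(dim(out), dim(img))
  maps <- dedscreen:::clahe_maps(img, cfg)$maps
  for (i in seq_len(dim(maps)[1])) for (j in seq_len(dim(maps)[2]))
    expect_true(all(diff(maps[i, j, ]) >= 0))
  expect_error(clahe(matrix(0, 4, 4), clahe_config(16, 16)), "tile larger")
})

test_that("clahe without interpolation matches a per-tile equalization oracle", {
  set.seed(9)
  G <- 16L
  img <- matrix(sample(0:(G - 1), 12 * 12, replace = TRUE), 12, 12)
  cfg <- clahe_config(6, 6, G, 2)  # 2 x 2 tile grid
  got <- clahe(img, cfg, interpolate = FALSE)
  # oracle: clip each tile histogram, redistribute, map through scaled CDF
  n_cl <- 2 * 6 * 6 / G
  oracle <- img * 0
  for (ti in 0:1) for (tj in 0:1) {
    rows <- (ti * 6 + 1):(ti * 6 + 6); cols <- (tj * 6 + 1):(tj * 6 + 6)
    tile <- img[rows, cols]
    h <- vapply(0:(G - 1), function(v) sum(tile == v), 0)
    extra <- sum(pmax(h - n_cl, 0))
    h <- pmin(h, n_cl) + extra / G
    cdf <- cumsum(h) / sum(h)
    oracle[rows, cols] <- floor((G - 1) * cdf[tile + 1] + 0.5)
  }
  expect_identical(got, oracle)
})

test_that("illumination correction implements p + desired - local mean", {
  # uniform image at the desired mean is a fixed point
  u <- matrix(128, 16, 16)
  expect_identical(correct_illumination(u, desired_mean = 128, window_side = 5L), u)

  # 3x3 image, center 100, window mean 90 -> corrected center 138
  m <- matrix(90, 3, 3); m[3, 3] <- 80; m[2, 2] <- 100
  stopifnot(mean(m) == 90)
  out <- correct_illumination(m, desired_mean = 128, window_side = 3L)
  expect_equal(out[2, 2], 138)

  expect_error(correct_illumination(u, window_side = 4L), "odd")
})

test_that("a linear illumination ramp is flattened to the target mean", {
  # ramp-lit field with mild sensor noise, as the generator produces it
  set.seed(19)
  side <- 96L
  ramp <- 110 + 30 * (matrix(seq_len(side), side, side, byrow = TRUE) / side - 0.5)
  img <- clamp(round_half_up(ramp + rnorm(side * side, 0, 2)), 0, 255)
  out <- correct_illumination(img, desired_mean = 120, window_side = 31L)
  sliding_mean <- function(m, k) {  # independent of the package box filter
    h <- (k - 1) / 2
    sapply(seq(h + 1, ncol(m) - h, by = 8), function(c)
      sapply(seq(h + 1, nrow(m) - h, by = 8), function(r)
        mean(m[(r - h):(r + h), (c - h):(c + h)])))
  }
  expect_true(all(abs(sliding_mean(out, 31L) - 120) <= 2))
})

test_that("illumination correction with the global mean preserves it", {
  set.seed(2)
  img <- matrix(sample(40:200, 40 * 40, replace = TRUE), 40, 40)
  out <- correct_illumination(img, desired_mean = mean(img), window_side = 7L)
  expect_lt(abs(mean(out) - mean(img)), 1)
})

test_that("contrast stretch maps the extremes and is idempotent", {
  img <- matrix(c(50, 100, 150), 1, 3)
  out <- stretch_contrast(img, 256L)
  expect_equal(as.vector(out), c(0, 128, 255))  # round-half-up at 127.5

  set.seed(5)
  r <- matrix(sample(30:220, 100, replace = TRUE), 10, 10)
  s1 <- stretch_contrast(r, 256L)
  expect_equal(min(s1), 0)
  expect_equal(max(s1), 255)
  expect_identical(stretch_contrast(s1, 256L), s1)

  expect_error(stretch_contrast(matrix(7, 3, 3)), "constant")
})

test_that("median filter matches the brute-force window-sort oracle", {
  m <- matrix(c(1, 4, 7, 2, 100, 8, 3, 6, 9), 3, 3)  # column-major
  expect_equal(median_filter(m, c(3L, 3L))[2, 2], 6)

  const <- matrix(42, 5, 7)
  expect_identical(median_filter(const, c(3L, 3L)), const)

  set.seed(8)
  img <- matrix(sample(0:255, 21 * 21, replace = TRUE), 21, 21)
  for (w in list(c(3L, 3L), c(5L, 3L))) {
    got <- median_filter(img, w)
    want <- brute_median(img, w[1], w[2])
    hr <- (w[1] - 1) / 2; hc <- (w[2] - 1) / 2
    ri <- (hr + 1):(21 - hr); ci <- (hc + 1):(21 - hc)
    expect_identical(got[ri, ci], want[ri, ci])
    expect_identical(got, want)  # same replication border rule
  }
  expect_error(median_filter(img, c(2L, 3L)), "odd")
})

test_that("median filter commutes with monotone gray relabeling", {
  set.seed(3)
  img <- matrix(sample(0:63, 15 * 15, replace = TRUE), 15, 15)
  relab <- function(x) 3 * x + 10  # strictly increasing
  a <- relab(median_filter(img, c(3L, 3L)))
  b <- median_filter(relab(img), c(3L, 3L))
  expect_identical(a[2:14, 2:14], b[2:14, 2:14])
})
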