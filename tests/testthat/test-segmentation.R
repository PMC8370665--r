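test_that("isodata threshold finds the intermeans fixed point", {
  img <- matrix(c(rep(10, 100), rep(200, 100)), 10, 20)
  expect_equal(isodata_threshold(img, 0.01), 105, tolerance = 0.02)

  img2 <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  expect_equal(isodata_threshold(img2, 0.01), 127.5, tolerance = 0.02)

  set.seed(6)
  v <- c(rnorm(600, 60, 8), rnorm(1400, 170, 15))
  v <- clamp(round(v), 0, 255)
  img3 <- matrix(v, 40, 50)
  t_pkg <- isodata_threshold(img3, 0.05)
  t_bf <- brute_isodata(as.vector(img3))
  expect_equal(t_pkg, t_bf, tolerance = 0.5)

  expect_error(isodata_threshold(matrix(5, 3, 3)), "constant")
})

test_that("vessel segmentation recovers the synthetic tree", {
  f <- cached_fundus("normal")
  vm <- segment_vessels(f$image)
  expect_true(is.logical(vm))
  expect_identical(dim(vm), dim(f$image)[1:2])
  expect_gte(dice_coef(vm, f$truth$vessel_mask), 0.6)
  # deterministic
  expect_identical(segment_vessels(f$image), vm)
})

test_that("a vessel-free field yields (almost) no vessel pixels", {
  cfg <- synth_config(seed = 13L, vessel_branches = 0L)
  f <- generate_fundus(cfg, "normal")
  expect_false(any(f$truth$vessel_mask))
  vm <- segment_vessels(f$image)
  expect_lt(mean(vm), 0.02)
})

test_that("the circular Hough transform recovers rasterized circles", {
  edges <- raster_circle(128, c(60, 50), 20)
  hyp <- hough_circles(edges, c(10, 30), n_best = 1L)
  expect_equal(nrow(hyp), 1L)
  expect_lte(abs(hyp$center_row - 60), 2)
  expect_lte(abs(hyp$center_col - 50), 2)
  expect_lte(abs(hyp$radius - 20), 1)
  # a perfect circle's center collects one vote per edge pixel
  expect_equal(hyp$votes, sum(edges))

  expect_identical(nrow(hough_circles(matrix(FALSE, 32, 32), c(5, 10))), 0L)
  expect_error(hough_circles(edges, c(30, 10)), "radius range")
})

test_that("two disjoint circles give two matching hypotheses", {
  edges <- raster_circle(128, c(40, 40), 15) | raster_circle(128, c(90, 95), 22)
  hyp <- hough_circles(edges, c(10, 30), n_best = 2L)
  expect_equal(nrow(hyp), 2L)
  err <- function(h, ctr, r)
    max(abs(h$center_row - ctr[1]), abs(h$center_col - ctr[2])) <= 2 &&
      abs(h$radius - r) <= 1
  match1 <- err(hyp[1, ], c(40, 40), 15) || err(hyp[1, ], c(90, 95), 22)
  match2 <- err(hyp[2, ], c(40, 40), 15) || err(hyp[2, ], c(90, 95), 22)
  expect_true(match1 && match2)
  expect_false(identical(hyp$center_row[1], hyp$center_row[2]) &&
                 identical(hyp$center_col[1], hyp$center_col[2]))
})

test_that("optic-disc detection localizes the disc and covers it", {
  for (lab in c("normal", "mild_gl")) {
    f <- cached_fundus(lab)
    od <- detect_optic_disc(f$image)
    ctr <- f$truth$disc_center
    expect_lte(sqrt((od$circle$center_row - ctr[1])^2 +
                      (od$circle$center_col - ctr[2])^2), 5)
    expect_lte(abs(od$circle$radius - f$truth$disc_radius),
               0.1 * f$truth$disc_radius)
    gt <- disc_mask_of(nrow(od$mask), ctr, f$truth$disc_radius)
    expect_gte(sum(od$mask & gt) / sum(gt), 0.9)
  }
})

test_that("detection fails cleanly when no bright circle exists", {
  set.seed(21)
  flat <- array(clamp(round(rnorm(96 * 96 * 3, 120, 4)), 0, 255), c(96, 96, 3))
  expect_error(detect_optic_disc(flat), "detection failure")
})

test_that("remove_region honors the fill strategies and leaves the rest alone", {
  set.seed(12)
  img <- matrix(as.numeric(sample(0:255, 20 * 20, replace = TRUE)), 20, 20)
  none <- matrix(FALSE, 20, 20)
  expect_identical(remove_region(img, none, "background-mean"), img)

  full <- matrix(TRUE, 20, 20)
  out <- remove_region(img, full, "background-mean")
  expect_equal(length(unique(as.vector(out))), 1L)

  m <- matrix(FALSE, 20, 20); m[5:9, 5:9] <- TRUE
  for (strat in c("background-mean", "neighborhood-mean")) {
    out <- remove_region(img, m, strat)
    expect_identical(out[!m], img[!m])
  }
  expect_error(remove_region(img, matrix(FALSE, 5, 5)), "dimensions")
})

test_that("exudate detection counts the synthetic blobs and spares normals", {
  cfg <- synth_config(seed = 17L, exudate_count_range = c(3, 3))
  f <- generate_fundus(cfg, "mild_dme")
  vm <- segment_vessels(f$image)
  od <- detect_optic_disc(f$image)
  ex <- detect_exudates(f$image, od$mask, vm)
  expect_identical(count_components(ex), 3L)
  # every detected component overlaps a ground-truth blob
  lab <- EBImage::bwlabel(ex * 1)
  for (k in seq_len(max(lab)))
    expect_true(any(f$truth$exudate_mask[lab == k]))
  expect_false(any(ex & od$mask))

  n <- cached_fundus("normal")
  vm_n <- segment_vessels(n$image)
  od_n <- detect_optic_disc(n$image)
  ex_n <- detect_exudates(n$image, od_n$mask, vm_n)
  expect_lt(mean(ex_n), 0.005)
  # deterministic
  expect_identical(detect_exudates(f$image, od$mask, vm), ex)
})

test_that("exudate recall does not increase as blob contrast drops", {
  base <- cached_fundus("normal", seed = 31)
  side <- nrow(base$truth$vessel_mask)
  centers <- rbind(c(40, 90), c(70, 75), c(95, 100))
  recalls <- vapply(c(120, 60, 30), function(amp) {
    img <- base$image
    gt <- matrix(FALSE, side, side)
    rr <- matrix(seq_len(side), side, side)
    cc <- matrix(seq_len(side), side, side, byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      a <- exp(-((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2) / (2 * 2.5^2))
      for (ch in 1:3) img[, , ch] <- clamp(img[, , ch] + amp * a, 0, 255)
      gt <- gt | (a >= 0.5)
    }
    vm <- segment_vessels(img)
    od <- detect_optic_disc(img)
    ex <- detect_exudates(img, od$mask, vm)
    sum(ex & gt) / sum(gt)
  }, 0)
  expect_true(all(diff(recalls) <= 1e-9))
})
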