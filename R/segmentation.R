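#' Region-of-interest segmentation
#'
#' Three pipelines: blood-vessel extraction (enhancement, ISODATA
#' thresholding of the darker class, morphological cleanup), optic-disc
#' detection (enhancement, median filtering, edge map, circular Hough
#' transform, threshold refinement) and exudate localization (enhancement,
#' disc and vessel removal, Otsu thresholding of the bright class, opening).
#'
#' @name segmentation
NULL

#' ISODATA (intermeans) threshold
#'
#' Iterates `t <- (mean of pixels <= t + mean of pixels > t) / 2` from the
#' global mean until the update is below `tolerance`.
#'
#' @param img gray matrix with at least two distinct values.
#' @param tolerance convergence tolerance in intensity units.
#' @param max_iter iteration cap.
#' @return threshold level (numeric scalar).
#' @export
isodata_threshold <- function(img, tolerance = 0.5, max_iter = 100L) {
  v <- as.vector(img)
  if (min(v) == max(v)) stop_degenerate("constant image: ISODATA threshold undefined")
  t <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(hi)) hi <- max(v)
    if (!length(lo)) lo <- min(v)
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tolerance) return(t_new)
    t <- t_new
  }
  t
}

#' Vessel segmentation configuration
#'
#' @param clahe a [clahe_config()].
#' @param closing_se structuring element for the closing step.
#' @param min_component_size drop vessel components smaller than this (px).
#' @param isodata_tolerance convergence tolerance for [isodata_threshold()].
#' @param illum_window window side for illumination correction.
#' @return object of class `vessel_config`.
#' @export
vessel_config <- function(clahe = clahe_config(), closing_se = struct_el(),
                          min_component_size = 20L, isodata_tolerance = 0.5,
                          illum_window = 31L) {
  if (min_component_size < 0) stop("min_component_size must be >= 0")
  structure(list(clahe = clahe, closing_se = closing_se,
                 min_component_size = as.integer(min_component_size),
                 isodata_tolerance = isodata_tolerance,
                 illum_window = as.integer(illum_window)),
            class = "vessel_config")
}

#' Blood-vessel segmentation
#'
#' Pipeline: green channel -> CLAHE -> illumination correction -> ISODATA
#' threshold (vessels are the darker class) -> closing -> small-component
#' removal. The vessel network occupies a small fraction of the retinal
#' field, so a dark class spanning more than `max_fraction` of the image is
#' background texture (e.g. the symmetric split of a vessel-free field) and
#' yields an empty mask. Deterministic.
#'
#' @param img RGB fundus array.
#' @param cfg a [vessel_config()].
#' @param max_fraction plausibility cap on the dark-class area fraction.
#' @return logical vessel mask with the input's dimensions.
#' @export
segment_vessels <- function(img, cfg = vessel_config(), max_fraction = 0.35) {
  e <- enhance_fundus(img, cfg$clahe, illum_window = cfg$illum_window)
  t <- isodata_threshold(e, cfg$isodata_tolerance)
  vess <- e <= t
  if (mean(vess) > max_fraction)
    return(matrix(FALSE, nrow(vess), ncol(vess)))
  vess <- close_mask(vess, cfg$closing_se)
  remove_small_components(vess, cfg$min_component_size)
}

#' Circular Hough transform
#'
#' Votes in `(center_row, center_col, radius)` space: each edge pixel votes
#' for every circle center at distance `radius` from it, at 1 px resolution
#' in all three coordinates. Candidates are ranked by raw votes (ties broken
#' by smallest radius, then row-major center order) with greedy non-maximum
#' suppression of centers closer than half the larger radius.
#'
#' @param edges logical edge map.
#' @param radius_range numeric `c(min, max)` radius in pixels, min >= 3.
#' @param n_best number of hypotheses to return.
#' @param min_votes drop hypotheses with fewer raw votes.
#' @return data.frame with columns `center_row`, `center_col`, `radius`,
#'   `votes`, `vote_fraction` (votes over circle circumference in pixels),
#'   at most `n_best` rows, sorted by votes descending. Zero rows when no
#'   votes were cast.
#' @export
hough_circles <- function(edges, radius_range, n_best = 1L, min_votes = 1L) {
  if (length(radius_range) != 2 || radius_range[2] < radius_range[1])
    stop("empty radius range")
  edges <- as_mask(edges)
  H <- nrow(edges); W <- ncol(edges)
  ep <- which(edges, arr.ind = TRUE)
  radii <- seq(max(3L, floor(radius_range[1])), ceiling(radius_range[2]))
  empty <- data.frame(center_row = integer(), center_col = integer(),
                      radius = integer(), votes = integer(),
                      vote_fraction = numeric())
  if (nrow(ep) == 0 || length(radii) == 0) return(empty)

  acc <- array(0L, c(H, W, length(radii)))
  for (k in seq_along(radii)) {
    r <- radii[k]
    ang <- seq(0, 2 * pi, length.out = max(16L, ceiling(4 * pi * r)))
    off <- unique(cbind(round(r * sin(ang)), round(r * cos(ang))))
    cr <- rep(ep[, 1], times = nrow(off)) - rep(off[, 1], each = nrow(ep))
    cc <- rep(ep[, 2], times = nrow(off)) - rep(off[, 2], each = nrow(ep))
    ok <- cr >= 1 & cr <= H & cc >= 1 & cc <= W
    if (!any(ok)) next
    acc[, , k] <- acc[, , k] + matrix(
      tabulate((cc[ok] - 1L) * H + cr[ok], nbins = H * W), H, W)
  }

  found <- empty
  for (pick in seq_len(n_best)) {
    vmax <- max(acc)
    if (vmax < min_votes) break
    hits <- which(acc == vmax, arr.ind = TRUE)
    # ties: smallest radius, then row-major center order
    hits <- hits[order(hits[, 3], hits[, 1], hits[, 2]), , drop = FALSE]
    b <- hits[1, 1]; a <- hits[1, 2]; r <- radii[hits[1, 3]]
    found <- rbind(found, data.frame(
      center_row = b, center_col = a, radius = r, votes = vmax,
      vote_fraction = vmax / (2 * pi * r)))
    # suppress the neighborhood across all radii
    supp <- max(2, r / 2)
    rr <- pmax(1, b - ceiling(supp)):pmin(H, b + ceiling(supp))
    cc <- pmax(1, a - ceiling(supp)):pmin(W, a + ceiling(supp))
    acc[rr, cc, ] <- 0L
  }
  found
}

#' Gradient-magnitude edge map
#'
#' Central-difference gradient magnitude thresholded at the given quantile
#' of its positive values.
#'
#' @param img gray matrix.
#' @param quantile edge threshold quantile of positive gradient magnitudes.
#' @return logical edge map.
#' @export
edge_map <- function(img, quantile = 0.9) {
  gx <- (shift_matrix(img, 0, 1, fill = NA) - shift_matrix(img, 0, -1, fill = NA)) / 2
  gy <- (shift_matrix(img, 1, 0, fill = NA) - shift_matrix(img, -1, 0, fill = NA)) / 2
  g <- sqrt(ifelse(is.na(gx), 0, gx)^2 + ifelse(is.na(gy), 0, gy)^2)
  pos <- g[g > 0]
  if (!length(pos)) return(matrix(FALSE, nrow(img), ncol(img)))
  g >= max(stats::quantile(pos, quantile), 1e-9)
}

#' Optic-disc detection and extraction
#'
#' Pipeline: green channel -> CLAHE (plus min-max stretch when the dynamic
#' range is low) -> median filter -> gradient edge map -> circular Hough
#' transform over a plausible disc radius range -> disc mask as the filled
#' detected circle extended by bright pixels (Otsu threshold inside a
#' bounding box of 1.5 times the detected radius) and closed.
#'
#' @param img RGB fundus array.
#' @param radius_range disc radius search range; default
#'   `c(side / 20, side / 6)`.
#' @param min_vote_frac detection fails when the best hypothesis has fewer
#'   votes than this fraction of its circle circumference.
#' @param min_snr detection also fails when the best hypothesis' votes do
#'   not exceed `min_snr` times the coincidental-vote expectation (edge
#'   density times the circle's rasterized perimeter cells); this rejects
#'   the vote maxima that dense random edges produce by chance.
#' @param cfg a [clahe_config()] for enhancement.
#' @return list with `circle` (one-row data.frame from [hough_circles()]) and
#'   logical `mask`.
#' @export
detect_optic_disc <- function(img, radius_range = NULL, min_vote_frac = 0.35,
                              min_snr = 2.8, cfg = clahe_config()) {
  side <- min(dim(img)[1:2])
  if (is.null(radius_range)) radius_range <- c(side / 20, side / 6)
  g <- extract_green(img)
  e <- clahe(g, cfg)
  if (diff(range(e)) < 0.75 * (cfg$gray_levels - 1))
    e <- stretch_contrast(e, cfg$gray_levels)
  e <- median_filter(e, c(3L, 3L))
  edges <- edge_map(e, 0.9)
  hyp <- hough_circles(edges, radius_range, n_best = 1L)
  snr <- if (nrow(hyp)) hyp$votes[1] /
    (mean(edges) * 1.42 * 2 * pi * hyp$radius[1]) else 0
  if (nrow(hyp) == 0 || hyp$vote_fraction[1] < min_vote_frac || snr < min_snr)
    stop("detection failure: no circular structure above the vote threshold")
  b <- hyp$center_row[1]; a <- hyp$center_col[1]; r <- hyp$radius[1]
  H <- nrow(g); W <- ncol(g)
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((rr - b)^2 + (cc - a)^2)
  circle <- d <= r
  # refine: bright pixels (Otsu inside a 1.5 r bounding box) near the circle
  box_r <- pmax(1, b - round(1.5 * r)):pmin(H, b + round(1.5 * r))
  box_c <- pmax(1, a - round(1.5 * r)):pmin(W, a + round(1.5 * r))
  box <- g[box_r, box_c]
  mask <- circle
  if (diff(range(box)) > 0) {
    ot <- otsu_threshold(gray_histogram(box))
    bright <- g > ot$threshold & d <= 1.3 * r
    mask <- close_mask(circle | bright, struct_el(matrix(1, 5, 5)))
  }
  list(circle = hyp[1, ], mask = mask)
}

#' Replace pixels under a mask
#'
#' `background-mean` fills masked pixels with the mean of the unmasked
#' pixels; `neighborhood-mean` fills each masked pixel with the mean of the
#' unmasked pixels in a surrounding window (falling back to the background
#' mean where the window holds none). Unmasked pixels are returned unchanged.
#'
#' @param img gray matrix.
#' @param mask logical matrix of the same dimensions.
#' @param fill `"background-mean"` or `"neighborhood-mean"`.
#' @param window odd window side for the neighborhood strategy.
#' @return gray matrix.
#' @export
remove_region <- function(img, mask,
                          fill = c("background-mean", "neighborhood-mean"),
                          window = 7L) {
  fill <- match.arg(fill)
  mask <- as_mask(mask)
  if (!all(dim(mask) == dim(img))) stop("mask dimensions must match image")
  if (!any(mask)) return(img)
  out <- img
  bg <- if (all(mask)) mean(img) else mean(img[!mask])
  if (fill == "background-mean") {
    out[mask] <- round_half_up(bg)
    return(out)
  }
  keep <- 1 - mask
  num <- box_mean(img * keep, window) * window^2
  den <- box_mean(keep, window) * window^2
  val <- ifelse(den > 0.5, num / pmax(den, 0.5), bg)
  out[mask] <- round_half_up(val[mask])
  out
}

#' Exudate localization
#'
#' Pipeline: green channel -> illumination correction + median filter ->
#' optic-disc removal (background-mean fill) -> vessel removal
#' (neighborhood-mean fill) -> Otsu threshold, bright class as candidates ->
#' opening -> exclusion of disc pixels. Exudates are small high-contrast
#' deposits, so candidates are rejected wholesale when the bright class is
#' large (over `max_bright_fraction` of the image) or the Otsu class means
#' are separated by less than `min_contrast` intensity units; both guards
#' reject the near-unimodal histograms of lesion-free images.
#'
#' @param img RGB fundus array.
#' @param disc_mask logical optic-disc mask.
#' @param vessel_mask logical vessel mask.
#' @param opening_se structuring element for the opening step.
#' @param max_bright_fraction,min_contrast plausibility guards (see above).
#' @return logical exudate candidate mask, disjoint from `disc_mask`.
#' @export
detect_exudates <- function(img, disc_mask, vessel_mask,
                            opening_se = struct_el(),
                            max_bright_fraction = 0.05, min_contrast = 25) {
  g <- extract_green(img)
  if (!all(dim(disc_mask) == dim(g)) || !all(dim(vessel_mask) == dim(g)))
    stop("mask dimensions must match image")
  e <- correct_illumination(g, window_side = 31L)
  e <- median_filter(e, c(3L, 3L))
  e <- remove_region(e, as_mask(disc_mask), "background-mean")
  e <- remove_region(e, as_mask(vessel_mask), "neighborhood-mean")
  ot <- otsu_threshold(gray_histogram(e))
  cand <- e > ot$threshold
  if (mean(cand) > max_bright_fraction || (ot$m2 - ot$m1) < min_contrast)
    return(matrix(FALSE, nrow(g), ncol(g)))
  cand <- open_mask(cand, opening_se)
  cand & !as_mask(disc_mask)
}
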