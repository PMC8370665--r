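#' Image enhancement operators for fundus photographs
#'
#' The enhancement stage works on the green channel, where the contrast
#' between the vessel network and the retinal background is highest, and
#' applies contrast-limited adaptive histogram equalization (CLAHE),
#' window-mean illumination correction, min-max contrast stretching and
#' median filtering. All operators quantize with round-half-up and keep
#' values in `[0, gray_levels - 1]`.
#'
#' @name enhancement
NULL

#' Extract the green channel of an RGB image
#'
#' @param img H x W x 3 array, 8-bit values.
#' @return H x W numeric matrix (gray levels 0-255).
#' @export
extract_green <- function(img) {
  if (!is_rgb_image(img)) stop("extract_green expects an H x W x 3 RGB array")
  img[, , 2]
}

#' CLAHE configuration
#'
#' @param tile_rows,tile_cols tile size in pixels (>= 2 each).
#' @param gray_levels number of gray levels/histogram bins (>= 2).
#' @param clip_factor dimensionless clip factor (>= 1); the histogram of each
#'   tile is clipped at `clip_factor` times the average bin count.
#' @return object of class `clahe_config`.
#' @export
clahe_config <- function(tile_rows = 32L, tile_cols = 32L,
                         gray_levels = 256L, clip_factor = 2) {
  if (tile_rows < 2 || tile_cols < 2) stop("tile dimensions must be >= 2")
  if (gray_levels < 2) stop("gray_levels must be >= 2")
  if (clip_factor < 1) stop("clip_factor must be >= 1")
  structure(list(tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols),
                 gray_levels = as.integer(gray_levels),
                 clip_factor = clip_factor), class = "clahe_config")
}

#' CLAHE clip limit
#'
#' The average bin count of a tile histogram is
#' `n_avg = tile_rows * tile_cols / gray_levels` and the actual clip limit is
#' `n_cl = clip_factor * n_avg`.
#'
#' @param cfg a [clahe_config()].
#' @return list with `n_avg` and `n_cl` (both real, > 0).
#' @export
clahe_clip_limit <- function(cfg) {
  stopifnot(inherits(cfg, "clahe_config"))
  n_avg <- cfg$tile_rows * cfg$tile_cols / cfg$gray_levels
  list(n_avg = n_avg, n_cl = cfg$clip_factor * n_avg)
}

# per-tile clipped-histogram equalization mappings
# returns list(maps = array [tr, tc, G] of output levels, tr, tc, pad dims)
clahe_maps <- function(img, cfg) {
  G <- cfg$gray_levels
  th <- cfg$tile_rows; tw <- cfg$tile_cols
  H <- nrow(img); W <- ncol(img)
  if (th > H || tw > W) stop("tile larger than image")
  tr <- ceiling(H / th); tc <- ceiling(W / tw)
  p <- pad_replicate(img, 0, tr * th - H, 0, tc * tw - W)
  n_cl <- clahe_clip_limit(cfg)$n_cl
  maps <- array(0, c(tr, tc, G))
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    tile <- p[((i - 1) * th + 1):(i * th), ((j - 1) * tw + 1):(j * tw)]
    counts <- tabulate(as.integer(tile) + 1L, nbins = G)
    excess <- sum(pmax(counts - n_cl, 0))
    counts <- pmin(counts, n_cl) + excess / G  # one-pass uniform redistribution
    cdf <- cumsum(counts) / sum(counts)
    maps[i, j, ] <- round_half_up((G - 1) * cdf)
  }
  list(maps = maps, tr = tr, tc = tc, th = th, tw = tw, padded = p)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile histograms are clipped at the [clahe_clip_limit()], the clipped mass
#' is redistributed uniformly over all bins in one pass, and each tile's
#' equalization mapping is derived from the resulting CDF. With
#' `interpolate = TRUE` (default) every pixel blends the mappings of the four
#' surrounding tile centers bilinearly; with `FALSE` each pixel uses its own
#' tile's mapping (useful for oracle comparisons).
#'
#' @param img gray matrix with integer values in `[0, gray_levels - 1]`.
#' @param cfg a [clahe_config()].
#' @param interpolate logical; bilinear stitching of tile mappings.
#' @return enhanced gray matrix, same dimensions, values in
#'   `[0, gray_levels - 1]`.
#' @export
clahe <- function(img, cfg = clahe_config(), interpolate = TRUE) {
  mp <- clahe_maps(img, cfg)
  G <- cfg$gray_levels
  H <- nrow(img); W <- ncol(img)
  v <- as.integer(img)  # column-major values of the original image
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  ti <- pmin(ceiling(rr / mp$th), mp$tr)
  tj <- pmin(ceiling(cc / mp$tw), mp$tc)
  if (!interpolate) {
    out <- mp$maps[cbind(ti, tj, v + 1L)]
    return(matrix(out, H, W))
  }
  gy <- (rr - (mp$th + 1) / 2) / mp$th + 1  # fractional tile-center coords
  gx <- (cc - (mp$tw + 1) / 2) / mp$tw + 1
  i0 <- clamp(floor(gy), 1, mp$tr); i1 <- clamp(i0 + 1, 1, mp$tr)
  j0 <- clamp(floor(gx), 1, mp$tc); j1 <- clamp(j0 + 1, 1, mp$tc)
  wy <- clamp(gy - floor(gy), 0, 1); wx <- clamp(gx - floor(gx), 0, 1)
  out <- mp$maps[cbind(i0, j0, v + 1L)] * (1 - wy) * (1 - wx) +
    mp$maps[cbind(i1, j0, v + 1L)] * wy * (1 - wx) +
    mp$maps[cbind(i0, j1, v + 1L)] * (1 - wy) * wx +
    mp$maps[cbind(i1, j1, v + 1L)] * wy * wx
  matrix(clamp(round_half_up(out), 0, G - 1), H, W)
}

#' Window-mean illumination correction
#'
#' Each pixel becomes `p' = p + desired_mean - local_mean`, where the local
#' mean is taken over an odd square window with edge replication at the
#' borders, then rounded and clamped. With `desired_mean` equal to the local
#' mean field's average this flattens slow illumination gradients while
#' preserving local structure such as vessels and microaneurysms.
#'
#' @param img gray matrix.
#' @param desired_mean target mean intensity; default the image's own mean.
#' @param window_side odd window side >= 3.
#' @param gray_levels number of gray levels (clamp bound).
#' @return corrected gray matrix.
#' @export
correct_illumination <- function(img, desired_mean = mean(img),
                                 window_side = 31L, gray_levels = 256L) {
  if (window_side %% 2 == 0 || window_side < 3)
    stop("window_side must be odd and >= 3")
  mu_l <- box_mean(img, window_side)
  clamp(round_half_up(img + desired_mean - mu_l), 0, gray_levels - 1)
}

#' Min-max contrast stretch
#'
#' Affine map sending the input minimum to 0 and the input maximum to
#' `gray_levels - 1`, with round-half-up quantization.
#'
#' @param img gray matrix with at least two distinct values.
#' @param gray_levels output gray-level count.
#' @return stretched gray matrix.
#' @export
stretch_contrast <- function(img, gray_levels = 256L) {
  lo <- min(img); hi <- max(img)
  if (hi == lo) stop_degenerate("constant image: contrast stretch undefined")
  round_half_up((img - lo) / (hi - lo) * (gray_levels - 1))
}

#' Median filter
#'
#' Replaces each pixel with the median of its odd `rows x cols` window; the
#' borders use edge replication so output dimensions equal input dimensions.
#'
#' @param img gray matrix.
#' @param window integer vector `c(rows, cols)`, both odd.
#' @return filtered gray matrix.
#' @export
median_filter <- function(img, window = c(3L, 3L)) {
  kr <- window[1]; kc <- window[2]
  if (any(c(kr, kc) %% 2 == 0) || any(c(kr, kc) < 1))
    stop("window dimensions must be odd and >= 1")
  hr <- (kr - 1L) / 2L; hc <- (kc - 1L) / 2L
  p <- pad_replicate(img, hr, hr, hc, hc)
  H <- nrow(img); W <- ncol(img)
  k <- kr * kc
  stack <- matrix(0, H * W, k)
  m <- 0L
  for (dc in -hc:hc) for (dr in -hr:hr) {
    m <- m + 1L
    stack[, m] <- as.vector(p[(1 + hr + dr):(H + hr + dr),
                              (1 + hc + dc):(W + hc + dc)])
  }
  h <- (k + 1L) / 2L
  med <- apply(stack, 1L, function(r) sort.int(r, partial = h)[h])
  matrix(med, H, W)
}

#' Full enhancement chain for a fundus image
#'
#' green channel -> CLAHE -> illumination correction; optional min-max
#' stretch when the dynamic range is low.
#'
#' @param img RGB fundus array.
#' @param cfg a [clahe_config()].
#' @param illum_window odd window for illumination correction.
#' @param stretch_if_range_below apply [stretch_contrast()] when the value
#'   range of the corrected image is below this many levels.
#' @return enhanced gray matrix.
#' @export
enhance_fundus <- function(img, cfg = clahe_config(),
                           illum_window = 31L, stretch_if_range_below = 0) {
  g <- extract_green(img)
  e <- clahe(g, cfg)
  e <- correct_illumination(e, window_side = illum_window,
                            gray_levels = cfg$gray_levels)
  if (diff(range(e)) < stretch_if_range_below)
    e <- stretch_contrast(e, cfg$gray_levels)
  e
}
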