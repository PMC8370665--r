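#' Synthetic fundus image generation
#'
#' Emulates the gross structure of a color fundus photograph at toy scale:
#' an orange-red background with a linear illumination ramp and Gaussian
#' pixel noise, a bright roughly circular optic disc, a dark recursively
#' branching vessel network radiating from the disc, and — depending on the
#' class label — bright exudate blobs near the macula (mild diabetic macular
#' edema), small dark microaneurysm dots on the vessels (mild diabetic
#' retinopathy), or an enlarged disc (mild glaucoma). Every image carries
#' pixel-level ground-truth masks so each downstream stage can be scored
#' without any dataset download.
#'
#' @name synthetic_fundus
NULL

#' Class labels understood by the generator
#' @export
ded_classes <- function() c("normal", "mild_dr", "mild_dme", "mild_gl")

#' Configuration for the synthetic fundus generator
#'
#' Defaults describe a 128 px image whose proportions (disc of roughly a
#' tenth of the image side, 2-4 px vessels) mirror a downsampled macula-
#' centered fundus photograph.
#'
#' @param image_side image side in pixels (square image), >= 64.
#' @param disc_radius_range optic-disc radius range in pixels; default
#'   9-12% of the image side, the proportion of a macula-centered view.
#' @param vessel_branches number of primary vessel branches leaving the disc.
#' @param vessel_width_range vessel stroke width range in pixels.
#' @param exudate_count_range number of exudate blobs for `mild_dme` images.
#' @param microaneurysm_count_range number of dark dots for `mild_dr` images.
#' @param illumination_gradient_amplitude peak-to-peak amplitude (intensity
#'   units, 0-255 scale) of the linear illumination ramp.
#' @param noise_sd standard deviation of per-pixel Gaussian noise.
#' @param seed integer seed; identical config + label gives identical output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(image_side = 128L,
                         disc_radius_range = round(c(0.09, 0.12) * image_side),
                         vessel_branches = 6L,
                         vessel_width_range = c(2, 4),
                         exudate_count_range = c(2, 4),
                         microaneurysm_count_range = c(3, 6),
                         illumination_gradient_amplitude = 20,
                         noise_sd = 3,
                         seed = 1L) {
  ranges <- list(disc_radius_range = disc_radius_range,
                 vessel_width_range = vessel_width_range,
                 exudate_count_range = exudate_count_range,
                 microaneurysm_count_range = microaneurysm_count_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r < 0) || r[2] < r[1])
      stop("configuration error: ", nm, " must be a non-empty non-negative range")
  }
  if (image_side < 64) stop("configuration error: image_side must be >= 64")
  if (disc_radius_range[2] * 2 >= image_side)
    stop("configuration error: disc cannot fit inside the image")
  structure(list(
    image_side = as.integer(image_side),
    disc_radius_range = disc_radius_range,
    vessel_branches = as.integer(vessel_branches),
    vessel_width_range = vessel_width_range,
    exudate_count_range = exudate_count_range,
    microaneurysm_count_range = microaneurysm_count_range,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# reference colors (R, G, B) on the 0-255 scale
.synth_colors <- list(
  background = c(190, 110, 55),
  disc       = c(250, 228, 185),
  vessel     = c(120, 40, 28),
  exudate    = c(252, 240, 150),
  ma         = c(90, 25, 20)
)

# draw a polyline of given width into a logical mask (dense point sampling)
draw_stroke <- function(mask, p0, p1, width) {
  n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) * 2))
  t <- seq(0, 1, length.out = n)
  pr <- p0[1] + t * (p1[1] - p0[1])
  pc <- p0[2] + t * (p1[2] - p0[2])
  rad <- width / 2
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(n)) {
    r0 <- max(1L, floor(pr[i] - rad)); r1 <- min(H, ceiling(pr[i] + rad))
    c0 <- max(1L, floor(pc[i] - rad)); c1 <- min(W, ceiling(pc[i] + rad))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - pr[i])^2, (cc - pc[i])^2, "+")
    mask[rr, cc] <- mask[rr, cc] | (d2 <= rad^2)
  }
  mask
}

# recursive branching vessel tree; returns list(mask, points on centerlines)
draw_vessel_tree <- function(side, origin, n_branches, width_range) {
  mask <- matrix(FALSE, side, side)
  pts <- list()
  grow <- function(p, angle, len, width, depth) {
    if (depth > 3 || len < 4 || width < 1) return()
    q <- p + len * c(sin(angle), cos(angle))
    q <- clamp(q, 3, side - 2)
    mask <<- draw_stroke(mask, p, q, width)
    pts[[length(pts) + 1L]] <<- (p + q) / 2
    # two children with diverging angles and tapering width
    a1 <- angle + stats::runif(1, 0.25, 0.7)
    a2 <- angle - stats::runif(1, 0.25, 0.7)
    grow(q, a1, len * stats::runif(1, 0.6, 0.85), width * 0.75, depth + 1)
    grow(q, a2, len * stats::runif(1, 0.6, 0.85), width * 0.75, depth + 1)
  }
  for (b in seq_len(n_branches)) {
    angle <- 2 * pi * (b - 0.5) / n_branches + stats::runif(1, -0.3, 0.3)
    w <- stats::runif(1, width_range[1], width_range[2])
    grow(origin, angle, side * stats::runif(1, 0.2, 0.3), w, 1)
  }
  list(mask = mask, points = pts)
}

#' Generate one labeled synthetic fundus image with ground truth
#'
#' Deterministic in `(config, label)`: repeated calls are byte-identical.
#'
#' @param config a [synth_config()].
#' @param label one of [ded_classes()].
#' @return list with `image` (H x W x 3 numeric array, integer values 0-255)
#'   and `truth`, a list holding `disc_center` (row, col), `disc_radius`,
#'   logical `vessel_mask`, `exudate_mask`, `microaneurysm_mask`, and `label`.
#' @export
generate_fundus <- function(config, label) {
  if (!inherits(config, "synth_config")) stop("config must be a synth_config")
  if (!label %in% ded_classes())
    stop("invalid label '", label, "'; must be one of ",
         paste(ded_classes(), collapse = ", "))
  with_seed(derive_seed(config$seed, "image", label), {
    generate_fundus_impl(config, label)
  })
}

generate_fundus_impl <- function(config, label) {
  side <- config$image_side
  col <- .synth_colors
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)

  # disc geometry: kept fully inside the image, off-center like a
  # macula-centered photograph; glaucoma presents as an enlarged disc
  rad <- stats::runif(1, config$disc_radius_range[1], config$disc_radius_range[2])
  if (label == "mild_gl") rad <- min(rad * 1.3, side / 5)
  margin <- ceiling(rad) + 4
  dc_row <- round(stats::runif(1, side * 0.35, side * 0.65))
  col_lo <- margin + side * 0.02
  dc_col <- round(stats::runif(1, col_lo, max(side * 0.35, col_lo)))
  dc_row <- clamp(dc_row, margin, side - margin)
  dc_col <- clamp(dc_col, margin, side - margin)
  d_disc <- sqrt((rr - dc_row)^2 + (cc - dc_col)^2)
  disc_alpha <- clamp((rad + 1 - d_disc) / 2, 0, 1)  # ~2 px soft rim

  vt <- draw_vessel_tree(side, c(dc_row, dc_col), config$vessel_branches,
                         config$vessel_width_range)
  vessel_mask <- vt$mask

  exudate_mask <- matrix(FALSE, side, side)
  ex_alpha <- matrix(0, side, side)
  if (label == "mild_dme") {
    n_ex <- if (config$exudate_count_range[1] == config$exudate_count_range[2])
      config$exudate_count_range[1]
    else sample(config$exudate_count_range[1]:config$exudate_count_range[2], 1)
    n_ex <- max(1L, n_ex)  # label consistency: >= 1 exudate component
    centers <- matrix(0, 0, 2)
    tries <- 0
    sep <- max(7, 0.11 * side)           # blob separation scales with the field
    disc_clear <- rad + max(6, 0.09 * side)
    while (nrow(centers) < n_ex && tries < 400) {
      tries <- tries + 1
      # macular side of the image (away from the disc), inside the field
      p <- c(stats::runif(1, side * 0.2, side * 0.8),
             stats::runif(1, side * 0.45, side * 0.9))
      if (sqrt(sum((p - c(dc_row, dc_col))^2)) < disc_clear) next
      if (nrow(centers) && min(sqrt(rowSums(sweep(centers, 2, p)^2))) < sep) next
      pr <- round(p)
      nb <- vessel_mask[max(1, pr[1] - 5):min(side, pr[1] + 5),
                        max(1, pr[2] - 5):min(side, pr[2] + 5)]
      if (any(nb)) next  # keep blobs off the vessel tree
      centers <- rbind(centers, p)
    }
    if (nrow(centers) < n_ex)
      stop("configuration error: could not place ", n_ex, " exudates")
    for (i in seq_len(n_ex)) {
      sig <- stats::runif(1, 2.2, 3.2)
      d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
      a <- exp(-d2 / (2 * sig^2))
      ex_alpha <- pmax(ex_alpha, a)
      exudate_mask <- exudate_mask | (a >= 0.5)
    }
  }

  ma_mask <- matrix(FALSE, side, side)
  if (label == "mild_dr") {
    n_ma <- if (config$microaneurysm_count_range[1] == config$microaneurysm_count_range[2])
      config$microaneurysm_count_range[1]
    else sample(config$microaneurysm_count_range[1]:config$microaneurysm_count_range[2], 1)
    anchors <- vt$points
    for (i in seq_len(max(0L, n_ma))) {
      a <- anchors[[sample(length(anchors), 1)]] + stats::runif(2, -3, 3)
      a <- round(clamp(a, 2, side - 1))
      sz <- sample(1:2, 1)
      ma_mask[a[1]:min(side, a[1] + sz - 1), a[2]:min(side, a[2] + sz - 1)] <- TRUE
    }
  }

  # compose channels: background + ramp, disc, then vessels over the disc
  # (as in a real photograph), lesions, and finally sensor noise
  ramp <- config$illumination_gradient_amplitude * (cc / side - 0.5)
  noise <- array(stats::rnorm(side * side * 3, 0, config$noise_sd),
                 c(side, side, 3))
  img <- array(0, c(side, side, 3))
  for (ch in 1:3) {
    base <- matrix(col$background[ch], side, side)
    base <- base * (1 - disc_alpha) + col$disc[ch] * disc_alpha
    base[vessel_mask] <- col$vessel[ch]
    base[ma_mask] <- col$ma[ch]
    base <- base * (1 - ex_alpha) + col$exudate[ch] * ex_alpha
    base <- base + ramp + noise[, , ch]
    img[, , ch] <- clamp(round_half_up(base), 0, 255)
  }

  truth <- list(disc_center = c(row = dc_row, col = dc_col), disc_radius = rad,
                vessel_mask = vessel_mask, exudate_mask = exudate_mask,
                microaneurysm_mask = ma_mask, label = label)
  list(image = img, truth = truth)
}

#' Generate a balanced labeled dataset
#'
#' @param config a [synth_config()].
#' @param n_per_class images per class (>= 1).
#' @param classes character vector of class tags, subset of [ded_classes()].
#' @return list of `generate_fundus()` results; attribute `labels` holds the
#'   label sequence.
#' @export
generate_dataset <- function(config, n_per_class,
                             classes = c("normal", "mild_dme")) {
  if (length(classes) == 0) stop("empty class list")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (!all(classes %in% ded_classes())) stop("unknown class tag")
  out <- vector("list", n_per_class * length(classes))
  labels <- character(length(out))
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      cfg_i <- config
      cfg_i$seed <- derive_seed(config$seed, "dataset", cl, i)
      out[[k]] <- generate_fundus(cfg_i, cl)
      labels[k] <- cl
    }
  }
  attr(out, "labels") <- labels
  out
}
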