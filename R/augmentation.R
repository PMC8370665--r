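#' Seeded geometric augmentation
#'
#' Streaming per-epoch transforms (horizontal/vertical flip, rotation,
#' random crop resized back to the input size) that never enlarge the stored
#' dataset: each epoch yields exactly one transformed variant per input
#' image, and the same seed reproduces the same stream. "Mirror" is treated
#' as a synonym of horizontal flip.
#'
#' @name augmentation
NULL

#' Augmentation configuration
#'
#' @param allow_horizontal_flip,allow_vertical_flip enable the flips (each
#'   applied with probability 1/2 when enabled).
#' @param rotation_range maximal absolute rotation in degrees (>= 0); angles
#'   are drawn uniformly from `[-rotation_range, rotation_range]`.
#' @param crop_fraction side fraction in `(0, 1]` of the random crop, which
#'   is resized back to the input size; 1 disables cropping.
#' @param seed integer stream seed.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(allow_horizontal_flip = TRUE,
                           allow_vertical_flip = FALSE,
                           rotation_range = 0,
                           crop_fraction = 1,
                           seed = 1L) {
  if (rotation_range < 0) stop("rotation_range must be >= 0")
  if (crop_fraction <= 0 || crop_fraction > 1)
    stop("invalid crop fraction: must be in (0, 1]")
  structure(list(allow_horizontal_flip = allow_horizontal_flip,
                 allow_vertical_flip = allow_vertical_flip,
                 rotation_range = rotation_range,
                 crop_fraction = crop_fraction,
                 seed = as.integer(seed)), class = "augment_config")
}

# one transform descriptor drawn from the current RNG stream
draw_one_transform <- function(cfg) {
  list(
    hflip = cfg$allow_horizontal_flip && stats::runif(1) < 0.5,
    vflip = cfg$allow_vertical_flip && stats::runif(1) < 0.5,
    angle = if (cfg$rotation_range > 0)
      stats::runif(1, -cfg$rotation_range, cfg$rotation_range) else 0,
    crop = if (cfg$crop_fraction < 1)
      c(row = stats::runif(1), col = stats::runif(1),
        frac = cfg$crop_fraction) else NULL
  )
}

#' Create a per-epoch augmentation stream
#'
#' @param cfg an [augment_config()].
#' @return function `(images, epoch)` returning a list of transformed images
#'   (same length and order as the input; labels are untouched by design).
#'   The descriptor stream is a pure function of `(cfg$seed, epoch)`.
#' @export
make_augmenter <- function(cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  function(images, epoch = 1L) {
    ds <- draw_transforms(cfg, length(images), epoch)
    lapply(seq_along(images), function(i) apply_transform(images[[i]], ds[[i]]))
  }
}

#' Draw the transform descriptors for one epoch
#'
#' @param cfg an [augment_config()].
#' @param n number of descriptors (one per image).
#' @param epoch epoch index (descriptors differ between epochs but are
#'   reproducible for a given seed and epoch).
#' @return list of `n` descriptors.
#' @export
draw_transforms <- function(cfg, n, epoch = 1L) {
  with_seed(derive_seed(cfg$seed, "augment", epoch),
            lapply(seq_len(n), function(i) draw_one_transform(cfg)))
}

# rotate one gray matrix about its center by `angle` degrees, bilinear
# resampling with edge replication
rotate_matrix <- function(m, angle) {
  th <- angle * pi / 180
  H <- nrow(m); W <- ncol(m)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  # inverse mapping: source position of each output pixel
  sr <- cr + cos(th) * (g$r - cr) - sin(th) * (g$c - cc)
  sc <- cc + sin(th) * (g$r - cr) + cos(th) * (g$c - cc)
  matrix(bilinear_sample(m, sr, sc), H, W)
}

#' Apply one transform descriptor to an image
#'
#' Order: flips, rotation, crop (resized back to the input size). Flips and
#' rotations by multiples of 90 degrees permute pixels exactly; other angles
#' and crops use bilinear resampling with edge replication, re-quantized
#' with round-half-up.
#'
#' @param img gray matrix or H x W x 3 array, 0-255 values.
#' @param descriptor a descriptor from [draw_transforms()]; may also be built
#'   manually as `list(hflip =, vflip =, angle =, crop =)`.
#' @return transformed image, same type and dimensions as the input.
#' @export
apply_transform <- function(img, descriptor) {
  d <- descriptor
  ok <- is.list(d) && all(c("hflip", "vflip", "angle") %in% names(d))
  if (!ok) stop("invalid transform descriptor")
  one <- function(m) {
    if (isTRUE(d$hflip)) m <- m[, ncol(m):1, drop = FALSE]
    if (isTRUE(d$vflip)) m <- m[nrow(m):1, , drop = FALSE]
    a <- d$angle %% 360
    if (a != 0) {
      if (a %% 90 == 0) {
        for (q in seq_len(a / 90)) m <- t(m[nrow(m):1, , drop = FALSE])
      } else {
        m <- clamp(round_half_up(rotate_matrix(m, d$angle)), 0, 255)
      }
    }
    if (!is.null(d$crop)) {
      H <- nrow(m); W <- ncol(m)
      ch <- max(1L, round(d$crop[["frac"]] * H))
      cw <- max(1L, round(d$crop[["frac"]] * W))
      r0 <- 1L + floor(d$crop[["row"]] * (H - ch))
      c0 <- 1L + floor(d$crop[["col"]] * (W - cw))
      m <- m[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
      m <- clamp(round_half_up(resize_bilinear(m, H, W)), 0, 255)
    }
    m
  }
  if (is.matrix(img)) return(one(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- one(img[, , ch])
  out
}
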