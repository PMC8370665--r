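# Independent brute-force oracles used to check the pixel operators.
# These re-derive each definition directly and share no code with the
# implementations they verify.

# erosion straight from the set definition: SE must fit inside the foreground
brute_erode <- function(mask, se) {
  off <- which(se$pattern, arr.ind = TRUE)
  off[, 1] <- off[, 1] - se$origin[1]
  off[, 2] <- off[, 2] - se$origin[2]
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    ok <- TRUE
    for (i in seq_len(nrow(off))) {
      rr <- r + off[i, 1]; cc <- c + off[i, 2]
      if (rr < 1 || rr > H || cc < 1 || cc > W || !mask[rr, cc]) { ok <- FALSE; break }
    }
    out[r, c] <- ok
  }
  out
}

# dilation: reflected SE translated there must intersect the foreground
brute_dilate <- function(mask, se) {
  off <- which(se$pattern, arr.ind = TRUE)
  off[, 1] <- off[, 1] - se$origin[1]
  off[, 2] <- off[, 2] - se$origin[2]
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    hit <- FALSE
    for (i in seq_len(nrow(off))) {
      rr <- r - off[i, 1]; cc <- c - off[i, 2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]) { hit <- TRUE; break }
    }
    out[r, c] <- hit
  }
  out
}

# median filter by explicit window sort, edge replication
brute_median <- function(img, kr, kc) {
  H <- nrow(img); W <- ncol(img)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    win <- numeric(0)
    for (dr in -hr:hr) for (dc in -hc:hc) {
      rr <- min(max(r + dr, 1), H); cc <- min(max(c + dc, 1), W)
      win <- c(win, img[rr, cc])
    }
    s <- sort(win)
    out[r, c] <- s[(length(s) + 1) / 2]
  }
  out
}

# Otsu by definition: exhaustive scan of between-class variance
brute_otsu <- function(counts) {
  L <- length(counts)
  p <- counts / sum(counts)
  v <- 0:(L - 1)
  mT <- sum(v * p)
  best_t <- NA; best_bcv <- -Inf
  curves <- rep(NA_real_, L - 1)
  for (t in 1:(L - 1)) {
    w1 <- sum(p[1:t]); w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0) next
    m1 <- sum(v[1:t] * p[1:t]) / w1
    m2 <- sum(v[(t + 1):L] * p[(t + 1):L]) / w2
    bcv <- w1 * (m1 - mT)^2 + w2 * (m2 - mT)^2
    curves[t] <- bcv
    if (bcv > best_bcv) { best_bcv <- bcv; best_t <- t }
  }
  list(t_index = best_t, bcv = best_bcv, curve = curves)
}

# ISODATA by dense fixed-point search over a threshold grid
brute_isodata <- function(v, grid = NULL) {
  if (is.null(grid)) grid <- seq(min(v) + 1e-6, max(v) - 1e-6, length.out = 2000)
  f <- vapply(grid, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(Inf)
    abs((mean(lo) + mean(hi)) / 2 - t)
  }, 0)
  grid[which.min(f)]
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# filled circle mask
disc_mask_of <- function(side, center, radius) {
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2) <= radius
}

# rasterized circle perimeter (the convention the CHT votes with)
raster_circle <- function(side, center, radius) {
  ang <- seq(0, 2 * pi, length.out = max(16, ceiling(4 * pi * radius)))
  pts <- unique(cbind(round(center[1] + radius * sin(ang)),
                      round(center[2] + radius * cos(ang))))
  pts <- pts[pts[, 1] >= 1 & pts[, 1] <= side & pts[, 2] >= 1 & pts[, 2] <= side, , drop = FALSE]
  m <- matrix(FALSE, side, side)
  m[pts] <- TRUE
  m
}

random_mask <- function(side, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(runif(side * side) < p, side, side)
}

# one cached fundus per label so the segmentation tests don't regenerate
fundus_cache <- new.env(parent = emptyenv())
cached_fundus <- function(label, seed = 11, ...) {
  key <- paste(label, seed, ...)
  if (is.null(fundus_cache[[key]])) {
    cfg <- synth_config(seed = seed, ...)
    fundus_cache[[key]] <- generate_fundus(cfg, label)
  }
  fundus_cache[[key]]
}
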