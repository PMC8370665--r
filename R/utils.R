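#' @keywords internal
"_PACKAGE"

#' Round half away from zero (half-up for non-negative values)
#'
#' All enhancement stages quantize back to integer gray levels with
#' round-half-up, so 127.5 -> 128 regardless of the platform's banker's
#' rounding.
#'
#' @param x numeric vector/matrix.
#' @return same shape as `x`, integer-valued numeric.
#' @export
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derive a well-spread child seed from a base seed and stream labels
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  })))
  s <- 0
  for (p in parts) s <- (s * 7919 + (as.numeric(p) %% 104729)) %% 2147483647
  as.integer(max(1, s))
}

# Pad a matrix by edge replication
pad_replicate <- function(m, top, bottom = top, left = top, right = left) {
  ri <- c(rep(1L, top), seq_len(nrow(m)), rep(nrow(m), bottom))
  ci <- c(rep(1L, left), seq_len(ncol(m)), rep(ncol(m), right))
  m[ri, ci, drop = FALSE]
}

# Sliding-window mean with edge replication, k odd
box_mean <- function(m, k) {
  stopifnot(k %% 2 == 1)
  h <- (k - 1L) / 2L
  p <- pad_replicate(m, h)
  cs <- apply(p, 2L, cumsum)      # cumulative down rows
  cs <- t(apply(cs, 1L, cumsum))  # then across columns
  ii <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  ii[-1L, -1L] <- cs
  r1 <- seq_len(nrow(m)); c1 <- seq_len(ncol(m))
  s <- ii[r1 + k, c1 + k, drop = FALSE] - ii[r1, c1 + k, drop = FALSE] -
    ii[r1 + k, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  s / (k * k)
}

# Shift a matrix by (dr, dc): out[r, c] = m[r + dr, c + dc], out-of-bounds -> fill
shift_matrix <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  r_src <- intersect(seq_len(H) + dr, seq_len(H))
  c_src <- intersect(seq_len(W) + dc, seq_len(W))
  if (length(r_src) && length(c_src))
    out[r_src - dr, c_src - dc] <- m[r_src, c_src]
  out
}

# Bilinear sampling of matrix `m` at fractional (row, col) positions with
# edge replication outside the domain.
bilinear_sample <- function(m, rr, cc) {
  H <- nrow(m); W <- ncol(m)
  rr <- clamp(rr, 1, H); cc <- clamp(cc, 1, W)
  r0 <- clamp(floor(rr), 1, H); r1 <- clamp(r0 + 1, 1, H)
  c0 <- clamp(floor(cc), 1, W); c1 <- clamp(c0 + 1, 1, W)
  fr <- rr - r0; fc <- cc - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc + m[cbind(r1, c1)] * fr * fc
}

#' Bilinear resize of a grayscale matrix or RGB array
#'
#' @param img matrix (H x W) or array (H x W x C).
#' @param out_h,out_w output dimensions in pixels.
#' @return resized image of the same kind, values not re-quantized.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  one <- function(m) {
    H <- nrow(m); W <- ncol(m)
    rr <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
    cc <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
    g <- expand.grid(r = rr, c = cc)
    matrix(bilinear_sample(m, g$r, g$c), out_h, out_w)
  }
  if (is.matrix(img)) return(one(img))
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- one(img[, , ch])
  out
}

stop_degenerate <- function(msg) stop(structure(
  class = c("dedscreen_degenerate_input", "error", "condition"),
  list(message = msg, call = sys.call(-1))))

is_rgb_image <- function(img) is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3
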