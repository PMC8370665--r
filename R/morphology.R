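#' Binary morphology
#'
#' Set-theoretic erosion, dilation, opening and closing on binary masks.
#' Pixels outside the image count as background: the structuring element (SE)
#' must fit entirely inside the foreground for erosion, and out-of-image
#' positions contribute nothing to dilation.
#'
#' @name morphology
NULL

#' Structuring element
#'
#' @param pattern logical/0-1 matrix with at least one active cell.
#' @param origin integer `c(row, col)` inside the pattern; defaults to the
#'   center cell.
#' @return object of class `struct_el`.
#' @export
struct_el <- function(pattern = matrix(1, 3, 3), origin = NULL) {
  pattern <- matrix(as.logical(pattern), nrow(pattern), ncol(pattern))
  if (!any(pattern)) stop("structuring element must have at least one active cell")
  if (is.null(origin)) origin <- c((nrow(pattern) + 1L) %/% 2L,
                                   (ncol(pattern) + 1L) %/% 2L)
  if (origin[1] < 1 || origin[1] > nrow(pattern) ||
      origin[2] < 1 || origin[2] > ncol(pattern))
    stop("origin must lie inside the pattern")
  structure(list(pattern = pattern, origin = as.integer(origin)),
            class = "struct_el")
}

# active-cell offsets relative to the origin, as an n x 2 matrix
se_offsets <- function(se) {
  w <- which(se$pattern, arr.ind = TRUE)
  cbind(w[, 1] - se$origin[1], w[, 2] - se$origin[2])
}

#' Reflect a structuring element through its origin
#' @param se a [struct_el()].
#' @return reflected `struct_el`.
#' @export
reflect_se <- function(se) {
  p <- se$pattern[nrow(se$pattern):1, ncol(se$pattern):1, drop = FALSE]
  o <- c(nrow(p) - se$origin[1] + 1L, ncol(p) - se$origin[2] + 1L)
  struct_el(p, o)
}

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  matrix(as.logical(m), nrow(m), ncol(m))
}

#' Erosion
#'
#' `A %erode% B = {p : B_p subset of A}`: a pixel stays foreground only if
#' the SE translated there fits entirely inside the foreground.
#'
#' @param mask logical/0-1 matrix.
#' @param se a [struct_el()].
#' @return logical matrix of the same dimensions.
#' @export
erode_mask <- function(mask, se = struct_el()) {
  mask <- as_mask(mask)
  off <- se_offsets(se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_matrix(mask, off[i, 1], off[i, 2], fill = FALSE)
  out
}

#' Dilation
#'
#' `A %dilate% B = {x : reflected(B)_x intersects A}`: a pixel becomes
#' foreground if any SE offset reaches a foreground pixel.
#'
#' @inheritParams erode_mask
#' @return logical matrix of the same dimensions.
#' @export
dilate_mask <- function(mask, se = struct_el()) {
  mask <- as_mask(mask)
  off <- se_offsets(se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_matrix(mask, -off[i, 1], -off[i, 2], fill = FALSE)
  out
}

#' Closing (dilation followed by erosion)
#'
#' Fills gaps and holes smaller than the structuring element.
#' @inheritParams erode_mask
#' @return logical matrix.
#' @export
close_mask <- function(mask, se = struct_el()) erode_mask(dilate_mask(mask, se), se)

#' Opening (erosion followed by dilation)
#'
#' Removes foreground regions smaller than the structuring element and
#' refines object contours.
#' @inheritParams erode_mask
#' @return logical matrix.
#' @export
open_mask <- function(mask, se = struct_el()) dilate_mask(erode_mask(mask, se), se)

#' Remove connected components below a pixel-count threshold
#'
#' 8-connected component labeling (via EBImage) followed by size filtering.
#'
#' @param mask logical matrix.
#' @param min_size keep components with at least this many pixels.
#' @return logical matrix.
#' @export
remove_small_components <- function(mask, min_size) {
  mask <- as_mask(mask)
  if (min_size <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Count 8-connected components of a mask
#' @param mask logical matrix.
#' @return integer component count.
#' @export
count_components <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(0L)
  max(EBImage::bwlabel(mask * 1))
}
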