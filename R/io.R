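#' Image and manifest I/O
#'
#' Images are written as 8-bit RGB PNG, masks as single-channel 0/255 PNG;
#' each generated set carries a CSV manifest (filename, label,
#' disc_center_row, disc_center_col, disc_radius).
#'
#' @name image_io
NULL

#' Write an RGB image (0-255) as PNG
#' @param img H x W x 3 array, values 0-255.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Read a PNG as a 0-255 RGB array
#' @param path PNG path.
#' @return H x W x 3 numeric array, integer values 0-255.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round_half_up(a * 255)
}

#' Write a binary mask as a 0/255 single-channel PNG
#' @param mask logical matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 mask PNG as a logical matrix
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a >= 0.5
}

#' Write a generated dataset to disk
#'
#' @param dataset a [generate_dataset()] result.
#' @param out_dir output directory (created if missing).
#' @param write_masks also write the ground-truth masks.
#' @return data.frame manifest (also written as `manifest.csv`).
#' @export
write_dataset <- function(dataset, out_dir, write_masks = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- attr(dataset, "labels")
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    it <- dataset[[i]]
    stem <- sprintf("img_%04d_%s", i, it$truth$label)
    write_image_png(it$image, file.path(out_dir, paste0(stem, ".png")))
    if (write_masks) {
      write_mask_png(it$truth$vessel_mask,
                     file.path(out_dir, paste0(stem, "_vessels.png")))
      write_mask_png(it$truth$exudate_mask,
                     file.path(out_dir, paste0(stem, "_exudates.png")))
      write_mask_png(it$truth$microaneurysm_mask,
                     file.path(out_dir, paste0(stem, "_microaneurysms.png")))
    }
    rows[[i]] <- data.frame(
      filename = paste0(stem, ".png"), label = it$truth$label,
      disc_center_row = it$truth$disc_center[["row"]],
      disc_center_col = it$truth$disc_center[["col"]],
      disc_radius = it$truth$disc_radius)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
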