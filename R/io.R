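#' Read and write the pipeline's image formats
#'
#' Frames are 16-bit single-channel TIFF, one file per frame, row 0 =
#' A-line 0, column 0 = catheter-proximal sample.  Label and mask maps are
#' 8-bit single-channel PNG whose pixel values are the palette ids of
#' [plaque_classes()] (respectively the mask codes of [MASK_EXCLUSION]).
#'
#' @param intensities numeric matrix of stored 16-bit values (0..65535).
#' @param path file path.
#' @name ivoct_io
NULL

#' @rdname ivoct_io
#' @export
write_polar_tiff <- function(intensities, path) {
  tiff::writeTIFF(intensities / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname ivoct_io
#' @export
read_polar_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  round(img * 65535)
}

#' @rdname ivoct_io
#' @param label_map integer matrix over a small non-negative palette.
#' @export
write_label_png <- function(label_map, path) {
  png::writePNG(label_map / 255, path)
  invisible(path)
}

#' @rdname ivoct_io
#' @export
read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

# Fetch the intensity image / label map / contour for one manifest row,
# preferring in-memory list columns over disk paths.
manifest_image <- function(row) {
  if (!is.null(row$image) && !is.null(row$image[[1]])) return(row$image[[1]])
  read_polar_tiff(row$image_path)
}

manifest_labels <- function(row) {
  if (!is.null(row$labels) && !is.null(row$labels[[1]])) return(row$labels[[1]])
  read_label_png(row$label_path)
}
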