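#' En-face OCT raster with physical scan-field dimensions
#'
#' A grayscale raster covering a physical scan field, by default the 3 mm x
#' 3 mm en-face pattern used for macular-hole imaging.  Intensities are kept
#' on \[0, 1\] (8/16-bit files are rescaled on load).  Pixels are assumed
#' square to within 1%; the assumption is asserted at construction.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\] (rows = image
#'   rows, origin top-left).
#' @param field_width_mm,field_height_mm Physical field size in mm
#'   (defaults 3.0 x 3.0).
#' @return Object of class `enface_image` with fields `pixels`,
#'   `field_width_mm`, `field_height_mm`, `pixel_size_mm`.
#' @export
enface_image <- function(pixels, field_width_mm = 3, field_height_mm = 3) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || !length(pixels))
    stop("pixels must be a non-empty numeric matrix")
  if (field_width_mm <= 0 || field_height_mm <= 0)
    stop("physical field dimensions must be positive")
  pw <- field_width_mm / ncol(pixels)
  ph <- field_height_mm / nrow(pixels)
  if (abs(pw - ph) / pw >= 0.01)
    stop("non-square pixels: width ", signif(pw, 4), " mm vs height ",
         signif(ph, 4), " mm (tolerance 1%)")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel intensities must lie in [0, 1] with no missing values")
  structure(list(pixels = pixels, field_width_mm = field_width_mm,
                 field_height_mm = field_height_mm, pixel_size_mm = pw),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("En-face raster %d x %d px, %.1f x %.1f mm (%.1f um/px)\n",
              nrow(x$pixels), ncol(x$pixels), x$field_width_mm,
              x$field_height_mm, 1000 * x$pixel_size_mm))
  invisible(x)
}

#' Read / write en-face rasters and masks as PNG
#'
#' Single-channel (or first-channel) PNG, 8- or 16-bit; intensities are
#' rescaled to \[0, 1\] on load.  `read_mask_png()` binarizes at half
#' maximum (foreground = max, as in 0/255 or 0/65535 masks).
#'
#' @param path PNG file path.
#' @param field_width_mm,field_height_mm Physical field size in mm.
#' @return `read_enface_png()`: an [enface_image]; `read_mask_png()`: a
#'   logical matrix.
#' @export
read_enface_png <- function(path, field_width_mm = 3, field_height_mm = 3) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  enface_image(px, field_width_mm, field_height_mm)
}

#' @rdname read_enface_png
#' @param image An [enface_image] (or plain matrix in \[0, 1\]) to write.
#' @export
write_enface_png <- function(image, path) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  png::writePNG(px, target = path)
  invisible(path)
}

#' @rdname read_enface_png
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px >= 0.5
}

#' @rdname read_enface_png
#' @param mask Logical matrix to write as a 0/255 PNG.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' Physical area of a binary mask
#'
#' Foreground pixel count times the squared pixel size; no sub-pixel
#' correction.
#'
#' @param mask Logical (or 0/1) matrix, same dimensions as `image`.
#' @param image The [enface_image] supplying the physical scale.
#' @return Area in mm^2.
#' @examples
#' img <- enface_image(matrix(0.5, 300, 300))
#' mask <- matrix(FALSE, 300, 300); mask[1:100, 1:100] <- TRUE
#' mask_area(mask, img)  # 1.0 mm^2
#' @export
mask_area <- function(mask, image) {
  if (!inherits(image, "enface_image")) stop("image must be an enface_image")
  if (!all(dim(mask) == dim(image$pixels)))
    stop("mask and image dimensions differ: ",
         paste(dim(mask), collapse = "x"), " vs ",
         paste(dim(image$pixels), collapse = "x"))
  sum(mask != 0) * image$pixel_size_mm^2
}
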