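#' Raster images with physical pixel size
#'
#' A `raster_image` is a 2-D pixel grid — either a numeric matrix (scalar
#' image) or a rows x cols x 3 array (RGB) — together with the physical size
#' of one pixel in micrometres. Coordinates are (row, col) with the origin at
#' the top-left pixel, matching how whole-mount scans are indexed.
#'
#' @param pixels numeric matrix (scalar) or rows x cols x 3 array (RGB).
#' @param pixel_size_um physical edge length of one pixel, in micrometres.
#' @return A `raster_image` object.
#' @examples
#' img <- raster_image(matrix(runif(100), 10, 10), pixel_size_um = 10.5)
#' dim(img$pixels)
#' @export
raster_image <- function(pixels, pixel_size_um) {
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (is.matrix(pixels)) {
    kind <- "scalar"
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    kind <- "rgb"
  } else {
    abort("`pixels` must be a matrix or a rows x cols x 3 array")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um, kind = kind),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d %s, %.4g um/px\n",
              d[1], d[2], x$kind, x$pixel_size_um))
  invisible(x)
}

#' Pixel size of a flatbed scan
#'
#' Converts a scan resolution in dots per inch to the physical pixel size in
#' micrometres (25,400 um per inch). A 2400 dpi whole-mount scan has
#' ~10.6 um pixels, commonly reported as 10.5 um.
#'
#' @param dpi scan resolution in dots per inch.
#' @return Pixel size in micrometres.
#' @examples
#' pixel_size_from_dpi(2400)
#' @export
pixel_size_from_dpi <- function(dpi) {
  stopifnot_scalar_num(dpi, "dpi", positive = TRUE)
  25400 / dpi
}

is_rgb <- function(img) inherits(img, "raster_image") && img$kind == "rgb"
is_scalar_img <- function(img) inherits(img, "raster_image") && img$kind == "scalar"

#' Read and write 8-bit TIFF raster images
#'
#' Thin wrappers around EBImage I/O that keep the package's (row, col)
#' convention and attach a pixel size. Values are stored as 8-bit (0-255).
#'
#' @param path file path.
#' @param pixel_size_um physical pixel size to attach on read.
#' @param img a [raster_image()] with values in 0-255.
#' @return `read_raster_tiff()` returns a [raster_image()]; `write_raster_tiff()`
#'   returns `path` invisibly.
#' @export
read_raster_tiff <- function(path, pixel_size_um) {
  x <- EBImage::readImage(path)
  a <- EBImage::imageData(x)
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) {
    px <- aperm(a[, , 1:3], c(2, 1, 3)) * 255
  } else {
    if (length(dim(a)) == 3L) a <- a[, , 1]
    px <- t(a) * 255
  }
  raster_image(px, pixel_size_um)
}

#' @rdname read_raster_tiff
#' @export
write_raster_tiff <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  a <- if (img$kind == "rgb") aperm(img$pixels, c(2, 1, 3)) else t(img$pixels)
  x <- EBImage::Image(a / 255, colormode = if (img$kind == "rgb") "Color" else "Grayscale")
  EBImage::writeImage(x, path, type = "tiff", bits.per.sample = 8L)
  invisible(path)
}

#' Write a binary mask as an 8-bit 0/255 TIFF
#' @param mask logical matrix.
#' @param path file path.
#' @param pixel_size_um pixel size recorded for round-tripping.
#' @export
write_mask_tiff <- function(mask, path, pixel_size_um = 1) {
  write_raster_tiff(raster_image(mask * 255, pixel_size_um), path)
}
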