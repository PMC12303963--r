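#' Load an 8-bit RGB image
#'
#' Reads a PNG, TIFF, or JPEG file into an integer array of dimension
#' `H x W x 3` with values in 0--255, origin top-left, row-major. An alpha
#' channel, if present, is dropped; grayscale images are promoted to RGB by
#' channel replication.
#'
#' @param path Path to an image file. Format is chosen by file extension
#'   (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @return Integer array `H x W x 3` of class `rgb_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      stop("unsupported image format: .", ext)
    ),
    error = function(e) stop("failed to decode '", path, "': ", conditionMessage(e))
  )
  as_rgb_image(arr)
}

#' Coerce a numeric array to an `rgb_image`
#'
#' Accepts an `H x W` grayscale matrix, or an `H x W x {1,2,3,4}` array.
#' Values in `[0, 1]` are scaled to 0--255; integer-valued inputs in 0--255
#' are used as-is.
#'
#' @param arr Numeric matrix or array.
#' @return Integer array `H x W x 3` of class `rgb_image`.
#' @export
as_rgb_image <- function(arr) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) stop("expected an H x W (x channels) array")
  nc <- dim(arr)[3L]
  if (nc == 1L || nc == 2L) {
    arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))  # grayscale (+alpha)
  } else if (nc == 4L) {
    arr <- arr[, , 1:3, drop = FALSE]                               # drop alpha
  } else if (nc != 3L) {
    stop("unsupported channel count: ", nc)
  }
  if (max(arr) <= 1 + 1e-12) {
    arr <- round(arr * 255)
  } else if (any(arr != round(arr)) || max(arr) > 255 || min(arr) < 0) {
    stop("pixel values must be in [0, 1] or integers in 0..255")
  }
  storage.mode(arr) <- "integer"
  class(arr) <- "rgb_image"
  arr
}

#' Write a binary mask as a 1-bit-style PNG
#'
#' @param mask Logical matrix; `TRUE` pixels are written white.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write an `rgb_image` as PNG
#'
#' @param img An `rgb_image` (integer `H x W x 3`, 0--255).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "rgb_image") || (is.array(img) && length(dim(img)) == 3L))
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 8-bit RGB\n", d[1L], d[2L]))
  invisible(x)
}
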