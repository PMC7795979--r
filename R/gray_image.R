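#' 8-bit grayscale image
#'
#' The unit exchanged by all image operators: an integer matrix of
#' intensities in \[0, 255\], stored row-major as rows = image lines (y,
#' top-down) and columns = pixels along a line (x, left-right).
#'
#' @param pixels numeric matrix of intensities in \[0, 255\]; values are
#'   rounded to integer.
#' @return An object of class `gray_image` (an integer matrix with
#'   attributes), with `width` and `height` accessors via [image_width()]
#'   and [image_height()].
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' image_width(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image dimensions must be >= 1", call. = FALSE)
  }
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(px) <- "integer"
  structure(px, class = c("gray_image", "matrix", "array"))
}

#' @rdname gray_image
#' @param img a `gray_image`.
#' @export
image_width <- function(img) ncol(img)

#' @rdname gray_image
#' @export
image_height <- function(img) nrow(img)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d (w x h), range [%d, %d]>\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

as_gray <- function(x) {
  if (is_gray_image(x)) x else gray_image(x)
}

#' Read an image file (PNG or TIFF)
#'
#' Returns a `gray_image` for single-channel files, or a height x width x 3
#' array of 8-bit values for RGB files (alpha, if present, is dropped).
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `gray_image` or a 3-channel 8-bit array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  vals <- round(raw * 255)
  if (length(dim(vals)) == 2L) return(gray_image(vals))
  ch <- dim(vals)[3]
  if (ch >= 3L) return(vals[, , 1:3, drop = FALSE])
  if (ch == 1L) return(gray_image(vals[, , 1]))
  stop("unsupported channel count: ", ch, call. = FALSE)
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param img a `gray_image`.
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_gray(img)
  norm <- unclass(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(norm, path),
    tif  = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}
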