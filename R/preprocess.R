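#' Convert an RGB raster to 8-bit grayscale
#'
#' Per-pixel luminance with the ITU-R BT.601 weights 0.299/0.587/0.114,
#' rounded half-up to integer. Grayscale input passes through unchanged.
#'
#' @param raster either a height x width x 3 array of 8-bit values, a plain
#'   height x width matrix, or a [gray_image()].
#' @return A [gray_image()].
#' @examples
#' rgb <- array(0, c(2, 2, 3)); rgb[, , 1] <- 255
#' to_grayscale(rgb)[1, 1]  # pure red -> 76
#' @export
to_grayscale <- function(raster) {
  if (is_gray_image(raster)) return(raster)
  if (is.matrix(raster)) return(gray_image(raster))
  d <- dim(raster)
  if (length(d) != 3L || !(d[3] %in% c(1L, 3L))) {
    stop("raster must have 1 or 3 channels", call. = FALSE)
  }
  if (d[3] == 1L) return(gray_image(raster[, , 1]))
  lum <- 0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
  gray_image(floor(lum + 0.5))
}

#' Kirsch compass kernel set
#'
#' Builds the eight directional edge kernels of the Kirsch compass operator
#' at size 3 or 5. Each ring cell (dx, dy) receives a positive weight when
#' the angular distance between its direction `atan2(-dy, dx)` and the
#' kernel direction (a multiple of 45 degrees) is at most 45 degrees, and -3
#' otherwise; the positive weight is `3 * n_neg / n_pos` per ring so every
#' ring — and hence the kernel — sums to exactly zero. The centre weight is
#' 0. At size 3 this reproduces the canonical Kirsch weights (5 / -3).
#'
#' @param size odd kernel size, 3 or 5.
#' @return Object of class `compass_kernels`: a list of 8 matrices named by
#'   compass direction (E, NE, N, NW, W, SW, S, SE, i.e. directions
#'   0, 45, ..., 315 degrees), with attribute `size`.
#' @examples
#' build_compass_kernels(3)$N  # the classic north Kirsch kernel
#' @export
build_compass_kernels <- function(size = 5L) {
  if (length(size) != 1L || !(size %in% c(3L, 5L))) {
    stop("kernel size must be 3 or 5", call. = FALSE)
  }
  size <- as.integer(size)
  rmax <- (size - 1L) %/% 2L
  dirs <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE")
  offs <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  ring <- pmax(abs(offs$dx), abs(offs$dy))
  ang <- atan2(-offs$dy, offs$dx) * 180 / pi
  kernels <- vector("list", 8L)
  for (k in 0:7) {
    theta <- 45 * k
    kern <- matrix(0, size, size)
    for (rho in seq_len(rmax)) {
      in_ring <- ring == rho
      d <- abs(((ang - theta + 180) %% 360) - 180)
      pos <- in_ring & d <= 45 + 1e-9
      neg <- in_ring & !pos
      w_pos <- 3 * sum(neg) / sum(pos)
      idx_pos <- cbind(offs$dy[pos] + rmax + 1L, offs$dx[pos] + rmax + 1L)
      idx_neg <- cbind(offs$dy[neg] + rmax + 1L, offs$dx[neg] + rmax + 1L)
      kern[idx_pos] <- w_pos
      kern[idx_neg] <- -3
    }
    kernels[[k + 1L]] <- kern
  }
  names(kernels) <- dirs
  structure(kernels, size = size, class = "compass_kernels")
}

#' Kirsch compass edge detection
#'
#' Per pixel, the response is the maximum over the eight compass kernels of
#' the linear correlation at that pixel, with replicate padding at the image
#' border. The clamped output maps responses to \[0, 255\]; constant input
#' yields an all-zero image because the kernels sum to zero.
#'
#' @param img a [gray_image()] (or matrix coercible to one).
#' @param size compass kernel size, 3 or 5 (default 5).
#' @param clamp if `TRUE` (default) return a [gray_image()] with responses
#'   clamped to \[0, 255\]; if `FALSE` return the raw (unclamped, possibly
#'   negative) response matrix.
#' @return A [gray_image()], or a numeric matrix when `clamp = FALSE`.
#' @export
kirsch_edges <- function(img, size = 5L, clamp = TRUE) {
  img <- as_gray(img)
  kernels <- build_compass_kernels(size)
  resp <- kirsch_max_response(unclass(img), unclass(kernels))
  if (!clamp) return(resp)
  gray_image(pmin(pmax(round(resp), 0), 255))
}

# Default analysis window: a centred crop of half the frame width and 7/9
# of its height; for a 640 x 360 frame this is the 320 x 280 window used
# throughout the study.
default_crop_region <- function(width, height) {
  w <- as.integer(round(width / 2))
  h <- as.integer(round(height * 7 / 9))
  list(x0 = (width - w) %/% 2L, y0 = (height - h) %/% 2L, w = w, h = h)
}

#' Crop a grayscale image
#'
#' Exact sub-rectangle copy with 0-based pixel coordinates (origin top-left).
#' Out-of-bounds rectangles raise an error; nothing is silently clamped.
#' With all geometry arguments missing, the default centred analysis window
#' is used (320 x 280 for a 640 x 360 frame).
#'
#' @param img a [gray_image()].
#' @param x0,y0 top-left corner of the crop (0-based).
#' @param w,h crop width and height in pixels.
#' @return A [gray_image()] of size `w` x `h`.
#' @export
crop <- function(img, x0 = NULL, y0 = NULL, w = NULL, h = NULL) {
  img <- as_gray(img)
  if (is.null(x0) && is.null(y0) && is.null(w) && is.null(h)) {
    reg <- default_crop_region(image_width(img), image_height(img))
    x0 <- reg$x0; y0 <- reg$y0; w <- reg$w; h <- reg$h
  }
  if (any(vapply(list(x0, y0, w, h), is.null, logical(1)))) {
    stop("either give all of x0, y0, w, h or none", call. = FALSE)
  }
  if (x0 < 0 || y0 < 0 || w < 1 || h < 1 ||
      x0 + w > image_width(img) || y0 + h > image_height(img)) {
    stop("crop rectangle out of bounds", call. = FALSE)
  }
  gray_image(unclass(img)[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE])
}

#' Frame preprocessing for texture analysis
#'
#' The standard chain applied to every frame before descriptor extraction:
#' grayscale conversion, Kirsch compass edge detection, and the centred
#' crop to the analysis window.
#'
#' @param raster RGB array, matrix or [gray_image()].
#' @param kirsch_size compass kernel size, 3 or 5.
#' @param crop_region optional list with `x0`, `y0`, `w`, `h` overriding the
#'   default centred window.
#' @return A [gray_image()] of the cropped edge map.
#' @export
preprocess_frame <- function(raster, kirsch_size = 5L, crop_region = NULL) {
  g <- to_grayscale(raster)
  e <- kirsch_edges(g, size = kirsch_size)
  if (is.null(crop_region)) crop(e)
  else crop(e, crop_region$x0, crop_region$y0, crop_region$w, crop_region$h)
}
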