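# RGB image container and colour-component math.
#
# A grayscale image is an ordinary numeric matrix (rows = image rows,
# columns = image columns, 1-based indexing); a binary mask is a logical
# matrix of the same layout.  Only the three-channel raster gets a class
# of its own, because it carries the working bit depth with it.

#' RGB leaf image
#'
#' Container for a three-channel raster at a declared working bit depth.
#' Channels are integer-valued matrices in `[0, max_value]` where
#' `max_value = 2^bit_depth - 1`.  Bit depth 8 covers standard image files;
#' bit depth 10 gives the 0--1023 working scale used for back-lit mosaic
#' imaging.
#'
#' @param red,green,blue Numeric matrices of identical dimensions.
#' @param bit_depth Bits per channel, 8 or 10.
#' @return An object of class `rgb_image`: a list with elements `red`,
#'   `green`, `blue`, `bit_depth`, `max_value`.
#' @examples
#' m <- matrix(0, 4, 4)
#' img <- rgb_image(m + 10, m + 20, m + 30)
#' extract_channel(img, "blue")[1, 1]
#' @export
rgb_image <- function(red, green, blue, bit_depth = 8L) {
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 10L)) {
    stop("bit_depth must be 8 or 10", call. = FALSE)
  }
  max_value <- 2L^bit_depth - 1L
  chans <- list(red = red, green = green, blue = blue)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) {
      stop(sprintf("channel '%s' must be a numeric matrix", nm), call. = FALSE)
    }
    if (anyNA(ch) || min(ch) < 0 || max(ch) > max_value) {
      stop(sprintf("channel '%s' has values outside [0, %d]", nm, max_value),
           call. = FALSE)
    }
  }
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue))) {
    stop("all three channels must share dimensions", call. = FALSE)
  }
  structure(
    list(red = red, green = green, blue = blue,
         bit_depth = bit_depth, max_value = max_value),
    class = "rgb_image"
  )
}

#' @export
dim.rgb_image <- function(x) dim(x$red)

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d, %d-bit (max %d)\n",
              d[1], d[2], x$bit_depth, x$max_value))
  invisible(x)
}

#' Extract one colour channel
#'
#' @param img An [rgb_image()].
#' @param channel One of `"red"`, `"green"`, `"blue"`.
#' @return The channel as a numeric matrix (a grayscale image).
#' @export
extract_channel <- function(img, channel = c("red", "green", "blue")) {
  stopifnot(inherits(img, "rgb_image"))
  channel <- match.arg(channel)
  img[[channel]]
}

#' Yellow colour component
#'
#' The yellow component used for chlorosis assessment is the equal-weight
#' combination of the red and green channels,
#' `Yellow = 0.5 * Red + 0.5 * Green`, kept real-valued.
#'
#' @param img An [rgb_image()].
#' @return Numeric matrix in `[0, max_value]`.
#' @export
compute_yellow <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  0.5 * img$red + 0.5 * img$green
}

#' Read an image file as an RGB leaf image
#'
#' Reads PNG, TIFF, or JPEG rasters (JPEG requires the optional \pkg{jpeg}
#' package; other formats can be converted externally).  Pixel values are
#' rescaled from the file's `[0, 1]` decoded range onto the declared working
#' bit depth.  Grayscale files are replicated onto all three channels.
#'
#' @param path File path.
#' @param bit_depth Working bits per channel (8 or 10).
#' @return An [rgb_image()].
#' @export
read_leaf_image <- function(path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE)
  )
  mx <- 2L^as.integer(bit_depth) - 1L
  if (length(dim(arr)) == 2L) {
    ch <- round(arr * mx)
    return(rgb_image(ch, ch, ch, bit_depth = bit_depth))
  }
  rgb_image(round(arr[, , 1] * mx), round(arr[, , 2] * mx),
            round(arr[, , 3] * mx), bit_depth = bit_depth)
}

#' Write an RGB image or binary mask as PNG
#'
#' Masks are written as 0/255 grayscale PNG; RGB images are scaled by their
#' `max_value`.
#'
#' @param x An [rgb_image()] or a logical matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) {
    png::writePNG(x * 1.0, path)
  } else if (inherits(x, "rgb_image")) {
    arr <- array(0, c(dim(x), 3L))
    arr[, , 1] <- x$red / x$max_value
    arr[, , 2] <- x$green / x$max_value
    arr[, , 3] <- x$blue / x$max_value
    png::writePNG(arr, path)
  } else if (is.matrix(x) && is.numeric(x)) {
    rng <- range(x)
    v <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
    png::writePNG(v, path)
  } else {
    stop("x must be an rgb_image, a numeric matrix, or a logical mask",
         call. = FALSE)
  }
  invisible(path)
}
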