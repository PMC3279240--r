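# Canny edge detection: Gaussian smoothing, Sobel gradients, non-maximum
# suppression perpendicular to the local gradient, and double-threshold
# hysteresis implemented through connected-component labelling (a weak
# edge survives when its 8-connected chain contains a strong pixel).

# separable convolution with a symmetric 1D kernel, replicate border
conv_sep <- function(img, wrow, wcol) {
  nr <- nrow(img)
  nc <- ncol(img)
  rr <- (length(wrow) - 1L) %/% 2L
  if (rr > 0L) {
    p <- rbind(img[rep(1L, rr), , drop = FALSE], img,
               img[rep(nr, rr), , drop = FALSE])
    acc <- matrix(0, nr, nc)
    for (t in seq_along(wrow)) {
      acc <- acc + wrow[t] * p[(t - 1L) + seq_len(nr), , drop = FALSE]
    }
    img <- acc
  }
  rc <- (length(wcol) - 1L) %/% 2L
  if (rc > 0L) {
    p <- cbind(img[, rep(1L, rc), drop = FALSE], img,
               img[, rep(nc, rc), drop = FALSE])
    acc <- matrix(0, nr, nc)
    for (t in seq_along(wcol)) {
      acc <- acc + wcol[t] * p[, (t - 1L) + seq_len(nc), drop = FALSE]
    }
    img <- acc
  }
  img
}

#' Gaussian smoothing
#'
#' Separable Gaussian filter with kernel radius `ceiling(3 * sigma)` and
#' replicated borders.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels.
#' @return Numeric matrix.
#' @export
gaussian_blur <- function(img, sigma = 1.4) {
  stopifnot(is.matrix(img), is.numeric(img), sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  w <- exp(-x^2 / (2 * sigma^2))
  w <- w / sum(w)
  conv_sep(img, w, w)
}

# Sobel derivatives: gx along columns (j), gy along rows (i)
sobel_gradients <- function(img) {
  smooth <- c(1, 2, 1) / 4
  diff <- c(1, 0, -1)  # value at j+1 minus j-1, up to sign convention
  gx <- conv_sep(img, smooth, rev(diff))
  gy <- conv_sep(img, rev(diff), smooth)
  list(gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' @param img Numeric matrix (grayscale image).
#' @param sigma Gaussian smoothing scale in pixels.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude after non-maximum suppression (`low < high`).
#' @return Logical matrix of edge pixels (thin, one pixel across the
#'   gradient direction).
#' @export
canny <- function(img, sigma = 1.4, low = 0.1, high = 0.25) {
  stopifnot(is.matrix(img), is.numeric(img), low > 0, high > low, high < 1)
  g <- sobel_gradients(gaussian_blur(img, sigma))
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx <= 0) return(matrix(FALSE, nrow(img), ncol(img)))

  # quantize gradient direction into 4 sectors; compare against the two
  # neighbours along the gradient
  ang <- atan2(g$gy, g$gx)           # radians, (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W 1:SE-NW 2:N-S 3:SW-NE
  nb <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  n_pos <- matrix(0, nrow(img), ncol(img))
  n_neg <- n_pos
  for (k in 0:3) {
    idx <- sector == k
    if (!any(idx)) next
    o <- nb[[k + 1L]]
    sp <- mm_shift(mag, o[1], o[2], 0)
    sn <- mm_shift(mag, -o[1], -o[2], 0)
    n_pos[idx] <- sp[idx]
    n_neg[idx] <- sn[idx]
  }
  keep <- mag >= n_pos & mag > n_neg
  nms <- ifelse(keep, mag, 0)

  strong <- nms >= high * mx
  weak <- nms >= low * mx
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  cc <- connected_components(weak, 8)
  keep_labels <- unique(cc$labels[strong])
  weak & matrix(cc$labels %in% keep_labels, nrow(img), ncol(img))
}
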