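# Shared grayscale primitives: contrast stretching, thresholding and the
# intensity-weighted centroid.

#' Linear contrast stretch
#'
#' Affinely maps the observed value range `[min(img), max(img)]` onto
#' `[out_lo, out_hi]`, e.g. onto the full 0--1023 working scale before
#' venation enhancement.  The map is monotone, so pixel ordering is
#' preserved.  A constant image has no contrast to stretch; it is returned
#' as a constant at the midpoint of the output range, with a warning.
#'
#' @param img Numeric matrix.
#' @param out_lo,out_hi Output range endpoints (`out_lo < out_hi`).
#' @return Numeric matrix with values in `[out_lo, out_hi]`.
#' @export
contrast_stretch <- function(img, out_lo = 0, out_hi = 1023) {
  stopifnot(is.matrix(img), is.numeric(img), out_hi > out_lo)
  lo <- min(img)
  hi <- max(img)
  if (hi == lo) {
    warning("constant image: returning midpoint of output range")
    return(matrix((out_lo + out_hi) / 2, nrow(img), ncol(img)))
  }
  out_lo + (img - lo) * (out_hi - out_lo) / (hi - lo)
}

#' Threshold a grayscale image into a binary mask
#'
#' Comparison is strict, so pixels exactly at the threshold are excluded in
#' both polarities.  `polarity = "above"` segments bright objects (white
#' spots, panel background); `polarity = "below"` segments dark objects
#' (leaf tissue against a bright panel, necrotic lesions).
#'
#' @param img Numeric matrix.
#' @param threshold Threshold value, on the scale of `img`.
#' @param polarity `"above"` (mask where `img > threshold`) or `"below"`
#'   (mask where `img < threshold`).
#' @return Logical matrix.
#' @export
binarize <- function(img, threshold, polarity = c("above", "below")) {
  stopifnot(is.matrix(img), is.numeric(img), length(threshold) == 1L)
  polarity <- match.arg(polarity)
  if (polarity == "above") img > threshold else img < threshold
}

#' Intensity-weighted centroid
#'
#' Centre of mass of a grayscale image:
#' `cx = sum(i * v(i,j)) / sum(v)` over rows `i`,
#' `cy = sum(j * v(i,j)) / sum(v)` over columns `j`.
#'
#' Note the axis naming: **`cx` is the ROW coordinate and `cy` the COLUMN
#' coordinate** (the row index carries the `x` label in the defining sums).
#' Coordinates are 1-based, matching R matrix indexing.
#'
#' @param img Numeric matrix with non-negative values and positive total.
#' @return Object of class `centroid`: list with `cx` (row), `cy` (column).
#' @export
weighted_centroid <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  tot <- sum(img)
  if (!is.finite(tot) || tot <= 0) {
    stop("zero total intensity", call. = FALSE)
  }
  cx <- sum(rowSums(img) * seq_len(nrow(img))) / tot
  cy <- sum(colSums(img) * seq_len(ncol(img))) / tot
  structure(list(cx = cx, cy = cy), class = "centroid")
}

#' @export
print.centroid <- function(x, ...) {
  cat(sprintf("<centroid> row cx = %.3f, col cy = %.3f\n", x$cx, x$cy))
  invisible(x)
}
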