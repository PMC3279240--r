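# Binary and grayscale mathematical morphology.
#
# Binary semantics are the literal set definitions on the finite image
# frame: erosion keeps the pixels where every structuring-element cell
# falls on foreground, dilation (with the reflected element) the pixels
# where at least one cell does.  Grayscale semantics are the min/max
# filters; outside-of-frame pixels are ignored (+Inf for erosion, -Inf
# for dilation), the usual convention of scientific image libraries.
# Closing is evaluated on a temporarily expanded frame so that it equals
# the infinite-plane closing of the image: this keeps closing extensive
# and idempotent all the way to the border.

# out[i, j] = m[i + di, j + dj], `fill` outside the frame
mm_shift <- function(m, di, dj, fill) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1L, 1L - di):min(nr, nr - di)
  rj <- max(1L, 1L - dj):min(nc, nc - dj)
  if (ri[1] > ri[length(ri)] || rj[1] > rj[length(rj)]) return(out)
  out[ri, rj] <- m[ri + di, rj + dj]
  out
}

mm_reduce <- function(img, offs, fun, fill) {
  acc <- NULL
  for (t in seq_len(nrow(offs))) {
    s <- mm_shift(img, offs[t, 1], offs[t, 2], fill)
    acc <- if (is.null(acc)) s else fun(acc, s)
  }
  acc
}

#' Morphological erosion and dilation
#'
#' `erode()` of a binary mask keeps a pixel when the structuring element
#' translated there lies entirely on foreground; `dilate()` keeps a pixel
#' when the reflected element overlaps foreground by at least one cell.
#' On grayscale images they are the running minimum / maximum over the
#' (reflected) neighbourhood.
#'
#' Border handling: by default pixels outside the frame count as
#' background for binary erosion (the element must fit inside the frame)
#' and for dilation (masks never grow past the frame); grayscale
#' operators ignore the outside.  `pad = "foreground"` makes binary
#' erosion treat the outside as foreground, which is what the
#' complement-duality identity
#' `dilate(A, B) == !erode(!A, reflect(B), pad = "foreground")` requires.
#'
#' @param img Logical matrix (binary mask) or numeric matrix (grayscale).
#' @param se A [struct_elem()].
#' @param pad Border policy for binary images: `"background"` or
#'   `"foreground"`.
#' @return Matrix of the same kind as `img`.
#' @export
erode <- function(img, se, pad = c("background", "foreground")) {
  stopifnot(is.matrix(img), inherits(se, "struct_elem"))
  pad <- match.arg(pad)
  offs <- se_offsets(se)
  if (is.logical(img)) {
    mm_reduce(img, offs, `&`, fill = pad == "foreground")
  } else {
    mm_reduce(img, offs, pmin, fill = Inf)
  }
}

#' @rdname erode
#' @export
dilate <- function(img, se, pad = c("background", "foreground")) {
  stopifnot(is.matrix(img), inherits(se, "struct_elem"))
  pad <- match.arg(pad)
  offs <- -se_offsets(se)  # slide the reflected element
  if (is.logical(img)) {
    mm_reduce(img, offs, `|`, fill = pad == "foreground")
  } else {
    mm_reduce(img, offs, pmax, fill = -Inf)
  }
}

#' Morphological opening, closing, top-hat and bottom-hat
#'
#' Opening is erosion followed by dilation with the same element; it
#' removes bright (or foreground) features smaller than the element and
#' is the median-like prefilter applied to the green channel before
#' necrosis thresholding.  Closing is dilation followed by erosion and
#' fills dark features.  The white top-hat is `img - opening(img)` and
#' extracts small bright structures such as back-lit venation; the black
#' bottom-hat is `closing(img) - img` and extracts small dark structures.
#' Both hats are non-negative everywhere.
#'
#' @inheritParams erode
#' @return Matrix of the same kind as `img` (hats: numeric matrix).
#' @export
opening <- function(img, se) {
  dilate(erode(img, se), se)
}

#' @rdname opening
#' @export
closing <- function(img, se) {
  offs <- se_offsets(se)
  ri <- max(abs(offs[, 1]))
  rj <- max(abs(offs[, 2]))
  nr <- nrow(img)
  nc <- ncol(img)
  fill <- if (is.logical(img)) FALSE else -Inf
  big <- matrix(fill, nr + 2L * ri, nc + 2L * rj)
  big[ri + seq_len(nr), rj + seq_len(nc)] <- img
  out <- erode(dilate(big, se), se)
  out[ri + seq_len(nr), rj + seq_len(nc), drop = FALSE]
}

#' @rdname opening
#' @export
top_hat <- function(img, se) {
  stopifnot(is.numeric(img))
  img - opening(img, se)
}

#' @rdname opening
#' @export
bottom_hat <- function(img, se) {
  stopifnot(is.numeric(img))
  closing(img, se) - img
}
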