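# Mosaic (vein-clearing) quantification on back-lit leaf images:
# contrast stretch onto the working gray scale, top-hat/bottom-hat
# enhancement of the bright venation, Canny edge detection, and the
# edge-area percentage of the leaf.

#' Enhance back-lit venation contrast
#'
#' Stretches the blue channel onto `[0, stretch_hi]` (the 0--1023 working
#' scale by default) and adds the white top-hat while subtracting the
#' black bottom-hat, the classical morphological contrast enhancement:
#' small bright structures (the transilluminated veins) are pushed up,
#' small dark structures down.  `hat_mode = "replace"` instead applies
#' the two hat subtractions sequentially
#' (`img - bottom_hat(img + top_hat(img))` stages collapsed to
#' sequential replacement), for a literal two-step reading.
#'
#' @param img An [rgb_image()].
#' @param se Structuring element; should be wider than the vein calibre
#'   (default 9x9 disk).
#' @param stretch_hi Upper end of the working range.
#' @param hat_mode `"additive"` (default) or `"replace"`.
#' @return Numeric matrix in `[0, stretch_hi]`.
#' @export
enhance_venation <- function(img, se = se_disk(4), stretch_hi = 1023,
                             hat_mode = c("additive", "replace")) {
  stopifnot(inherits(img, "rgb_image"))
  hat_mode <- match.arg(hat_mode)
  blue <- extract_channel(img, "blue")
  if (min(blue) == max(blue)) {
    warning("constant blue channel: venation enhancement is a no-op")
    return(blue)
  }
  a <- contrast_stretch(blue, 0, stretch_hi)
  enh <- if (hat_mode == "additive") {
    a + top_hat(a, se) - bottom_hat(a, se)
  } else {
    b <- a + top_hat(a, se)
    b - bottom_hat(b, se)
  }
  pmin(pmax(enh, 0), stretch_hi)
}

#' Quantify mosaic (vein-clearing) density
#'
#' Runs [enhance_venation()], detects venation edges with the Canny
#' algorithm, restricts the edge map to the leaf mask (blue channel
#' below-threshold, largest component, holes filled) and reports
#' `A_mosaic = 100 * A_map / A_TL`, the percentage of leaf area covered
#' by mosaic edges.  Intended for back-lit images where transmitted
#' light makes the venation brighter than the lamina.
#'
#' @param img An [rgb_image()] photographed under back-light.
#' @param se Structuring element for the hat enhancement.
#' @param sigma,edge_lo,edge_hi Canny parameters (see [canny()]).
#' @param t_leaf Leaf threshold as a fraction of `max_value`.
#' @param stretch_hi,hat_mode Passed to [enhance_venation()].
#' @return Object of class `mosaic_result`: list with `a_map`, `a_tl`,
#'   `a_mosaic` (percent), `edge_mask`, `leaf_mask` and the parameters
#'   used.
#' @export
quantify_mosaic <- function(img, se = se_disk(4), sigma = 1.4,
                            edge_lo = 0.1, edge_hi = 0.25, t_leaf = 0.80,
                            stretch_hi = 1023,
                            hat_mode = c("additive", "replace")) {
  hat_mode <- match.arg(hat_mode)
  leaf <- fill_holes(segment_leaf(img, t_leaf))
  enh <- enhance_venation(img, se, stretch_hi, hat_mode)
  edges <- canny(enh, sigma, edge_lo, edge_hi) & leaf
  a_map <- sum(edges)
  a_tl <- sum(leaf)
  structure(
    list(a_map = a_map, a_tl = a_tl, a_mosaic = 100 * a_map / a_tl,
         edge_mask = edges, leaf_mask = leaf,
         params = list(se = se, sigma = sigma, edge_lo = edge_lo,
                       edge_hi = edge_hi, t_leaf = t_leaf,
                       stretch_hi = stretch_hi, hat_mode = hat_mode)),
    class = "mosaic_result"
  )
}

#' @export
print.mosaic_result <- function(x, ...) {
  cat(sprintf("<mosaic_result> A_mosaic = %.2f%% (%d edge px of %d leaf px)\n",
              x$a_mosaic, x$a_map, x$a_tl))
  invisible(x)
}
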