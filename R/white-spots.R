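# White-spot quantification by exhaustive pixel accounting: every frame
# pixel is background, leaf-without-spots, or white spot, so the spot
# area is what the other two classes leave over.

#' Quantify white-spot leaf area
#'
#' The blue channel is thresholded from above; bright connected
#' components touching the image border form the panel background
#' `A_BG` (interior bright spots cannot touch the border and so are
#' excluded).  In the complement, the largest dark component is the leaf
#' without its spots, `A_TL`.  The spot area follows from the exact
#' accounting identity over the frame size `A_ZS`:
#' `A_ws = A_ZS - A_BG - A_TL`, and the reported percentage is
#' `A_pws = 100 * A_ws / (A_TL + A_ws)`.
#'
#' Dark noise outside the leaf is, by this arithmetic, attributed to
#' `A_ws`; `denoise = TRUE` applies a small binary opening to the bright
#' mask first to suppress isolated noise pixels.
#'
#' @param img An [rgb_image()].
#' @param t_spot Brightness threshold as a fraction of `max_value`.
#' @param denoise Apply a 3x3 binary opening to the thresholded mask.
#' @param connectivity Passed to the component labelling.
#' @return Object of class `white_spots_result`: list with `a_zs`,
#'   `a_bg`, `a_tl`, `a_ws`, `a_pws` (percent) and the class masks.
#' @export
quantify_white_spots <- function(img, t_spot = 0.80, denoise = FALSE,
                                 connectivity = 8) {
  stopifnot(inherits(img, "rgb_image"), t_spot > 0, t_spot <= 1)
  bright <- binarize(extract_channel(img, "blue"), t_spot * img$max_value,
                     "above")
  if (denoise) bright <- opening(bright, se_box(3))
  a_zs <- length(bright)

  cc_b <- connected_components(bright, connectivity)
  bg_ids <- which(cc_b$border_touching)
  a_bg <- sum(cc_b$sizes[bg_ids])
  bg_mask <- matrix(cc_b$labels %in% bg_ids, nrow(bright), ncol(bright)) & bright

  dark <- !bright
  cc_d <- connected_components(dark, connectivity)
  if (cc_d$n == 0L) stop("no leaf found", call. = FALSE)
  leaf_id <- which.max(cc_d$sizes)
  a_tl <- cc_d$sizes[leaf_id]
  leaf_mask <- cc_d$labels == leaf_id

  a_ws <- a_zs - a_bg - a_tl
  structure(
    list(a_zs = a_zs, a_bg = a_bg, a_tl = a_tl, a_ws = a_ws,
         a_pws = 100 * a_ws / (a_tl + a_ws),
         background_mask = bg_mask, leaf_mask = leaf_mask,
         params = list(t_spot = t_spot, denoise = denoise,
                       connectivity = connectivity)),
    class = "white_spots_result"
  )
}

#' @export
print.white_spots_result <- function(x, ...) {
  cat(sprintf("<white_spots_result> A_pws = %.2f%% (A_ws = %d, A_TL = %d, A_BG = %d of %d)\n",
              x$a_pws, x$a_ws, x$a_tl, x$a_bg, x$a_zs))
  invisible(x)
}
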