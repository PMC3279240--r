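# Necrotic-area quantification: dark lesions segmented on the green
# channel (best lesion/tissue contrast), total leaf area on the blue
# channel (least sensitive to chlorosis).

#' Segment the leaf silhouette from a bright panel background
#'
#' Thresholds the blue channel from below (the leaf is darker than the
#' panel in blue, and blue is barely affected by yellowing) and keeps the
#' largest connected component, discarding stray dark debris.
#'
#' @param img An [rgb_image()].
#' @param t_leaf Leaf threshold as a fraction of `max_value`; pixels with
#'   blue `< t_leaf * max_value` are leaf candidates.
#' @param connectivity Passed to the component labelling.
#' @return Logical leaf mask.
#' @export
segment_leaf <- function(img, t_leaf = 0.80, connectivity = 8) {
  stopifnot(inherits(img, "rgb_image"), t_leaf > 0, t_leaf <= 1)
  cand <- binarize(extract_channel(img, "blue"), t_leaf * img$max_value, "below")
  if (!any(cand)) stop("no leaf found", call. = FALSE)
  largest_component(cand, connectivity)
}

#' Quantify necrotic leaf area
#'
#' The green channel is prefiltered with a grayscale morphological
#' opening (removing bright speckle smaller than the structuring
#' element), then thresholded from below inside the leaf mask to count
#' necrotic pixels `A_np`; the result is the percentage
#' `A_n = 100 * A_np / A_T` of the total leaf area `A_T`.
#'
#' @param img An [rgb_image()].
#' @param t_necro Necrosis threshold as a fraction of `max_value` applied
#'   to the opened green channel.
#' @param t_leaf Leaf threshold, as in [segment_leaf()].
#' @param se Structuring element for the opening prefilter.
#' @return Object of class `necrosis_result`: list with `a_np`, `a_t`,
#'   `a_n` (percent), `necrotic_mask`, `leaf_mask` and the parameters
#'   used.
#' @export
quantify_necrosis <- function(img, t_necro = 0.35, t_leaf = 0.80,
                              se = se_box(3)) {
  stopifnot(inherits(img, "rgb_image"), t_necro > 0, t_necro <= 1)
  leaf <- segment_leaf(img, t_leaf)
  green <- opening(extract_channel(img, "green"), se)
  necro <- binarize(green, t_necro * img$max_value, "below") & leaf
  a_np <- sum(necro)
  a_t <- sum(leaf)
  structure(
    list(a_np = a_np, a_t = a_t, a_n = 100 * a_np / a_t,
         necrotic_mask = necro, leaf_mask = leaf,
         params = list(t_necro = t_necro, t_leaf = t_leaf, se = se)),
    class = "necrosis_result"
  )
}

#' @export
print.necrosis_result <- function(x, ...) {
  cat(sprintf("<necrosis_result> A_n = %.2f%% (%d of %d leaf pixels)\n",
              x$a_n, x$a_np, x$a_t))
  invisible(x)
}
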