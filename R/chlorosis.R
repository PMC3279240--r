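# Chlorosis quantification: overall yellowing (R_n) and its localization
# (R_diff) from the yellow colour component.

#' Partition an image into four sections around a centroid
#'
#' Pixels are split into quadrants by comparing the row index against the
#' centroid row `cx` and the column index against the centroid column
#' `cy`; a pixel on a centroid line goes to the `>=` side.  Sections are
#' numbered 1 (top-left), 2 (top-right), 3 (bottom-left), 4
#' (bottom-right); downstream statistics are invariant to this labelling.
#'
#' @param img Numeric matrix (used for its dimensions).
#' @param centroid A `centroid` (see [weighted_centroid()]) or numeric
#'   `c(cx, cy)`; must lie inside the frame.
#' @param leaf_mask Optional logical matrix; pixels outside it belong to
#'   no section (region id 0).
#' @return Integer matrix of region ids in `0:4`.
#' @export
partition_regions <- function(img, centroid, leaf_mask = NULL) {
  stopifnot(is.matrix(img))
  if (inherits(centroid, "centroid")) centroid <- c(centroid$cx, centroid$cy)
  cx <- centroid[1]
  cy <- centroid[2]
  if (cx < 1 || cx > nrow(img) || cy < 1 || cy > ncol(img)) {
    stop("centroid outside frame", call. = FALSE)
  }
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cols <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  reg <- 1L + (rows >= cx) * 2L + (cols >= cy) * 1L
  if (!is.null(leaf_mask)) {
    stopifnot(is.logical(leaf_mask), identical(dim(leaf_mask), dim(img)))
    reg[!leaf_mask] <- 0L
  }
  reg
}

#' Quantify chlorosis level and localization
#'
#' Computes the yellow component (`0.5 R + 0.5 G`), locates its weighted
#' centroid, splits the frame (or the leaf) into four sections around it,
#' and reports the per-section mean yellow levels `R_1..R_4`, the modulus
#' `R_n = sqrt(sum(R_k^2))` of that vector, and the modulus `R_diff` of
#' the vector of the six pairwise differences `R_k - R_l`.  A uniformly
#' yellowing (generalized chlorosis) leaf raises `R_n` while `R_diff`
#' stays small; chlorosis confined to one section raises `R_diff`.
#'
#' @param img An [rgb_image()].
#' @param leaf_mask Optional logical matrix restricting the section means
#'   to leaf pixels (recommended: a bright panel background would
#'   otherwise dominate the means).  `NULL` uses the whole frame.
#' @param centroid Optional centroid overriding the computed one.
#' @param masked_centroid If `TRUE` and a `leaf_mask` is given, the
#'   centroid is computed over the masked yellow image instead of the
#'   whole frame.
#' @return Object of class `chlorosis_result`: list with `region_means`
#'   (`R_1..R_4`, `NA` for an empty section), `l_counts` (pixels per
#'   section), `rn`, `rdiff`, `centroid`.
#' @export
quantify_chlorosis <- function(img, leaf_mask = NULL, centroid = NULL,
                               masked_centroid = FALSE) {
  stopifnot(inherits(img, "rgb_image"))
  yellow <- compute_yellow(img)
  if (is.null(centroid)) {
    cimg <- yellow
    if (masked_centroid && !is.null(leaf_mask)) {
      cimg <- yellow * leaf_mask
    }
    centroid <- weighted_centroid(cimg)
  }
  reg <- partition_regions(yellow, centroid, leaf_mask)
  r_k <- rep(NA_real_, 4)
  l_k <- integer(4)
  for (k in 1:4) {
    idx <- reg == k
    l_k[k] <- sum(idx)
    if (l_k[k] > 0L) r_k[k] <- mean(yellow[idx])
  }
  if (anyNA(r_k)) {
    warning(sprintf("empty section(s) %s excluded from R_n / R_diff",
                    paste(which(is.na(r_k)), collapse = ", ")))
  }
  def <- which(!is.na(r_k))
  rn <- sqrt(sum(r_k[def]^2))
  rdiff <- if (length(def) >= 2L) {
    pairs <- utils::combn(def, 2L)
    sqrt(sum((r_k[pairs[1, ]] - r_k[pairs[2, ]])^2))
  } else {
    0
  }
  structure(
    list(region_means = r_k, l_counts = l_k, rn = rn, rdiff = rdiff,
         centroid = centroid),
    class = "chlorosis_result"
  )
}

#' @export
print.chlorosis_result <- function(x, ...) {
  cat(sprintf("<chlorosis_result> R_n = %.2f, R_diff = %.2f\n", x$rn, x$rdiff))
  cat(sprintf("  sections R_k: %s (pixels: %s)\n",
              paste(sprintf("%.2f", x$region_means), collapse = ", "),
              paste(x$l_counts, collapse = ", ")))
  invisible(x)
}
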