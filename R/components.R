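# Connected-component labelling ("the connectivity algorithm"):
# column-run extraction followed by union-find merging of runs in
# adjacent columns.  Pure R, but run-based so the work scales with the
# number of runs, not the number of pixels.

#' Connected-component labelling of a binary mask
#'
#' Labels every foreground (`TRUE`) pixel with a component id under 4- or
#' 8-neighbourhood adjacency.  Component 0 is background.  Besides the
#' label raster the result records each component's pixel count and
#' whether it touches the image border -- the property used to tell panel
#' background (border-touching bright region) from interior white spots.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default; diagonal neighbours connected) or 4.
#' @return Object of class `labelled_components`: list with `labels`
#'   (integer matrix, 0 = background), `sizes` (pixel count per component),
#'   `border_touching` (logical per component), `n` (component count) and
#'   `connectivity`.
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
#' connected_components(m, 4)$n  # 2: diagonal pixels are separate
#' connected_components(m, 8)$n  # 1
#' @export
connected_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  empty <- structure(
    list(labels = labels, sizes = integer(0), border_touching = logical(0),
         n = 0L, connectivity = connectivity),
    class = "labelled_components"
  )
  if (!any(mask)) return(empty)

  # vertical runs per column
  run_s <- vector("list", nc)
  run_e <- vector("list", nc)
  run_id <- vector("list", nc)
  nruns <- 0L
  for (j in seq_len(nc)) {
    v <- mask[, j]
    if (!any(v)) next
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- r$values
    s <- s[keep]; e <- e[keep]
    run_s[[j]] <- s
    run_e[[j]] <- e
    run_id[[j]] <- nruns + seq_along(s)
    nruns <- nruns + length(s)
  }

  parent <- seq_len(nruns)
  find_root <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nx <- parent[x]
      parent[x] <<- root
      x <- nx
    }
    root
  }
  # runs in adjacent columns meet if their row intervals overlap,
  # extended by 1 when diagonal adjacency counts
  d <- if (connectivity == 8L) 1L else 0L
  for (j in 2:nc) {
    ida <- run_id[[j - 1L]]
    idb <- run_id[[j]]
    if (is.null(ida) || is.null(idb)) next
    sa <- run_s[[j - 1L]]; ea <- run_e[[j - 1L]]
    sb <- run_s[[j]]; eb <- run_e[[j]]
    lo <- findInterval(sb - d - 0.5, ea) + 1L  # first a-run ending >= sb - d
    hi <- findInterval(eb + d + 0.5, sa)       # last a-run starting <= eb + d
    for (t in which(lo <= hi)) {
      rb <- find_root(idb[t])
      for (u in lo[t]:hi[t]) {
        ra <- find_root(ida[u])
        if (ra != rb) {
          parent[ra] <- rb
        }
      }
    }
  }

  roots <- vapply(seq_len(nruns), find_root, integer(1))
  comp_of_root <- integer(nruns)
  ord_roots <- unique(roots)  # run scan order = column-major first appearance
  comp_of_root[ord_roots] <- seq_along(ord_roots)
  comp <- comp_of_root[roots]
  K <- length(ord_roots)

  sizes <- integer(K)
  border <- logical(K)
  for (j in seq_len(nc)) {
    ids <- run_id[[j]]
    if (is.null(ids)) next
    s <- run_s[[j]]; e <- run_e[[j]]
    cs <- comp[ids]
    for (t in seq_along(ids)) {
      k <- cs[t]
      labels[s[t]:e[t], j] <- k
      sizes[k] <- sizes[k] + (e[t] - s[t] + 1L)
      if (j == 1L || j == nc || s[t] == 1L || e[t] == nr) border[k] <- TRUE
    }
  }

  structure(
    list(labels = labels, sizes = sizes, border_touching = border,
         n = K, connectivity = connectivity),
    class = "labelled_components"
  )
}

#' @export
print.labelled_components <- function(x, ...) {
  cat(sprintf("<labelled_components> %d component(s), connectivity %d\n",
              x$n, x$connectivity))
  invisible(x)
}

#' Keep only the largest connected component
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @param connectivity Passed to [connected_components()].
#' @return Logical matrix containing the largest component only.
#' @export
largest_component <- function(mask, connectivity = 8) {
  cc <- connected_components(mask, connectivity)
  if (cc$n == 0L) stop("mask is empty", call. = FALSE)
  cc$labels == which.max(cc$sizes)
}

#' Fill holes in a binary mask
#'
#' A hole is a background component (4-connected, the dual of 8-connected
#' foreground) that does not touch the image border.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with interior holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  bg <- connected_components(!mask, 4)
  if (bg$n == 0L) return(mask)
  hole_ids <- which(!bg$border_touching)
  if (length(hole_ids)) {
    mask[bg$labels %in% hole_ids] <- TRUE
  }
  mask
}
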