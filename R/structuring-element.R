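# Structuring elements: the neighbourhood probes of the morphological
# operators.  A structuring element is a small logical pattern plus an
# origin cell; its point reflection through the origin is what dilation
# slides over the image.

#' Structuring element
#'
#' @param pattern Logical matrix with at least one `TRUE` cell.
#' @param origin Integer `c(row, col)` inside the pattern; defaults to the
#'   centre cell.
#' @return Object of class `struct_elem`.
#' @seealso [se_box()], [se_disk()], [se_cross()], [se_reflect()]
#' @export
struct_elem <- function(pattern, origin = NULL) {
  if (is.numeric(pattern)) pattern <- pattern != 0
  stopifnot(is.matrix(pattern), is.logical(pattern))
  if (!any(pattern)) stop("structuring element must have at least one TRUE cell", call. = FALSE)
  if (is.null(origin)) origin <- (dim(pattern) + 1L) %/% 2L
  origin <- as.integer(origin)
  if (length(origin) != 2L ||
      origin[1] < 1L || origin[1] > nrow(pattern) ||
      origin[2] < 1L || origin[2] > ncol(pattern)) {
    stop("origin must lie inside the pattern", call. = FALSE)
  }
  structure(list(pattern = pattern, origin = origin), class = "struct_elem")
}

#' @rdname struct_elem
#' @param n Side length (box/cross), a positive integer.
#' @export
se_box <- function(n = 3) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  struct_elem(matrix(TRUE, n, n))
}

#' @rdname struct_elem
#' @param r Disk radius in pixels; the pattern is `(2r+1) x (2r+1)`.
#' @export
se_disk <- function(r = 4) {
  r <- as.integer(r)
  stopifnot(r >= 0L)
  x <- (-r):r
  struct_elem(outer(x, x, function(a, b) a * a + b * b <= r * r))
}

#' @rdname struct_elem
#' @export
se_cross <- function(n = 3) {
  n <- as.integer(n)
  stopifnot(n >= 1L, n %% 2L == 1L)
  p <- matrix(FALSE, n, n)
  mid <- (n + 1L) %/% 2L
  p[mid, ] <- TRUE
  p[, mid] <- TRUE
  struct_elem(p)
}

#' Point reflection of a structuring element
#'
#' Reflects the pattern through its origin; reflecting twice returns the
#' original element.
#'
#' @param se A [struct_elem()].
#' @return A [struct_elem()].
#' @export
se_reflect <- function(se) {
  stopifnot(inherits(se, "struct_elem"))
  p <- se$pattern[nrow(se$pattern):1, ncol(se$pattern):1, drop = FALSE]
  struct_elem(p, dim(se$pattern) + 1L - se$origin)
}

# offsets (row, col) of TRUE cells relative to the origin
se_offsets <- function(se) {
  w <- which(se$pattern, arr.ind = TRUE)
  cbind(w[, 1] - se$origin[1], w[, 2] - se$origin[2])
}

#' Read a structuring element from a text grid
#'
#' The format is one row of the pattern per line: `0` background, `1`
#' foreground, `2` foreground origin (`o` marks a background origin).
#' If no origin is marked the centre cell is used.
#'
#' @param path Path to the text file.
#' @param text Character vector of lines (alternative to `path`).
#' @return A [struct_elem()].
#' @examples
#' se <- se_parse(c("010", "121", "010"))  # cross with centre origin
#' @export
se_parse <- function(text) {
  text <- trimws(text)
  text <- text[nzchar(text)]
  rows <- strsplit(text, "")
  nc <- unique(lengths(rows))
  if (length(nc) != 1L) stop("ragged structuring-element grid", call. = FALSE)
  m <- do.call(rbind, rows)
  if (!all(m %in% c("0", "1", "2", "o"))) {
    stop("structuring-element grid may contain only 0, 1, 2, o", call. = FALSE)
  }
  origin_idx <- which(m == "2" | m == "o", arr.ind = TRUE)
  if (nrow(origin_idx) > 1L) stop("more than one origin marked", call. = FALSE)
  origin <- if (nrow(origin_idx) == 1L) as.integer(origin_idx[1, ]) else NULL
  struct_elem(matrix(m %in% c("1", "2"), nrow(m), ncol(m)), origin)
}

#' @rdname se_parse
#' @export
se_read <- function(path) {
  se_parse(readLines(path))
}

#' @export
print.struct_elem <- function(x, ...) {
  ch <- ifelse(x$pattern, "1", "0")
  ch[x$origin[1], x$origin[2]] <- if (x$pattern[x$origin[1], x$origin[2]]) "2" else "o"
  cat("<struct_elem>\n")
  cat(apply(ch, 1, paste, collapse = ""), sep = "\n")
  invisible(x)
}
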