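# Independent brute-force oracles used throughout the suite.  They are
# written directly from the set / min-max definitions with explicit
# double loops, deliberately sharing no code with the implementation.

# binary erosion: z kept iff every SE cell translated to z lands on
# foreground; `outside` is the assumed value beyond the frame
oracle_erode_bin <- function(mask, se, outside = FALSE) {
  offs <- which(se$pattern, arr.ind = TRUE)
  offs[, 1] <- offs[, 1] - se$origin[1]
  offs[, 2] <- offs[, 2] - se$origin[2]
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (t in seq_len(nrow(offs))) {
      a <- i + offs[t, 1]; b <- j + offs[t, 2]
      v <- if (a >= 1 && a <= nr && b >= 1 && b <= nc) mask[a, b] else outside
      if (!v) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

# binary dilation: z kept iff the reflected SE translated to z overlaps
# foreground in at least one cell
oracle_dilate_bin <- function(mask, se) {
  offs <- which(se$pattern, arr.ind = TRUE)
  offs[, 1] <- se$origin[1] - offs[, 1]   # reflected
  offs[, 2] <- se$origin[2] - offs[, 2]
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (t in seq_len(nrow(offs))) {
      a <- i + offs[t, 1]; b <- j + offs[t, 2]
      if (a >= 1 && a <= nr && b >= 1 && b <= nc && mask[a, b]) {
        hit <- TRUE; break
      }
    }
    out[i, j] <- hit
  }
  out
}

# grayscale min / max filters; pixels outside the frame are ignored
oracle_erode_gray <- function(img, se) {
  offs <- which(se$pattern, arr.ind = TRUE)
  offs[, 1] <- offs[, 1] - se$origin[1]
  offs[, 2] <- offs[, 2] - se$origin[2]
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (t in seq_len(nrow(offs))) {
      a <- i + offs[t, 1]; b <- j + offs[t, 2]
      if (a >= 1 && a <= nr && b >= 1 && b <= nc) vals <- c(vals, img[a, b])
    }
    out[i, j] <- if (length(vals)) min(vals) else Inf
  }
  out
}

oracle_dilate_gray <- function(img, se) {
  offs <- which(se$pattern, arr.ind = TRUE)
  offs[, 1] <- se$origin[1] - offs[, 1]
  offs[, 2] <- se$origin[2] - offs[, 2]
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (t in seq_len(nrow(offs))) {
      a <- i + offs[t, 1]; b <- j + offs[t, 2]
      if (a >= 1 && a <= nr && b >= 1 && b <= nc) vals <- c(vals, img[a, b])
    }
    out[i, j] <- if (length(vals)) max(vals) else -Inf
  }
  out
}

# breadth-first flood fill labelling
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  nbr <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    k <- k + 1L
    queue <- list(c(i, j))
    lab[i, j] <- k
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (t in seq_len(nrow(nbr))) {
        a <- p[1] + nbr[t, 1]; b <- p[2] + nbr[t, 2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- k
          queue <- c(queue, list(c(a, b)))
        }
      }
    }
  }
  lab
}

# same partition? (labellings may number components differently)
same_labelling <- function(la, lb) {
  if (!identical(la != 0L, lb != 0L)) return(FALSE)
  fg <- which(la != 0L)
  if (!length(fg)) return(TRUE)
  pairs <- unique(cbind(la[fg], lb[fg]))
  !(anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
}

# centroid by explicit double loop
oracle_centroid <- function(img) {
  s <- 0; sx <- 0; sy <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    s <- s + img[i, j]
    sx <- sx + i * img[i, j]
    sy <- sy + j * img[i, j]
  }
  c(cx = sx / s, cy = sy / s)
}

# convenience builders
uniform_rgb <- function(nr, nc, r, g, b, bit_depth = 8L) {
  rgb_image(matrix(r, nr, nc), matrix(g, nr, nc), matrix(b, nr, nc),
            bit_depth = bit_depth)
}

random_mask <- function(nr, nc, p = 0.5) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

random_se <- function(max_dim = 5) {
  repeat {
    d1 <- sample.int(max_dim, 1)
    d2 <- sample.int(max_dim, 1)
    pat <- matrix(stats::runif(d1 * d2) < 0.6, d1, d2)
    if (any(pat)) break
  }
  struct_elem(pat, c(sample.int(d1, 1), sample.int(d2, 1)))
}

# all 512 3x3 binary masks
all_3x3_masks <- function() {
  lapply(0:511, function(code) {
    matrix(bitwAnd(bitwShiftR(code, 0:8), 1L) == 1L, 3, 3)
  })
}

# analytic disk raster (pixel centres)
disk_mask <- function(r, pad = 4L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  x <- seq_len(n) - ctr
  outer(x, x, function(a, b) a * a + b * b) <= r * r
}

square_mask <- function(s, pad = 4L) {
  m <- matrix(FALSE, s + 2L * pad, s + 2L * pad)
  m[pad + seq_len(s), pad + seq_len(s)] <- TRUE
  m
}
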