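# Parametric synthetic diseased-leaf generator with pixel-exact ground
# truth.  The silhouette is a polar curve r(theta) = R * (1 +
# a*cos(k*theta) + roughness * n(theta)) with seeded band-limited radial
# noise; symptom classes are painted in disjoint intensity bands so that
# thresholding at band midpoints recovers the class raster exactly.
# Class codes: 0 background, 1 tissue, 2 chlorotic, 3 necrotic, 4 white
# spot, 5 vein.

# 8-bit reference palettes; scaled to the working bit depth on render.
# Bands in the channel each pipeline thresholds are separated by well
# over 10% of the full scale (blue: tissue ~45 / panel ~250; green:
# necrotic ~34 / tissue ~150+).
lq_palette <- function(lighting) {
  if (lighting == "panel") {
    rbind(background = c(246, 246, 250),
          tissue     = c(60, 170, 45),
          chlorotic  = c(228, 212, 40),
          necrotic   = c(42, 34, 28),
          spot       = c(250, 250, 252),
          vein       = c(90, 160, 70))
  } else {
    rbind(background = c(252, 252, 253),
          tissue     = c(112, 150, 95),
          chlorotic  = c(205, 195, 80),
          necrotic   = c(42, 34, 28),
          spot       = c(250, 250, 250),
          vein       = c(228, 235, 185))
  }
}

run_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic leaf image
#'
#' Collects and validates the generator parameters.  The defaults give a
#' symptom-free leaf on a bright panel at the native frame size of the
#' imaging setup (1280 x 1024).
#'
#' @param width,height Frame size in pixels.
#' @param seed Integer seed; the image is bit-exactly reproducible from
#'   it.
#' @param radius Base silhouette radius in pixels (default
#'   `0.35 * min(width, height)`).
#' @param lobes,lobe_amp Lobe count and relative amplitude of the smooth
#'   silhouette modulation.
#' @param boundary_roughness Relative amplitude of seeded band-limited
#'   radial noise on the boundary (0 = smooth; ~0.3 = heavily deformed).
#' @param chlorosis_mode `"none"`, `"generalized"` (whole lamina yellows
#'   by `chlorosis_level`), or `"localized"` (only `chlorosis_quadrant`).
#' @param chlorosis_level Yellowing intensity in `[0, 1]`.
#' @param chlorosis_quadrant Quadrant 1--4 (relative to the silhouette
#'   centroid) for localized chlorosis.
#' @param necrotic_fraction,spot_fraction Target fractions of the
#'   silhouette covered by necrotic blobs / white spots; painted within
#'   +-1% of the request.
#' @param vein_depth Branching recursion depth of the venation tree
#'   (0 = no veins; veins render only under back-light).
#' @param lighting `"panel"` (front-lit on an opaque white panel) or
#'   `"backlit"` (LED panel behind the leaf; venation bright).
#' @param bit_depth Working bits per channel (8 or 10).
#' @param noise_amp Uniform pixel noise amplitude, in 8-bit units.
#' @return Object of class `leaf_spec`.
#' @export
leaf_spec <- function(width = 1280, height = 1024, seed = 1L, radius = NULL,
                      lobes = 5, lobe_amp = 0.07, boundary_roughness = 0,
                      chlorosis_mode = c("none", "generalized", "localized"),
                      chlorosis_level = 0, chlorosis_quadrant = 1,
                      necrotic_fraction = 0, spot_fraction = 0,
                      vein_depth = 0,
                      lighting = c("panel", "backlit"),
                      bit_depth = 8L, noise_amp = 3) {
  chlorosis_mode <- match.arg(chlorosis_mode)
  lighting <- match.arg(lighting)
  if (is.null(radius)) radius <- 0.35 * min(width, height)
  stopifnot(width >= 64, height >= 64, radius >= 20,
            lobe_amp >= 0, lobe_amp < 0.3,
            boundary_roughness >= 0, boundary_roughness <= 0.35,
            chlorosis_level >= 0, chlorosis_level <= 1,
            chlorosis_quadrant %in% 1:4,
            necrotic_fraction >= 0, spot_fraction >= 0,
            vein_depth >= 0, vein_depth <= 8)
  if (necrotic_fraction + spot_fraction > 0.9) {
    stop("infeasible spec: necrotic_fraction + spot_fraction > 0.9",
         call. = FALSE)
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         seed = as.integer(seed), radius = radius, lobes = lobes,
         lobe_amp = lobe_amp, boundary_roughness = boundary_roughness,
         chlorosis_mode = chlorosis_mode, chlorosis_level = chlorosis_level,
         chlorosis_quadrant = as.integer(chlorosis_quadrant),
         necrotic_fraction = necrotic_fraction,
         spot_fraction = spot_fraction, vein_depth = as.integer(vein_depth),
         lighting = lighting, bit_depth = as.integer(bit_depth),
         noise_amp = noise_amp),
    class = "leaf_spec"
  )
}

# paint random disks of class `class_id` onto `allowed` pixels until
# `target_frac` of the silhouette is covered; returns updated class
# raster.  Radii adapt to the remaining deficit, so the painted count
# lands within ~sqrt of the target above it.
paint_blobs <- function(class, sil_count, target_frac, class_id, allowed,
                        rmax, nr, nc) {
  target <- round(target_frac * sil_count)
  painted <- 0L
  tries <- 0L
  while (painted < target && tries < 10000L) {
    tries <- tries + 1L
    pool <- which(allowed)
    if (!length(pool)) break
    remaining <- target - painted
    r_d <- max(2L, min(as.integer(rmax), as.integer(ceiling(sqrt(remaining / pi)))))
    ctr <- pool[[sample.int(length(pool), 1L)]]
    ci <- ((ctr - 1L) %% nr) + 1L
    cj <- ((ctr - 1L) %/% nr) + 1L
    x <- (-r_d):r_d
    dd <- which(outer(x, x, function(a, b) a * a + b * b) <= r_d * r_d,
                arr.ind = TRUE)
    ii <- ci + x[dd[, 1]]
    jj <- cj + x[dd[, 2]]
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    idx <- (jj[ok] - 1L) * nr + ii[ok]
    idx <- idx[allowed[idx]]
    if (length(idx)) {
      class[idx] <- class_id
      allowed[idx] <- FALSE
      painted <- painted + length(idx)
    }
  }
  list(class = class, allowed = allowed, painted = painted)
}

# deterministic bifurcating venation tree; returns logical mask
draw_veins <- function(nr, nc, base, ang0, len0, depth) {
  mask <- matrix(FALSE, nr, nc)
  seg <- function(p0, p1, halfw) {
    len <- sqrt(sum((p1 - p0)^2))
    np <- max(2L, as.integer(ceiling(2 * len)))
    tt <- seq(0, 1, length.out = np)
    pis <- as.integer(round(p0[1] + tt * (p1[1] - p0[1])))
    pjs <- as.integer(round(p0[2] + tt * (p1[2] - p0[2])))
    x <- (-halfw):halfw
    off <- which(outer(x, x, function(a, b) a * a + b * b) <= halfw * halfw,
                 arr.ind = TRUE)
    oi <- x[off[, 1]]
    oj <- x[off[, 2]]
    ii <- rep(pis, each = length(oi)) + oi
    jj <- rep(pjs, each = length(oj)) + oj
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    mask[(jj[ok] - 1L) * nr + ii[ok]] <<- TRUE
  }
  grow <- function(p, ang, len, halfw, depth) {
    if (depth <= 0L || len < 3) return(invisible())
    p1 <- p + len * c(cos(ang), sin(ang))
    seg(p, p1, halfw)
    grow(p1, ang - 0.55, len * 0.62, max(1L, halfw - 1L), depth - 1L)
    grow(p1, ang + 0.62, len * 0.62, max(1L, halfw - 1L), depth - 1L)
  }
  grow(base, ang0, len0, 2L, depth)
  mask
}

#' Generate a synthetic leaf image with ground truth
#'
#' Renders the leaf described by a [leaf_spec()] and returns both the
#' image and the pixel-exact ground truth used by the validation suite.
#' Generation is deterministic: the same spec (including its seed) gives
#' a bit-identical image.
#'
#' @param spec A [leaf_spec()].
#' @return List with `image` (an [rgb_image()]), `truth` and `spec`.
#'   `truth` is a list: `class` (integer raster, 0 background, 1 tissue,
#'   2 chlorotic, 3 necrotic, 4 spot, 5 vein), `silhouette` (logical),
#'   `fractions` (realized necrotic/spot/vein fractions of the
#'   silhouette and chlorotic fraction per quadrant), `centroid`
#'   (silhouette centroid), `area_analytic` and `perimeter_analytic`
#'   (of the unperturbed polar silhouette), `seed`.
#' @export
generate_leaf <- function(spec) {
  stopifnot(inherits(spec, "leaf_spec"))
  run_with_seed(spec$seed, {
    nr <- spec$height
    nc <- spec$width
    cx <- (nr + 1) / 2
    cy <- (nc + 1) / 2
    R <- spec$radius

    # seeded boundary noise profile (drawn for every spec so that
    # roughness sweeps at a fixed seed share the same base shape)
    harm <- 4:11
    hcoef <- stats::runif(length(harm), -1, 1)
    hphase <- stats::runif(length(harm), 0, 2 * pi)
    ph0 <- stats::runif(1, 0, 2 * pi)
    nfun <- function(th) {
      acc <- 0
      for (t in seq_along(harm)) {
        acc <- acc + hcoef[t] * cos(harm[t] * th + hphase[t])
      }
      acc
    }
    thfine <- seq(0, 2 * pi, length.out = 4096L)
    nmax <- max(abs(nfun(thfine)))
    hcoef <- hcoef / nmax

    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dy <- rows - cx
    dx <- cols - cy
    th <- atan2(dx, dy)
    rho <- sqrt(dy * dy + dx * dx)
    rth <- R * (1 + spec$lobe_amp * cos(spec$lobes * th + ph0) +
                  spec$boundary_roughness * nfun(th))
    sil <- rho <= rth
    sil_count <- sum(sil)
    if (sil_count < 100L) stop("silhouette degenerate", call. = FALSE)

    # analytic area / perimeter of the unperturbed (roughness-free) curve
    r0 <- R * (1 + spec$lobe_amp * cos(spec$lobes * thfine + ph0))
    dr0 <- -R * spec$lobe_amp * spec$lobes * sin(spec$lobes * thfine + ph0)
    dth <- thfine[2] - thfine[1]
    area_analytic <- sum(0.5 * r0[-1]^2) * dth
    perimeter_analytic <- sum(sqrt(r0[-1]^2 + dr0[-1]^2)) * dth

    class <- matrix(0L, nr, nc)
    class[sil] <- 1L

    # silhouette centroid and quadrant raster (for localized chlorosis
    # and the per-quadrant ground truth)
    cs <- c(mean(rows[sil]), mean(cols[sil]))
    quad <- 1L + (rows >= cs[1]) * 2L + (cols >= cs[2]) * 1L

    if (spec$chlorosis_mode == "generalized" && spec$chlorosis_level > 0) {
      class[class == 1L] <- 2L
    } else if (spec$chlorosis_mode == "localized" && spec$chlorosis_level > 0) {
      class[class == 1L & quad == spec$chlorosis_quadrant] <- 2L
    }

    if (spec$lighting == "backlit" && spec$vein_depth > 0L) {
      veins <- draw_veins(nr, nc,
                          base = c(cx + 0.92 * R, cy),
                          ang0 = pi, len0 = 0.85 * R,  # (cos,sin)=(-1,0): up
                          depth = spec$vein_depth + 1L)
      class[veins & (class == 1L | class == 2L)] <- 5L
    }

    if (spec$necrotic_fraction > 0) {
      allowed <- class == 1L | class == 2L
      pb <- paint_blobs(class, sil_count, spec$necrotic_fraction, 3L,
                        allowed, rmax = 0.12 * R, nr, nc)
      class <- pb$class
    }

    if (spec$spot_fraction > 0) {
      # spots stay >= 1 px clear of the silhouette edge
      interior <- erode(sil, se_box(3))
      allowed <- (class == 1L | class == 2L) & interior
      pb <- paint_blobs(class, sil_count, spec$spot_fraction, 4L,
                        allowed, rmax = 0.12 * R, nr, nc)
      class <- pb$class
    }

    # render
    mx <- 2L^spec$bit_depth - 1L
    sc <- mx / 255
    pal <- lq_palette(spec$lighting) * sc
    lam <- spec$chlorosis_level
    pal["chlorotic", ] <- pal["tissue", ] +
      lam * (pal["chlorotic", ] - pal["tissue", ])
    chans <- vector("list", 3L)
    for (ch in 1:3) {
      lut <- pal[, ch][c("background", "tissue", "chlorotic", "necrotic",
                         "spot", "vein")]
      v <- matrix(lut[class + 1L], nr, nc)
      na <- spec$noise_amp * sc
      if (na > 0) {
        v <- v + matrix(stats::runif(nr * nc, -na, na), nr, nc)
      }
      chans[[ch]] <- round(pmin(pmax(v, 0), mx))
    }

    quad_chl <- vapply(1:4, function(k) {
      denom <- sum(sil & quad == k)
      if (denom == 0L) return(0)
      sum(class == 2L & quad == k) / denom
    }, numeric(1))

    truth <- list(
      class = class,
      silhouette = sil,
      fractions = list(
        necrotic = sum(class == 3L) / sil_count,
        spot = sum(class == 4L) / sil_count,
        vein = sum(class == 5L) / sil_count,
        chlorotic_quadrant = quad_chl,
        chlorosis_level = lam
      ),
      centroid = cs,
      area_analytic = area_analytic,
      perimeter_analytic = perimeter_analytic,
      seed = spec$seed
    )
    list(image = rgb_image(chans[[1]], chans[[2]], chans[[3]],
                           bit_depth = spec$bit_depth),
         truth = truth, spec = spec)
  })
}

#' Generate a named suite of synthetic leaves
#'
#' Presets sweep one symptom axis each, mirroring the experimental
#' progressions the pipelines are meant to resolve:
#' \describe{
#'   \item{chlorosis}{generalized levels 0, 0.3, 0.6, 1.0 plus one
#'     localized single-quadrant case.}
#'   \item{necrosis}{necrotic fractions 0, 5, 10, 25, 50\%.}
#'   \item{deformation}{boundary roughness 0, 0.1, 0.2, 0.3 at a
#'     fixed seed (same base shape).}
#'   \item{spots}{white-spot fractions 0, 2, 8, 20\%.}
#'   \item{mosaic}{back-lit, venation depth 2--6.}
#' }
#'
#' @param preset Preset name.
#' @param width,height Frame size.
#' @param seed Base seed; images use `seed`, `seed + 1`, ... except for
#'   the deformation sweep, which reuses `seed` so only roughness varies.
#' @return List of `generate_leaf()` results.
#' @export
generate_suite <- function(preset = c("chlorosis", "necrosis", "deformation",
                                      "spots", "mosaic"),
                           width = 1280, height = 1024, seed = 1L) {
  preset <- match.arg(preset)
  mk <- function(i, ...) {
    generate_leaf(leaf_spec(width = width, height = height, ...))
  }
  switch(preset,
    chlorosis = {
      lv <- c(0, 0.3, 0.6, 1.0)
      c(
        lapply(seq_along(lv), function(i) {
          mk(i, seed = seed + i - 1L, chlorosis_mode = "generalized",
             chlorosis_level = lv[i])
        }),
        list(mk(5, seed = seed + 4L, chlorosis_mode = "localized",
                chlorosis_level = 0.8, chlorosis_quadrant = 2L))
      )
    },
    necrosis = {
      fr <- c(0, 0.05, 0.10, 0.25, 0.50)
      lapply(seq_along(fr), function(i) {
        mk(i, seed = seed + i - 1L, necrotic_fraction = fr[i])
      })
    },
    deformation = {
      rg <- c(0, 0.1, 0.2, 0.3)
      lapply(seq_along(rg), function(i) {
        mk(i, seed = seed, boundary_roughness = rg[i])
      })
    },
    spots = {
      fr <- c(0, 0.02, 0.08, 0.20)
      lapply(seq_along(fr), function(i) {
        mk(i, seed = seed + i - 1L, spot_fraction = fr[i])
      })
    },
    mosaic = {
      dp <- 2:6
      lapply(seq_along(dp), function(i) {
        mk(i, seed = seed + i - 1L, lighting = "backlit", vein_depth = dp[i])
      })
    }
  )
}
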