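test_that("digital squares and single pixels measure by convention", {
  sq <- square_mask(5)
  m <- measure_area_perimeter(sq, method = "chain")
  expect_equal(m$area_px, 25)
  expect_equal(m$perimeter_px, 16)  # 4*(5-1) axial boundary steps

  one <- matrix(FALSE, 5, 5)
  one[3, 3] <- TRUE
  m1 <- measure_area_perimeter(one)
  expect_equal(m1$area_px, 1)
  expect_equal(m1$perimeter_px, 4)

  expect_error(measure_area_perimeter(matrix(FALSE, 3, 3)), "empty")
})

test_that("disk calibration: area within 1%, perimeter within 3%, index 1.00 +- 0.06", {
  d <- disk_mask(200L)
  m <- measure_area_perimeter(d)
  expect_lt(abs(m$area_px - pi * 200^2) / (pi * 200^2), 0.01)
  expect_lt(abs(m$perimeter_px - 2 * pi * 200) / (2 * pi * 200), 0.03)
  I <- m$perimeter_px^2 / (4 * pi * m$area_px)
  expect_lt(abs(I - 1), 0.06)
})

test_that("square calibration: index 4/pi +- 0.03 for a large axis-aligned square", {
  sq <- square_mask(300L)
  m <- measure_area_perimeter(sq)
  I <- m$perimeter_px^2 / (4 * pi * m$area_px)
  expect_lt(abs(I - 4 / pi), 0.03)
})

test_that("the disk index converges toward 1 as the radius doubles", {
  devs <- vapply(c(100L, 200L, 400L), function(r) {
    m <- measure_area_perimeter(disk_mask(r))
    abs(m$perimeter_px^2 / (4 * pi * m$area_px) - 1)
  }, numeric(1))
  expect_lt(devs[3], devs[1])       # discretization bias shrinks
  expect_true(all(devs < 0.06))
})

test_that("the index is rotation-robust within 5%", {
  rot_square <- function(s, ang) {
    n <- as.integer(s * 1.6) + 16L
    ctr <- (n + 1) / 2
    idx <- seq_len(n) - ctr
    th <- ang * pi / 180
    u <- outer(idx, idx, function(i, j) i * cos(th) + j * sin(th))
    v <- outer(idx, idx, function(i, j) -i * sin(th) + j * cos(th))
    abs(u) <= s / 2 & abs(v) <= s / 2
  }
  Is <- vapply(c(0, 15, 30, 45, 60, 90), function(a) {
    m <- measure_area_perimeter(rot_square(200, a))
    m$perimeter_px^2 / (4 * pi * m$area_px)
  }, numeric(1))
  expect_lt(max(abs(Is / Is[1] - 1)), 0.05)
})

test_that("holes are filled before measuring: only the outer contour counts", {
  d <- disk_mask(60L)
  holed <- d
  holed[55:70, 55:70] <- FALSE
  ma <- measure_area_perimeter(d)
  mb <- measure_area_perimeter(holed)
  expect_equal(ma$area_px, mb$area_px)
  expect_equal(ma$perimeter_px, mb$perimeter_px)
})

test_that("deformation index from images reproduces the sweep ordering (healthy lowest)", {
  suite <- generate_suite("deformation", width = 448, height = 384, seed = 6)
  Is <- vapply(suite, function(s) quantify_deformation(s$image)$index,
               numeric(1))
  expect_true(all(diff(Is) > 0))  # strictly increasing with roughness
  expect_lt(Is[1], 1.15)          # smooth lobed leaf stays near circular
})

test_that("the index is scale-invariant across rasterizations of the same shape", {
  Ia <- quantify_deformation(generate_leaf(
    leaf_spec(width = 256, height = 224, seed = 9, boundary_roughness = 0.15))$image)$index
  Ib <- quantify_deformation(generate_leaf(
    leaf_spec(width = 512, height = 448, seed = 9, boundary_roughness = 0.15,
              radius = 2 * 0.35 * 224))$image)$index
  expect_lt(abs(Ia - Ib) / Ib, 0.08)
})
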