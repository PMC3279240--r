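test_that("a zero-symptom spec yields a pure leaf with all-zero truth fractions", {
  g <- generate_leaf(leaf_spec(width = 256, height = 224, seed = 1))
  fr <- g$truth$fractions
  expect_equal(fr$necrotic, 0)
  expect_equal(fr$spot, 0)
  expect_equal(fr$vein, 0)
  expect_true(all(fr$chlorotic_quadrant == 0))
  expect_true(all(g$truth$class[g$truth$silhouette] == 1L))
  expect_true(all(g$truth$class[!g$truth$silhouette] == 0L))
})

test_that("generation is bit-exact per seed and leaves the global RNG stream alone", {
  s <- leaf_spec(width = 256, height = 224, seed = 42,
                 necrotic_fraction = 0.1, spot_fraction = 0.05,
                 boundary_roughness = 0.1)
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  g1 <- generate_leaf(s)
  mid <- runif(1)
  g2 <- generate_leaf(s)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$truth$class, g2$truth$class)
  expect_identical(before, mid)  # generator restores the caller's stream

  g3 <- generate_leaf(leaf_spec(width = 256, height = 224, seed = 43,
                                necrotic_fraction = 0.1, spot_fraction = 0.05,
                                boundary_roughness = 0.1))
  expect_false(identical(g1$image, g3$image))
})

test_that("painted class fractions land within 1% of the request", {
  for (seed in c(2, 9)) {
    g <- generate_leaf(leaf_spec(width = 384, height = 320, seed = seed,
                                 necrotic_fraction = 0.10,
                                 spot_fraction = 0.08))
    expect_lt(abs(g$truth$fractions$necrotic - 0.10), 0.01)
    expect_lt(abs(g$truth$fractions$spot - 0.08), 0.01)
  }
})

test_that("infeasible symptom loads are rejected", {
  expect_error(leaf_spec(necrotic_fraction = 0.6, spot_fraction = 0.5),
               "infeasible")
})

test_that("intensity bands are separated: midpoint thresholds recover the classes exactly", {
  g <- generate_leaf(leaf_spec(width = 320, height = 288, seed = 7,
                               necrotic_fraction = 0.15, spot_fraction = 0.05))
  img <- g$image
  cls <- g$truth$class
  # blue channel: {tissue, necrotic} dark vs {background, spot} bright
  bright <- binarize(extract_channel(img, "blue"), 0.8 * img$max_value, "above")
  expect_identical(bright, cls == 0L | cls == 4L)
  # green channel: necrotic dark vs everything else on the leaf
  dark_green <- binarize(extract_channel(img, "green"),
                         0.35 * img$max_value, "below")
  expect_identical(dark_green & g$truth$silhouette, cls == 3L)
})

test_that("silhouette area and perimeter match the analytic polar curve within 1%", {
  g <- generate_leaf(leaf_spec(width = 512, height = 448, seed = 3))
  m <- measure_area_perimeter(g$truth$silhouette)
  expect_lt(abs(m$area_px - g$truth$area_analytic) / g$truth$area_analytic,
            0.01)
  expect_lt(abs(m$perimeter_px - g$truth$perimeter_analytic) /
              g$truth$perimeter_analytic, 0.01)
})

test_that("presets define the advertised sweeps and all pass their pipelines", {
  def <- generate_suite("deformation", width = 256, height = 224, seed = 5)
  rough <- vapply(def, function(s) s$spec$boundary_roughness, numeric(1))
  expect_true(all(diff(rough) > 0))

  chl <- generate_suite("chlorosis", width = 256, height = 224, seed = 5)
  modes <- vapply(chl, function(s) s$spec$chlorosis_mode, character(1))
  expect_equal(sum(modes == "localized"), 1L)

  expect_error(generate_suite("nonesuch"))

  # smoke: every preset image passes its own pipeline without error
  for (s in def) expect_s3_class(quantify_deformation(s$image),
                                 "deformation_result")
  for (s in chl) {
    expect_s3_class(quantify_chlorosis(s$image,
                                       leaf_mask = segment_leaf(s$image)),
                    "chlorosis_result")
  }
})

test_that("10-bit rendering scales the palette onto the 0..1023 range", {
  g8 <- generate_leaf(leaf_spec(width = 256, height = 224, seed = 2))
  g10 <- generate_leaf(leaf_spec(width = 256, height = 224, seed = 2,
                                 bit_depth = 10))
  expect_equal(g10$image$max_value, 1023L)
  expect_gt(max(g10$image$blue), 900)
  expect_identical(g8$truth$class, g10$truth$class)
  # pipelines accept both depths with fraction-scaled thresholds
  expect_equal(quantify_necrosis(g10$image)$a_n,
               quantify_necrosis(g8$image)$a_n, tolerance = 0.2)
})
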