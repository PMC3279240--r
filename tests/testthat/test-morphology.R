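test_that("structuring element constructors and reflection behave", {
  expect_equal(sum(se_box(3)$pattern), 9L)
  expect_equal(sum(se_cross(3)$pattern), 5L)
  expect_equal(sum(se_disk(1)$pattern), 5L)  # radius-1 disk = cross
  expect_error(struct_elem(matrix(FALSE, 2, 2)), "at least one")

  set.seed(5)
  for (rep in 1:10) {
    se <- random_se()
    rr <- se_reflect(se_reflect(se))
    expect_equal(rr$pattern, se$pattern)
    expect_equal(rr$origin, se$origin)
  }
})

test_that("structuring elements parse from the text grid format", {
  se <- se_parse(c("010", "121", "010"))
  expect_equal(se$pattern, se_cross(3)$pattern)
  expect_equal(se$origin, c(2L, 2L))

  # off-centre background origin
  se2 <- se_parse(c("o1", "11"))
  expect_false(se2$pattern[1, 1])
  expect_equal(se2$origin, c(1L, 1L))

  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("111", "121", "111"), f)
  expect_equal(se_read(f)$pattern, se_box(3)$pattern)
  expect_error(se_parse(c("01", "011")), "ragged")
})

test_that("erosion and dilation match their textbook special cases", {
  m <- matrix(TRUE, 3, 3)
  e <- erode(m, se_box(3))
  expect_equal(sum(e), 1L)
  expect_true(e[2, 2])  # only the centre survives a 3x3 box

  one <- struct_elem(matrix(TRUE, 1, 1))
  expect_equal(erode(m, one), m)
  expect_equal(dilate(m, one), m)

  pt <- matrix(FALSE, 5, 5)
  pt[3, 3] <- TRUE
  expect_equal(sum(dilate(pt, se_box(3))), 9L)
})

test_that("all six operators equal the brute-force oracles exhaustively on 3x3 masks", {
  se <- se_cross(3)
  for (m in all_3x3_masks()) {
    e <- oracle_erode_bin(m, se)
    d <- oracle_dilate_bin(m, se)
    expect_identical(erode(m, se), e)
    expect_identical(dilate(m, se), d)
    expect_identical(opening(m, se), oracle_dilate_bin(e, se))
    # closing on the infinite plane: compute the oracle on a padded frame
    big <- matrix(FALSE, 7, 7)
    big[3:5, 3:5] <- m
    clos <- oracle_erode_bin(oracle_dilate_bin(big, se), se)[3:5, 3:5]
    expect_identical(closing(m, se), clos)
  }
})

test_that("operators equal the oracles on random grayscale images and random elements", {
  set.seed(77)
  for (rep in 1:20) {
    img <- matrix(runif(256, 0, 255), 16, 16)
    se <- random_se(5)
    expect_equal(erode(img, se), oracle_erode_gray(img, se))
    expect_equal(dilate(img, se), oracle_dilate_gray(img, se))
    expect_equal(opening(img, se),
                 oracle_dilate_gray(oracle_erode_gray(img, se), se))
    expect_equal(top_hat(img, se), img - opening(img, se))
    expect_equal(bottom_hat(img, se), closing(img, se) - img)
  }
})

test_that("binary duality: dilation is the complement of eroding the complement", {
  set.seed(13)
  for (rep in 1:25) {
    m <- random_mask(16, 16, runif(1, 0.2, 0.8))
    se <- random_se(5)
    expect_identical(dilate(m, se),
                     !erode(!m, se_reflect(se), pad = "foreground"))
  }
})

test_that("grayscale duality: dilation is the negation of eroding the negation", {
  set.seed(14)
  for (rep in 1:10) {
    img <- matrix(runif(144, 0, 100), 12, 12)
    se <- random_se(5)
    expect_equal(dilate(img, se), -erode(-img, se_reflect(se)))
  }
})

test_that("opening is anti-extensive, increasing and idempotent; closing extensive and idempotent", {
  set.seed(99)
  for (rep in 1:50) {
    se <- random_se(4)
    m <- random_mask(12, 12, runif(1, 0.3, 0.7))
    om <- opening(m, se)
    cm <- closing(m, se)
    expect_true(all(om <= m))            # anti-extensive
    expect_true(all(cm >= m))            # extensive
    expect_identical(opening(om, se), om)  # idempotent
    expect_identical(closing(cm, se), cm)

    img <- matrix(runif(144, 0, 255), 12, 12)
    oi <- opening(img, se)
    ci <- closing(img, se)
    expect_true(all(oi <= img + 1e-12))
    expect_true(all(ci >= img - 1e-12))
    expect_equal(opening(oi, se), oi)
    expect_equal(closing(ci, se), ci)

    # increasing: img <= img2 pointwise => opening(img) <= opening(img2)
    img2 <- img + matrix(runif(144, 0, 50), 12, 12)
    expect_true(all(opening(img, se) <= opening(img2, se) + 1e-12))
  }
})

test_that("top-hat and bottom-hat are non-negative and vanish on constants", {
  cst <- matrix(42, 10, 10)
  expect_true(all(top_hat(cst, se_disk(2)) == 0))
  expect_true(all(bottom_hat(cst, se_disk(2)) == 0))

  set.seed(31)
  for (rep in 1:10) {
    img <- matrix(runif(100, 0, 1023), 10, 10)
    se <- random_se(4)
    expect_true(all(top_hat(img, se) >= -1e-12))
    expect_true(all(bottom_hat(img, se) >= -1e-12))
  }
})

test_that("opening removes specks smaller than the element, keeps large solids, fills work dually", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE  # isolated speck
  expect_false(any(opening(m, se_box(3))))

  solid <- matrix(FALSE, 9, 9)
  solid[3:7, 3:7] <- TRUE
  expect_identical(opening(solid, se_box(3)), solid)

  holed <- solid
  holed[5, 5] <- FALSE
  expect_identical(closing(holed, se_box(3)), solid)  # hole filled
  expect_identical(closing(holed, struct_elem(matrix(TRUE, 1, 1))), holed)
})

test_that("top-hat isolates a thin bright ridge; bottom-hat a thin dark valley", {
  img <- matrix(10, 15, 15)
  img[8, ] <- 200  # one-pixel bright ridge
  th <- top_hat(img, se_box(5))
  expect_true(all(th[8, ] == 190))
  expect_true(all(th[-8, ] == 0))

  img2 <- matrix(200, 15, 15)
  img2[8, ] <- 10  # dark valley
  bh <- bottom_hat(img2, se_box(5))
  expect_true(all(bh[8, ] == 190))
  expect_true(all(bh[-8, ] == 0))
})

test_that("binary operators agree with an independent imaging library", {
  skip_if_not_installed("EBImage")
  set.seed(55)
  kern <- EBImage::makeBrush(3, "box")
  for (rep in 1:5) {
    m <- random_mask(20, 20, 0.55)
    got <- dilate(m, se_box(3))
    ref <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), kern)) > 0.5
    expect_equal(unname(got), unname(as.matrix(ref)))
  }
})
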