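test_that("tip profiles follow their closed forms", {
  pt <- build_tip("point", pixel_size_nm = 0.5)
  expect_identical(dim(pt$profile), c(1L, 1L))
  expect_identical(pt$profile[1, 1], 0)

  s2 <- build_tip("sphere", 2, 0.5)
  ctr <- (dim(s2$profile) + 1L) %/% 2L
  expect_identical(s2$profile[ctr[1], ctr[2]], 0)          # apex
  expect_equal(s2$profile[ctr[1], ctr[2] + 4L], -2)        # r = R = 2 nm
  expect_true(all(s2$profile <= 0, na.rm = TRUE))

  s10 <- build_tip("sphere", 10, 0.5)
  ctr <- (dim(s10$profile) + 1L) %/% 2L
  expect_equal(s10$profile[ctr[1], ctr[2] + 12L], -(10 - 8))  # r = 6 nm

  pb <- build_tip("paraboloid", 5, 0.5)
  ctr <- (dim(pb$profile) + 1L) %/% 2L
  expect_equal(pb$profile[ctr[1], ctr[2] + 4L], -(2^2) / (2 * 5))
})

test_that("dilation matches the brute-force double-loop oracle exactly", {
  set.seed(7)
  for (tip in list(build_tip("sphere", 2, 0.5),
                   build_tip("paraboloid", 3, 0.5))) {
    v <- matrix(rnorm(48 * 64, sd = 2), 48, 64)
    m <- height_map(v, 0.5)
    expect_identical(tip_dilate(m, tip)$values, oracle_dilate(v, tip$profile))
  }
})

test_that("dilation is extensive, monotone, and point-tip is the identity", {
  set.seed(1)
  v <- matrix(rnorm(40 * 40), 40, 40)
  m <- height_map(v, 0.5)
  tip <- build_tip("sphere", 3, 0.5)

  expect_identical(tip_dilate(m, build_tip("point", pixel_size_nm = 0.5))$values, v)
  expect_true(all(tip_dilate(m, tip)$values >= v))

  b <- height_map(v + abs(rnorm(1600, 0.5)), 0.5)  # b >= v pointwise
  expect_true(all(tip_dilate(b, tip)$values >= tip_dilate(m, tip)$values))

  # commutes with adding a constant
  expect_equal(tip_dilate(height_map(v + 3.7, 0.5), tip)$values,
               tip_dilate(m, tip)$values + 3.7)
})

test_that("a spike dilates to the circle-geometry contact width", {
  h <- 3; R <- 5; d <- 0.5
  v <- matrix(0, 41, 41); v[21, 21] <- h
  out <- tip_dilate(height_map(v, d), build_tip("sphere", R, d))$values
  half_width <- sqrt(h * (2 * R - h))          # contact half-width, nm
  on_row <- which(out[21, ] > 1e-12)
  expect_equal(length(on_row), 2 * floor(half_width / d) + 1)
  expect_equal(out[21, 21], h)
})

test_that("dilation validates pixel sizes and tip support", {
  m <- height_map(matrix(0, 20, 20), 0.5)
  expect_error(tip_dilate(m, build_tip("sphere", 2, 0.4)), "pixel size")
  expect_error(tip_dilate(m, build_tip("sphere", 8, 0.5)), "support")
})

test_that("erosion closes what dilation opened", {
  set.seed(3)
  v <- matrix(rnorm(50 * 50), 50, 50)
  m <- height_map(v, 0.5)
  tip <- build_tip("sphere", 2, 0.5)
  img <- tip_dilate(m, tip)
  rec <- tip_erode(img, tip)
  # closing is extensive: reconstruction never digs below the true surface
  expect_true(all(rec$values >= v - 1e-12))
  # morphological filter idempotence: re-imaging the reconstruction is stable
  expect_equal(tip_dilate(rec, tip)$values, img$values, tolerance = 1e-12)
})
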