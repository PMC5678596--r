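rgb_frame <- function(r, g, b) {
  px <- array(0, c(2, 2, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  px
}

test_that("colour-space conversion matches HSV/Lab definitions", {
  red <- convert_space(rgb_frame(255, 0, 0), "HSV")
  expect_equal(red[1, 1, ], c(0, 1, 1))
  grey <- convert_space(rgb_frame(128, 128, 128), "HSV")
  expect_equal(grey[1, 1, 2], 0)  # achromatic
  green <- convert_space(rgb_frame(0, 255, 0), "HSV")
  expect_equal(green[1, 1, 1], 120)  # closed-form hue
  # Lab: white is L=100, a=b=0; channel scales as documented
  white <- convert_space(rgb_frame(255, 255, 255), "Lab")
  expect_equal(white[1, 1, 1], 100, tolerance = 1e-3)
  expect_equal(white[1, 1, 2], 0, tolerance = 0.01)
  expect_equal(white[1, 1, 3], 0, tolerance = 0.01)
  expect_error(convert_space(matrix(5, 4, 4), "HSV"), "single-channel")
})

test_that("range thresholding is conjunctive, inclusive, and hue-wrapping", {
  px <- rgb_frame(10, 200, 30)
  full <- threshold_spec("RGB", c(0, 255, 0, 255, 0, 255))
  expect_true(all(threshold_ranges(px, full)))
  empty <- threshold_spec("RGB", c(200, 100, 0, 255, 0, 255))  # low > high
  expect_false(any(threshold_ranges(px, empty)))
  # hue wrap: red (hue 0) caught by [350, 10]
  wrap <- threshold_spec("HSV", c(350, 10, 0, 1, 0, 1))
  expect_true(all(threshold_ranges(rgb_frame(255, 0, 0), wrap)))
  expect_false(any(threshold_ranges(rgb_frame(0, 255, 0), wrap)))
})

test_that("thresholding green disks on brown soil recovers the rasterised area", {
  sc <- small_scene()
  f <- sc$session$frames[[1]]
  spec <- threshold_spec("HSV", c(90, 150, 0.2, 1, 0.1, 1))
  mask <- clean_mask(threshold_ranges(f, spec), 25, TRUE)
  truth <- sc$truth$masks[[1]] > 0
  expect_gte(dice(mask, truth), 0.97)
  expect_equal(sum(mask), sum(truth), tolerance = 0.02)
})

test_that("widening a channel range never removes foreground (monotonicity)", {
  sc <- small_scene()
  f <- sc$session$frames[[1]]
  narrow <- threshold_ranges(f, threshold_spec("HSV", c(100, 140, 0.3, 0.9, 0.2, 0.8)))
  for (wider in list(c(90, 150, 0.3, 0.9, 0.2, 0.8),
                     c(100, 140, 0.1, 1.0, 0.2, 0.8),
                     c(100, 140, 0.3, 0.9, 0.0, 1.0))) {
    m <- threshold_ranges(f, threshold_spec("HSV", wider))
    expect_true(all(m[narrow]))
  }
})

test_that("Otsu equals exhaustive between-class-variance search on random images", {
  set.seed(2024)
  agree <- 0L
  for (k in 1:100) {
    g <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    if (otsu_threshold(g)$threshold == otsu_exhaustive(g)) agree <- agree + 1L
  }
  expect_equal(agree, 100L)
})

test_that("Otsu handles the half/half and constant cases", {
  g <- matrix(c(rep(0, 128), rep(255, 128)), 16, 16)
  res <- otsu_threshold(g)
  # every cut between the two values separates perfectly; ties break to the
  # smallest maximiser, and the mask is exactly the 255-valued pixels
  expect_true(res$threshold >= 0 && res$threshold < 255)
  expect_identical(res$mask, g == 255)
  expect_error(otsu_threshold(matrix(7, 8, 8)), "degenerate histogram")
})

test_that("Otsu agrees with EBImage's implementation on a bimodal image", {
  set.seed(9)
  g <- matrix(round(c(rnorm(300, 60, 10), rnorm(212, 190, 12))), 16, 32)
  g <- pmin(pmax(g, 0), 255)
  ours <- otsu_threshold(g)$threshold
  theirs <- EBImage::otsu(EBImage::Image(t(g) / 255), range = c(0, 1), levels = 256)
  expect_equal(ours, round(theirs * 255), tolerance = 1)
})

test_that("clean_mask removes speckle, fills holes, and is identity at zero", {
  m <- matrix(FALSE, 40, 40)
  m[10:29, 10:29] <- TRUE              # 400-px blob
  m[35, 35] <- TRUE                    # 1-px speckle
  expect_identical(clean_mask(m, 0, FALSE), m)
  cleaned <- clean_mask(m, 50, FALSE)
  expect_false(cleaned[35, 35])
  expect_equal(sum(cleaned), 400)
  expect_true(all(cleaned[clean_mask(m, 50, FALSE)]))  # subset when not filling

  # annulus: filling adds exactly the hole area
  d <- sqrt((row(matrix(0, 41, 41)) - 21)^2 + (col(matrix(0, 41, 41)) - 21)^2)
  ann <- d <= 15 & d >= 8
  hole <- sum(d < 8)
  filled <- clean_mask(ann, 0, TRUE)
  expect_equal(sum(filled) - sum(ann), hole)
  expect_true(all(filled[d <= 15]))
})
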