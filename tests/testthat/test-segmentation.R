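# Color-component threshold segmentation and ROI placement.

test_that("gray thresholding follows the >= rule", {
  img <- matrix(c(10, 100, 200), 1, 3)
  expect_equal(as.vector(unclass(threshold_gray(img, 100))), c(0L, 1L, 1L))
  expect_true(all(unclass(threshold_gray(img, 0)) == 1L))
  expect_true(all(unclass(threshold_gray(matrix(254, 2, 2), 255)) == 0L))
})

test_that("published component bounds classify anchor pixels correctly", {
  tt <- threshold_table()
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  in_mask <- function(p, row) unclass(segment_component(p, tt$rows[[row]]))[1, 1] == 1L
  # a saturated warm pixel belongs to the red (hot-spot) component
  expect_true(in_mask(px(240, 100, 50), "red"))
  # pure white matches none of the three rows
  expect_false(any(vapply(c("red", "green", "blue"),
                          function(r) in_mask(px(255, 255, 255), r),
                          logical(1))))
  # pure black satisfies only the blue row
  expect_true(in_mask(px(0, 0, 0), "blue"))
  expect_false(in_mask(px(0, 0, 0), "red"))
  expect_false(in_mask(px(0, 0, 0), "green"))
})

test_that("segmentation equals a brute-force per-pixel range check", {
  tt <- threshold_table()
  set.seed(21)
  for (rep in 1:3) {
    img <- array(sample(0:255, 32 * 32 * 3, replace = TRUE),
                 dim = c(32, 32, 3))
    for (nm in names(tt$rows)) {
      got <- segment_component(img, tt$rows[[nm]])
      expect_identical(matrix(unclass(got), 32, 32),
                       brute_component_mask(img, tt$rows[[nm]]),
                       info = nm)
    }
  }
})

test_that("masks are idempotent and non-exclusive with a union bound", {
  tt <- threshold_table()
  img <- make_preset_image("normal", 34.62, seed = 4)
  seg <- segment_all(img, tt)
  total <- unclass(seg$masks$red) + unclass(seg$masks$green) +
    unclass(seg$masks$blue)
  expect_true(all(total <= 3))
  # idempotence: segmenting the masked component image again re-selects
  # every masked pixel
  for (nm in c("green", "blue")) {
    m <- unclass(seg$masks[[nm]])
    comp <- img
    for (ch in 1:3) comp[, , ch] <- comp[, , ch] * m
    m2 <- unclass(segment_component(comp, tt$rows[[nm]]))
    expect_true(all(m2[m == 1L] == 1L), info = nm)
  }
  # all-black image has an empty red component
  black <- array(0L, dim = c(8, 8, 3))
  expect_equal(attr(segment_component(black, tt$rows$red), "fraction"), 0)
})

test_that("red-to-gray uses Rec. 601 luminance and zeroes unmasked pixels", {
  img <- array(0L, dim = c(1, 3, 3))
  img[1, 1, ] <- c(255L, 0L, 0L)
  img[1, 2, ] <- c(255L, 255L, 255L)
  img[1, 3, ] <- c(10L, 200L, 30L)
  mask <- matrix(c(1L, 1L, 0L), 1, 3)
  g <- red_to_gray(img, mask)
  expect_equal(g[1, 1], 76L)   # round(0.2989 * 255)
  expect_equal(g[1, 2], 255L)  # weights sum to ~1
  expect_equal(g[1, 3], 0L)    # unmasked
  expect_error(red_to_gray(img, matrix(1L, 2, 2)),
               class = "tonguetherm_error_input")
})

test_that("centre ROI placement: image centre, centroid, and fallbacks", {
  img <- matrix(0, 256, 256)
  roi <- center_roi(img, 40, 48)
  expect_equal(c(roi$row0, roi$col0), c(108L, 104L))
  # centroid-driven placement
  mask <- matrix(0L, 256, 256)
  mask[101, 101] <- 1L  # centroid at 0-based (100, 100)
  roi2 <- center_roi(img, 40, 48, tongue_mask = mask)
  # even-sized ROI cannot centre exactly; ties round toward top-left
  expect_equal(c(roi2$row0, roi2$col0), c(80L, 76L))
  # degenerate empty mask falls back to the image centre
  roi3 <- center_roi(img, 40, 48, tongue_mask = matrix(0L, 256, 256))
  expect_equal(c(roi3$row0, roi3$col0), c(108L, 104L))
  expect_error(center_roi(matrix(0, 30, 30), 40, 48),
               class = "tonguetherm_error_roi")
})

test_that("threshold tables survive a JSON round trip", {
  tt <- threshold_table(include_white = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_threshold_json(tt, path)
  back <- read_threshold_json(path)
  for (nm in names(tt$rows)) {
    expect_identical(back$rows[[nm]]$r, tt$rows[[nm]]$r)
    expect_identical(back$rows[[nm]]$g, tt$rows[[nm]]$g)
    expect_identical(back$rows[[nm]]$b, tt$rows[[nm]]$b)
  }
})
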