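#' Per-component RGB channel thresholds
#'
#' A color component (red, green or blue -- i.e. hot-spot, mid-temperature
#' and cold-spot bands of the rendered thermogram) is defined by an inclusive
#' `[min, max]` interval on each of the three RGB channels; a pixel belongs
#' to the component iff all three channel values fall inside their intervals.
#'
#' @param component `"red"`, `"green"`, `"blue"` or `"white"`.
#' @param r,g,b Length-2 integer vectors `c(min, max)`, each within 0..255.
#' @return An object of class `channel_thresholds`.
#' @examples
#' channel_thresholds("red", c(222, 252), c(0, 176), c(0, 122))
#' @export
channel_thresholds <- function(component, r, g, b) {
  component <- match.arg(component, c("red", "green", "blue", "white"))
  for (ch in list(r = r, g = g, b = b)) {
    if (length(ch) != 2L || any(ch < 0) || any(ch > 255) || ch[1] > ch[2]) {
      abort("Channel bounds must satisfy 0 <= min <= max <= 255.",
            class = "tonguetherm_error_input")
    }
  }
  structure(
    list(component = component,
         r = as.integer(r), g = as.integer(g), b = as.integer(b)),
    class = "channel_thresholds"
  )
}

#' Threshold table for color-component segmentation
#'
#' The default rows reproduce the published per-component bounds exactly:
#'
#' | component | R min | R max | G min | G max | B min | B max |
#' |-----------|-------|-------|-------|-------|-------|-------|
#' | red       | 222   | 252   | 0     | 176   | 0     | 122   |
#' | green     | 8     | 255   | 165   | 255   | 6     | 96    |
#' | blue      | 0     | 28    | 0     | 161   | 0     | 255   |
#'
#' Components are not mutually exclusive (the green row's R range overlaps
#' the red row's for some pixels); masks are computed independently. An
#' optional fourth "white" rule (all channels >= 240) is available for
#' coated-tongue regions but is off by default, as an extrapolation beyond
#' the published table.
#'
#' @param rows A named list of [channel_thresholds()], one per component.
#' @param include_white Add the optional white rule.
#' @return An object of class `threshold_table`.
#' @export
threshold_table <- function(rows = NULL, include_white = FALSE) {
  if (is.null(rows)) {
    rows <- list(
      red = channel_thresholds("red", c(222, 252), c(0, 176), c(0, 122)),
      green = channel_thresholds("green", c(8, 255), c(165, 255), c(6, 96)),
      blue = channel_thresholds("blue", c(0, 28), c(0, 161), c(0, 255))
    )
    if (include_white) {
      rows$white <- channel_thresholds("white", c(240, 255), c(240, 255),
                                       c(240, 255))
    }
  }
  if (!all(c("red", "green", "blue") %in% names(rows))) {
    abort("A threshold table needs red, green and blue rows.",
          class = "tonguetherm_error_input")
  }
  structure(list(rows = rows), class = "threshold_table")
}

#' Binary thresholding of a gray image
#'
#' The single-threshold rule: output 1 where the gray level is >= `T`,
#' 0 elsewhere.
#'
#' @param img Numeric matrix of gray levels 0..255 (a `gray_image`).
#' @param T Threshold gray level in 0..255.
#' @return A `component_mask` (0/1 integer matrix).
#' @examples
#' threshold_gray(matrix(c(10, 100, 200), 1), 100) # 0 1 1
#' @export
threshold_gray <- function(img, T) {
  stopifnot_scalar_number(T, "T", min = 0, max = 255)
  m <- as_gray_matrix(img)
  new_component_mask((m >= T) * 1L, component = "gray")
}

new_component_mask <- function(m, component) {
  structure(matrix(as.integer(m), nrow(m), ncol(m)),
            class = c("component_mask", "matrix"),
            component = component, fraction = mean(m))
}

as_gray_matrix <- function(img) {
  if (inherits(img, "gray_image") || (is.matrix(img) && is.numeric(img))) {
    return(unclass(img))
  }
  abort("Expected a gray image (numeric matrix).",
        class = "tonguetherm_error_input")
}

#' Segment one color component of a thermogram
#'
#' A pixel belongs to the component mask iff its R, G and B values each lie
#' inside the row's inclusive `[min, max]` interval.
#'
#' @param img A `color_thermogram` (H x W x 3, 8-bit).
#' @param th A [channel_thresholds()] row.
#' @return A `component_mask` with attributes `component` and `fraction`
#'   (mean of the mask).
#' @export
segment_component <- function(img, th) {
  if (!inherits(th, "channel_thresholds")) {
    abort("`th` must be a `channel_thresholds` row.",
          class = "tonguetherm_error_input")
  }
  if (!is_rgb_array(img)) {
    abort("`img` must be an H x W x 3 RGB array.",
          class = "tonguetherm_error_input")
  }
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  m <- (r >= th$r[1] & r <= th$r[2] &
        g >= th$g[1] & g <= th$g[2] &
        b >= th$b[1] & b <= th$b[2]) * 1L
  new_component_mask(matrix(m, dim(img)[1], dim(img)[2]), th$component)
}

#' Segment a thermogram into all color components
#'
#' Applies every row of the threshold table independently (masks are
#' non-exclusive) and reports per-component pixel fractions.
#'
#' @param img A `color_thermogram`.
#' @param table A [threshold_table()].
#' @return A list with `masks` (named list of `component_mask`) and
#'   `fractions` (a tibble with `component`, `fraction`).
#' @export
segment_all <- function(img, table = threshold_table()) {
  if (!inherits(table, "threshold_table")) {
    abort("`table` must be a `threshold_table`.",
          class = "tonguetherm_error_input")
  }
  masks <- purrr::map(table$rows, ~segment_component(img, .x))
  fractions <- tibble::tibble(
    component = names(masks),
    fraction = purrr::map_dbl(masks, ~attr(.x, "fraction"))
  )
  list(masks = masks, fractions = fractions)
}

#' Convert the red (hot-spot) component to grayscale
#'
#' Pixels inside the mask are converted to luminance
#' `0.2989 R + 0.5870 G + 0.1140 B` (Rec. 601 weights), rounded to the
#' nearest integer; pixels outside the mask become 0.
#'
#' @param img A `color_thermogram`.
#' @param red_mask A `component_mask` of the same height/width.
#' @return A `gray_image` (integer matrix in 0..255).
#' @export
red_to_gray <- function(img, red_mask) {
  if (!is_rgb_array(img)) {
    abort("`img` must be an H x W x 3 RGB array.",
          class = "tonguetherm_error_input")
  }
  if (!all(dim(red_mask) == dim(img)[1:2])) {
    abort("Mask and image shapes differ.", class = "tonguetherm_error_input")
  }
  lum <- 0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3]
  out <- matrix(as.integer(round(lum)), dim(img)[1], dim(img)[2])
  out[unclass(red_mask) == 0L] <- 0L
  structure(out, class = c("gray_image", "matrix"))
}

#' Whole-image grayscale conversion
#'
#' Luminance conversion of the full thermogram (no component masking); the
#' fallback used when the red component is empty over the ROI.
#'
#' @param img A `color_thermogram`.
#' @return A `gray_image`.
#' @export
rgb_to_gray <- function(img) {
  red_to_gray(img, matrix(1L, dim(img)[1], dim(img)[2]))
}

#' Place the centre region of interest
#'
#' Returns an ROI of the requested size centred on the tongue-mask centroid
#' when a non-empty mask is given, else on the image centre. Tie positions
#' round toward the top-left. An empty mask falls back to the image centre.
#'
#' @param img Any image (matrix or H x W x 3 array) defining the bounds.
#' @param roi_h,roi_w ROI size in pixels.
#' @param tongue_mask Optional 0/1 matrix marking tongue pixels.
#' @return An [roi_spec()].
#' @examples
#' center_roi(matrix(0, 256, 256), 40, 48) # top-left (108, 104)
#' @export
center_roi <- function(img, roi_h, roi_w, tongue_mask = NULL) {
  d <- if (is.matrix(img)) dim(img) else dim(img)[1:2]
  stopifnot_scalar_number(roi_h, "roi_h", min = 1)
  stopifnot_scalar_number(roi_w, "roi_w", min = 1)
  if (roi_h > d[1] || roi_w > d[2]) {
    abort("ROI larger than the image.", class = "tonguetherm_error_roi")
  }
  if (!is.null(tongue_mask) && sum(tongue_mask) > 0) {
    idx <- which(unclass(tongue_mask) == 1L, arr.ind = TRUE)
    centre <- c(mean(idx[, 1]), mean(idx[, 2])) - 1  # 0-based centroid
  } else {
    centre <- c((d[1] - 1) / 2, (d[2] - 1) / 2)
  }
  row0 <- min(max(0, floor(centre[1] - (roi_h - 1) / 2)), d[1] - roi_h)
  col0 <- min(max(0, floor(centre[2] - (roi_w - 1) / 2)), d[2] - roi_w)
  roi_spec(row0, col0, roi_h, roi_w)
}

#' Write a component mask as a PNG (0/255)
#'
#' @param mask A `component_mask`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(unclass(mask) * 1.0, path)
  invisible(path)
}

#' Threshold-table JSON serialization
#'
#' @param table A [threshold_table()].
#' @param path File path.
#' @return `write_threshold_json()` returns `path` invisibly;
#'   `read_threshold_json()` a `threshold_table`.
#' @export
write_threshold_json <- function(table, path) {
  obj <- purrr::map(table$rows, function(row) {
    list(r = row$r, g = row$g, b = row$b)
  })
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_json
#' @export
read_threshold_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- purrr::imap(obj, function(row, nm) {
    channel_thresholds(nm, row$r, row$g, row$b)
  })
  threshold_table(rows = rows)
}
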