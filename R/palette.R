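#' Rainbow palette for thermogram rendering
#'
#' Constructs the 256-entry blue-to-red rainbow palette used to render a
#' [temperature_field()] into a false-color thermogram and to invert foreign
#' thermograms back to temperatures. Hue sweeps linearly from 240 deg (blue,
#' coldest) to 0 deg (red, hottest). Saturation and value default slightly
#' below 1 so that rendered colors fall inside the component bounds of the
#' default [threshold_table()]: a fully saturated sweep emits channel values
#' 0 and 255, which the red-component row (max 252) and green-component row
#' (mins 8 and 6) can never match.
#'
#' The temperature scale is fixed (the acquisition protocol keeps one scale
#' for all subjects); it defaults to 28-38 deg C and is configurable.
#'
#' @param t_min,t_max Temperature bounds of the color scale (deg C).
#' @param saturation,value HSV saturation and value of the sweep, in (0, 1].
#' @return An object of class `thermo_palette`: a list with `colors`
#'   (256 x 3 integer matrix of 8-bit RGB rows) and `t_min`, `t_max`.
#' @examples
#' pal <- rainbow_palette()
#' pal$colors[1, ]   # coldest entry: blue
#' pal$colors[256, ] # hottest entry: red
#' @export
rainbow_palette <- function(t_min = 28, t_max = 38,
                            saturation = 0.96, value = 252 / 255) {
  stopifnot_scalar_number(t_min, "t_min")
  stopifnot_scalar_number(t_max, "t_max")
  if (t_min >= t_max) {
    abort("`t_min` must be strictly below `t_max`.",
          class = "tonguetherm_error_input")
  }
  stopifnot_scalar_number(saturation, "saturation", min = 0, max = 1)
  stopifnot_scalar_number(value, "value", min = 0, max = 1)
  hue <- 240 * (1 - (0:255) / 255) / 360
  hex <- grDevices::hsv(h = hue, s = saturation, v = value)
  colors <- t(grDevices::col2rgb(hex))
  colnames(colors) <- c("r", "g", "b")
  structure(
    list(colors = colors, t_min = t_min, t_max = t_max),
    class = "thermo_palette"
  )
}

validate_palette <- function(palette) {
  if (!inherits(palette, "thermo_palette")) {
    abort("`palette` must be a `thermo_palette` (see `rainbow_palette()`).",
          class = "tonguetherm_error_input")
  }
  if (nrow(palette$colors) != 256L || ncol(palette$colors) != 3L) {
    abort("Palette must hold 256 RGB entries.",
          class = "tonguetherm_error_input")
  }
  if (anyDuplicated(palette$colors)) {
    abort("Palette entries must be distinct for single-valued inversion.",
          class = "tonguetherm_error_input")
  }
  invisible(palette)
}

#' Render a temperature field as a color thermogram
#'
#' Each pixel temperature is clamped to the palette scale, binned linearly
#' into 256 levels and mapped to the corresponding palette entry.
#'
#' @param field A [temperature_field()] (numeric matrix of deg C).
#' @param palette A [rainbow_palette()].
#' @return A `color_thermogram`: an H x W x 3 integer array of 8-bit RGB
#'   values carrying the palette used as an attribute.
#' @examples
#' f <- temperature_field(matrix(seq(28, 38, length.out = 64 * 64), 64, 64))
#' img <- temp_to_rgb(f, rainbow_palette())
#' dim(img)
#' @export
temp_to_rgb <- function(field, palette = rainbow_palette()) {
  validate_palette(palette)
  m <- as_field_matrix(field)
  idx <- palette_bin(m, palette)
  img <- array(0L, dim = c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) {
    img[, , ch] <- matrix(palette$colors[idx + 1L, ch], nrow(m), ncol(m))
  }
  structure(img, class = "color_thermogram", palette = palette)
}

# Linear binning of temperatures into palette levels 0..255.
palette_bin <- function(m, palette) {
  tcl <- pmin(pmax(m, palette$t_min), palette$t_max)
  idx <- floor((tcl - palette$t_min) / (palette$t_max - palette$t_min) * 256)
  pmin(as.integer(idx), 255L)
}

#' Invert a color thermogram to a temperature field
#'
#' Maps each pixel to the temperature midpoint of the nearest palette entry
#' (Euclidean distance in RGB space). For images rendered with the same
#' palette the round-trip error is at most half a quantization step,
#' `(t_max - t_min) / 512`.
#'
#' @param img A `color_thermogram` or any H x W x 3 array of 8-bit RGB values.
#' @param palette A [rainbow_palette()].
#' @return A [temperature_field()].
#' @examples
#' pal <- rainbow_palette()
#' f <- temperature_field(matrix(34.5, 32, 32))
#' max(abs(rgb_to_temp(temp_to_rgb(f, pal), pal) - 34.5)) < 10 / 512
#' @export
rgb_to_temp <- function(img, palette = rainbow_palette()) {
  validate_palette(palette)
  if (!is_rgb_array(img)) {
    abort("`img` must be an H x W x 3 RGB array.",
          class = "tonguetherm_error_input")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  key <- as.vector(img[, , 1]) * 65536 + as.vector(img[, , 2]) * 256 +
    as.vector(img[, , 3])
  uk <- unique(key)
  ur <- uk %/% 65536; ug <- (uk %/% 256) %% 256; ub <- uk %% 256
  pc <- palette$colors
  # nearest palette entry per unique color (exact Euclidean search)
  d2 <- outer(ur, pc[, 1], "-")^2 + outer(ug, pc[, 2], "-")^2 +
    outer(ub, pc[, 3], "-")^2
  nearest <- max.col(-d2, ties.method = "first") - 1L
  step <- (palette$t_max - palette$t_min) / 256
  utemp <- palette$t_min + (nearest + 0.5) * step
  temps <- utemp[match(key, uk)]
  temperature_field(matrix(temps, h, w))
}

#' Read or write a palette as JSON
#'
#' Serializes the 256 RGB triples together with the scale bounds, so a
#' rendering palette can travel with the images it produced.
#'
#' @param palette A [rainbow_palette()].
#' @param path File path.
#' @return `write_palette_json()` returns `path` invisibly;
#'   `read_palette_json()` returns a `thermo_palette`.
#' @export
write_palette_json <- function(palette, path) {
  validate_palette(palette)
  obj <- list(
    t_min = palette$t_min, t_max = palette$t_max,
    colors = unname(apply(palette$colors, 1, as.integer, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_palette_json
#' @export
read_palette_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  colors <- matrix(as.integer(obj$colors), 256, 3)
  colnames(colors) <- c("r", "g", "b")
  structure(
    list(colors = colors, t_min = obj$t_min, t_max = obj$t_max),
    class = "thermo_palette"
  )
}
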