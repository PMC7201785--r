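#' Temperature field
#'
#' The latent object a thermogram renders: an H x W matrix of surface
#' temperatures in deg C, optionally with a spatial calibration (mm per
#' pixel) used to convert physical region-of-interest sizes to pixels.
#'
#' @param m Numeric matrix of temperatures (deg C), all finite.
#' @param mm_per_pixel Optional spatial calibration (mm per pixel).
#' @return An object of class `thermo_field` (a numeric matrix).
#' @examples
#' f <- temperature_field(matrix(34.6, 64, 64), mm_per_pixel = 0.25)
#' @export
temperature_field <- function(m, mm_per_pixel = NULL) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) < 1L || ncol(m) < 1L) {
    abort("`m` must be a non-empty numeric matrix.",
          class = "tonguetherm_error_input")
  }
  if (!all(is.finite(m))) {
    abort("Temperature fields must be finite everywhere.",
          class = "tonguetherm_error_input")
  }
  if (!is.null(mm_per_pixel)) {
    stopifnot_scalar_number(mm_per_pixel, "mm_per_pixel", min = 1e-9)
  }
  structure(m, class = c("thermo_field", "matrix"),
            mm_per_pixel = mm_per_pixel)
}

as_field_matrix <- function(field) {
  if (inherits(field, "thermo_field") || (is.matrix(field) && is.numeric(field))) {
    m <- unclass(field)
    attr(m, "mm_per_pixel") <- NULL
    return(m)
  }
  abort("Expected a `thermo_field` or numeric matrix.",
        class = "tonguetherm_error_input")
}

#' Rectangular region of interest
#'
#' Pixel rectangles are 0-based, row-major and half-open:
#' rows `[row0, row0 + height)`, columns `[col0, col0 + width)`.
#'
#' @param row0,col0 Top-left corner (0-based pixel indices).
#' @param height,width Extent in pixels (positive integers).
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(108, 104, 40, 48)
#' @export
roi_spec <- function(row0, col0, height, width) {
  stopifnot_scalar_number(row0, "row0", min = 0)
  stopifnot_scalar_number(col0, "col0", min = 0)
  stopifnot_scalar_number(height, "height", min = 1)
  stopifnot_scalar_number(width, "width", min = 1)
  structure(
    list(row0 = as.integer(row0), col0 = as.integer(col0),
         height = as.integer(height), width = as.integer(width)),
    class = "roi_spec"
  )
}

check_roi_inside <- function(roi, nr, nc) {
  if (!inherits(roi, "roi_spec")) {
    abort("`roi` must be an `roi_spec`.", class = "tonguetherm_error_input")
  }
  if (roi$row0 + roi$height > nr || roi$col0 + roi$width > nc) {
    abort(
      sprintf("ROI [%d,%d) x [%d,%d) lies outside a %d x %d image.",
              roi$row0, roi$row0 + roi$height, roi$col0, roi$col0 + roi$width,
              nr, nc),
      class = "tonguetherm_error_roi"
    )
  }
  invisible(roi)
}

roi_rows <- function(roi) (roi$row0 + 1L):(roi$row0 + roi$height)
roi_cols <- function(roi) (roi$col0 + 1L):(roi$col0 + roi$width)

#' Mean temperature over a rectangular ROI
#'
#' The arithmetic mean of the field values inside the half-open pixel
#' rectangle; this is the "area tool" measurement reported per subject.
#'
#' @param field A [temperature_field()].
#' @param roi An [roi_spec()], fully inside the field.
#' @return Mean temperature (deg C).
#' @examples
#' f <- temperature_field(matrix(c(34, 35, 36, 37), 2, 2))
#' mean_roi_temperature(f, roi_spec(0, 0, 2, 2)) # 35.5
#' @export
mean_roi_temperature <- function(field, roi) {
  m <- as_field_matrix(field)
  check_roi_inside(roi, nrow(m), ncol(m))
  mean(m[roi_rows(roi), roi_cols(roi)])
}

#' Read and write temperature fields as CSV matrices
#'
#' Plain numeric CSV (no header): one row per pixel row, values in deg C.
#'
#' @param field A [temperature_field()].
#' @param path File path.
#' @param mm_per_pixel Optional calibration to attach on read.
#' @return `write_field_csv()` returns `path` invisibly; `read_field_csv()`
#'   a `thermo_field`.
#' @export
write_field_csv <- function(field, path) {
  m <- as_field_matrix(field)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path, mm_per_pixel = NULL) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  temperature_field(m, mm_per_pixel = mm_per_pixel)
}

#' Read and write 8-bit RGB thermogram images
#'
#' PNG or TIFF, selected by file extension. Images are stored as standard
#' 8-bit RGB; the palette is not embedded (serialize it with
#' [write_palette_json()] alongside).
#'
#' @param img A `color_thermogram` or H x W x 3 array of values in 0..255.
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `write_thermogram()` returns `path` invisibly;
#'   `read_thermogram()` returns a `color_thermogram`.
#' @export
write_thermogram <- function(img, path) {
  if (!is_rgb_array(img)) {
    abort("`img` must be an H x W x 3 RGB array.",
          class = "tonguetherm_error_input")
  }
  arr <- img / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    abort("Unsupported image extension; use .png, .tif or .tiff.",
          class = "tonguetherm_error_input")
  }
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image file does not exist: %s", path),
          class = "tonguetherm_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    if (ext == "png") {
      png::readPNG(path)
    } else if (ext %in% c("tif", "tiff")) {
      res <- tiff::readTIFF(path)
      if (is.list(res)) res[[1]] else res
    } else {
      abort("Unsupported image extension; use .png, .tif or .tiff.",
            class = "tonguetherm_error_input")
    },
    error = function(e) {
      abort(sprintf("Could not decode image %s: %s", path, conditionMessage(e)),
            class = "tonguetherm_error_io")
    }
  )
  if (length(dim(arr)) == 2L) {
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  }
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  img <- array(as.integer(round(arr * 255)), dim = dim(arr))
  structure(img, class = "color_thermogram", palette = NULL)
}
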