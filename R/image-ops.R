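# Preprocessing: resize to the working resolution and Gaussian smoothing.

# Corner-aligned bilinear interpolation of a single channel matrix.
bilinear_resize_matrix <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  src_r <- if (out_h == 1L) rep((in_h - 1) / 2, 1L) else
    (seq_len(out_h) - 1) * (in_h - 1) / (out_h - 1)
  src_c <- if (out_w == 1L) rep((in_w - 1) / 2, 1L) else
    (seq_len(out_w) - 1) * (in_w - 1) / (out_w - 1)
  r0 <- pmin(floor(src_r), in_h - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(src_c), in_w - 2); c0 <- pmax(c0, 0)
  if (in_h == 1L) r0 <- rep(0, out_h)
  if (in_w == 1L) c0 <- rep(0, out_w)
  fr <- src_r - r0; fc <- src_c - c0
  r1 <- pmin(r0 + 1, in_h - 1); c1 <- pmin(c0 + 1, in_w - 1)
  # gather the four corners as out_h x out_w matrices
  m00 <- m[r0 + 1, c0 + 1, drop = FALSE]
  m01 <- m[r0 + 1, c1 + 1, drop = FALSE]
  m10 <- m[r1 + 1, c0 + 1, drop = FALSE]
  m11 <- m[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, out_h, out_w)
  wc <- matrix(fc, out_h, out_w, byrow = TRUE)
  m00 * (1 - wr) * (1 - wc) + m01 * (1 - wr) * wc +
    m10 * wr * (1 - wc) + m11 * wr * wc
}

#' Resize an RGB image
#'
#' Per-channel corner-aligned bilinear interpolation; [resize_256()] is the
#' pipeline's standard step that brings every thermogram to the 256 x 256
#' working resolution.
#'
#' @param img A `color_thermogram` or H x W x 3 array (8-bit values).
#' @param height,width Output size in pixels.
#' @return A `color_thermogram` of the requested size.
#' @examples
#' img <- temp_to_rgb(temperature_field(matrix(35, 64, 64)))
#' dim(resize_256(img))
#' @export
resize_rgb <- function(img, height, width) {
  if (!is_rgb_array(img) || dim(img)[1] < 1L || dim(img)[2] < 1L) {
    abort("`img` must be a non-empty H x W x 3 RGB array.",
          class = "tonguetherm_error_input")
  }
  stopifnot_scalar_number(height, "height", min = 1)
  stopifnot_scalar_number(width, "width", min = 1)
  out <- array(0L, dim = c(height, width, 3L))
  for (ch in 1:3) {
    out[, , ch] <- as.integer(round(
      bilinear_resize_matrix(img[, , ch], height, width)
    ))
  }
  structure(out, class = "color_thermogram", palette = attr(img, "palette"))
}

#' @rdname resize_rgb
#' @export
resize_256 <- function(img) resize_rgb(img, 256L, 256L)

# Reflect (mirror without repeating the edge pixel) index into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j >= n, period - j, j) + 1L)
}

gaussian_kernel <- function(sigma) {
  radius <- ceiling(3 * sigma)
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian convolution of one matrix with reflect padding.
gaussian_smooth_matrix <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  radius <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (o in -radius:radius) {
    out <- out + k[o + radius + 1L] * m[reflect_index(seq_len(nr) + o, nr), ]
  }
  res <- matrix(0, nr, nc)
  for (o in -radius:radius) {
    res <- res + k[o + radius + 1L] * out[, reflect_index(seq_len(nc) + o, nc)]
  }
  res
}

#' Gaussian smoothing of an RGB thermogram
#'
#' Per-channel convolution with a normalized Gaussian kernel of radius
#' `ceiling(3 * sigma)`, reflect-padded at the borders (so constant images
#' pass through unchanged and channel means are preserved up to rounding).
#'
#' @param img A `color_thermogram` or H x W x 3 array.
#' @param sigma Kernel standard deviation in pixels (> 0); default 1.
#' @return A smoothed `color_thermogram`.
#' @export
gaussian_smooth <- function(img, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.",
          class = "tonguetherm_error_input")
  }
  if (!is_rgb_array(img)) {
    abort("`img` must be an H x W x 3 RGB array.",
          class = "tonguetherm_error_input")
  }
  out <- array(0L, dim = dim(img))
  for (ch in 1:3) {
    out[, , ch] <- as.integer(round(gaussian_smooth_matrix(img[, , ch], sigma)))
  }
  out[out < 0L] <- 0L
  out[out > 255L] <- 255L
  structure(out, class = "color_thermogram", palette = attr(img, "palette"))
}
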