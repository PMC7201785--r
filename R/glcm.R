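#' GLCM configuration
#'
#' Defaults follow the most common co-occurrence convention: `n_levels = 8`
#' gray levels, offset `(0, 1)` (horizontal neighbour at distance 1),
#' symmetric, normalized.
#'
#' @param n_levels Number of gray levels N (>= 2).
#' @param offset Integer pair `c(drow, dcol)`, not `(0, 0)`.
#' @param symmetric Add the transposed pair counts.
#' @param normalize Divide counts by their total so entries sum to 1.
#' @param literal_entropy Use the literal entropy form `sum(-ln P)` over
#'   nonzero cells instead of the standard Shannon `-sum(P ln P)`; see
#'   [glcm_entropy()].
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(n_levels = 8L, offset = c(0L, 1L), symmetric = TRUE,
                        normalize = TRUE, literal_entropy = FALSE) {
  stopifnot_scalar_number(n_levels, "n_levels", min = 2)
  if (length(offset) != 2L || all(offset == 0)) {
    abort("`offset` must be a nonzero integer pair.",
          class = "tonguetherm_error_input")
  }
  structure(
    list(n_levels = as.integer(n_levels), offset = as.integer(offset),
         symmetric = isTRUE(symmetric), normalize = isTRUE(normalize),
         literal_entropy = isTRUE(literal_entropy)),
    class = "glcm_config"
  )
}

#' Quantize a gray image to N levels
#'
#' Uniform binning of the 8-bit range `[0, 255]` into `n_levels` bins; value
#' 255 maps to the top level `n_levels - 1`, and `n_levels = 256` is the
#' identity.
#'
#' @param img A `gray_image` (matrix of values 0..255).
#' @param n_levels Number of levels (>= 2).
#' @return An integer matrix of levels `0 .. n_levels - 1`.
#' @examples
#' quantize(matrix(c(0, 255), 1), 2) # 0 1
#' @export
quantize <- function(img, n_levels) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2) {
    abort("`n_levels` must be an integer >= 2.",
          class = "tonguetherm_error_input")
  }
  m <- as_gray_matrix(img)
  q <- floor(m / 256 * n_levels)
  matrix(as.integer(pmin(q, n_levels - 1L)), nrow(m), ncol(m))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs `(p, p + offset)` of quantized levels over all pixel
#' positions where both ends fall inside the image; optionally symmetrizes
#' (adds the transpose) and normalizes to probabilities.
#'
#' @param img A quantized integer matrix (levels `0 .. n_levels - 1`, e.g.
#'   from [quantize()]).
#' @param cfg A [glcm_config()].
#' @return An N x N matrix of class `glcm` with attribute `normalized`.
#' @examples
#' q <- matrix(c(0L, 1L, 0L, 1L), 2, 2)           # 2-level checkerboard
#' compute_glcm(q, glcm_config(n_levels = 2))     # [[0, .5], [.5, 0]]
#' @export
compute_glcm <- function(img, cfg = glcm_config()) {
  m <- if (is.matrix(img)) img else as_gray_matrix(img)
  n <- cfg$n_levels
  if (any(m < 0) || any(m >= n)) {
    abort("Image levels must lie in 0 .. n_levels - 1; quantize first.",
          class = "tonguetherm_error_input")
  }
  dr <- cfg$offset[1]; dc <- cfg$offset[2]
  h <- nrow(m); w <- ncol(m)
  r_from <- max(1L, 1L - dr):min(h, h - dr)
  c_from <- max(1L, 1L - dc):min(w, w - dc)
  if (length(r_from) < 1L || length(c_from) < 1L ||
      min(r_from) > max(r_from) || (h - abs(dr)) < 1L || (w - abs(dc)) < 1L) {
    abort("No valid pixel pair exists at this offset.",
          class = "tonguetherm_error_glcm")
  }
  a <- m[r_from, c_from, drop = FALSE]
  b <- m[r_from + dr, c_from + dc, drop = FALSE]
  tab <- table(factor(a, levels = 0:(n - 1L)), factor(b, levels = 0:(n - 1L)))
  counts <- matrix(as.numeric(tab), n, n)
  if (cfg$symmetric) counts <- counts + t(counts)
  if (cfg$normalize) counts <- counts / sum(counts)
  structure(counts, class = c("glcm", "matrix"),
            normalized = cfg$normalize, config = cfg)
}

check_normalized_glcm <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p) || any(p < 0)) {
    abort("`p` must be a square nonnegative GLCM.",
          class = "tonguetherm_error_glcm")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort("GLCM must be normalized (entries summing to 1).",
          class = "tonguetherm_error_glcm")
  }
  invisible(p)
}

glcm_grids <- function(p) {
  n <- nrow(p)
  i <- matrix(0:(n - 1), n, n)            # row index grid
  j <- matrix(0:(n - 1), n, n, byrow = TRUE)
  list(i = i, j = j)
}

# Marginal mean of a (symmetric) normalized GLCM over the row index.
glcm_mu <- function(p) {
  g <- glcm_grids(p)
  sum(g$i * p)
}

#' GLCM texture features
#'
#' The individual co-occurrence statistics computed from a normalized GLCM
#' `P(i, j)` with levels `i, j = 0 .. N-1`, marginal mean `mu` and marginal
#' variance `sigma^2` (of a symmetric GLCM, row and column marginals agree):
#'
#' * `glcm_contrast()`: `sum P(i,j) (i - j)^2`
#' * `glcm_correlation()`: `sum P(i,j) (i - mu)(j - mu) / sigma^2`
#' * `glcm_energy()`: `sum P(i,j)^2`
#' * `glcm_homogeneity()`: `sum P(i,j) / (1 + (i - j)^2)`
#' * `glcm_mean()`: `sum i P(i,j)`
#' * `glcm_variance()`: `sum P(i,j) (i - mu)^2`
#' * `glcm_std()`: square root of the variance
#' * `glcm_entropy()`: Shannon entropy `-sum P ln P` over nonzero cells by
#'   default. The literal printed form `sum(-ln P)` diverges for any zero
#'   cell; with `literal = TRUE` it is applied over the nonzero cells only.
#'
#' A constant image gives a single-cell GLCM: contrast 0, energy 1,
#' homogeneity 1, variance 0, and an undefined correlation (`NA`, since
#' `sigma = 0`).
#'
#' @param p A normalized `glcm`.
#' @param literal For `glcm_entropy()`: use the literal summed negative-log
#'   form.
#' @return A finite scalar (or `NA` with a warning where undefined).
#' @name glcm-features
NULL

#' @rdname glcm-features
#' @export
glcm_contrast <- function(p) {
  check_normalized_glcm(p)
  g <- glcm_grids(p)
  sum(p * (g$i - g$j)^2)
}

#' @rdname glcm-features
#' @export
glcm_correlation <- function(p) {
  check_normalized_glcm(p)
  g <- glcm_grids(p)
  mu <- glcm_mu(p)
  s2 <- sum(p * (g$i - mu)^2)
  if (s2 <= 0) {
    warn("GLCM correlation undefined for a zero-variance GLCM.",
         class = "tonguetherm_warning_degenerate")
    return(NA_real_)
  }
  sum(p * (g$i - mu) * (g$j - mu)) / s2
}

#' @rdname glcm-features
#' @export
glcm_energy <- function(p) {
  check_normalized_glcm(p)
  sum(p^2)
}

#' @rdname glcm-features
#' @export
glcm_homogeneity <- function(p) {
  check_normalized_glcm(p)
  g <- glcm_grids(p)
  sum(p / (1 + (g$i - g$j)^2))
}

#' @rdname glcm-features
#' @export
glcm_mean <- function(p) {
  check_normalized_glcm(p)
  glcm_mu(p)
}

#' @rdname glcm-features
#' @export
glcm_variance <- function(p) {
  check_normalized_glcm(p)
  g <- glcm_grids(p)
  mu <- glcm_mu(p)
  sum(p * (g$i - mu)^2)
}

#' @rdname glcm-features
#' @export
glcm_std <- function(p) {
  sqrt(glcm_variance(p))
}

#' @rdname glcm-features
#' @export
glcm_entropy <- function(p, literal = FALSE) {
  check_normalized_glcm(p)
  nz <- p[p > 0]
  if (literal) sum(-log(nz)) else -sum(nz * log(nz))
}

#' Intensity skewness and kurtosis of ROI pixel values
#'
#' Population-moment ratios over the raw pixel values `X_i` (n pixels):
#' skewness `sum((X - mu)^3) / (n sigma^3)` and kurtosis
#' `sum((X - mu)^4) / (n sigma^4)` with `sigma` the population standard
#' deviation. No excess-kurtosis subtraction is applied (a standard normal
#' sample has kurtosis close to 3).
#'
#' @param x Numeric vector of pixel values, `length(x) >= 2`.
#' @return A scalar; errors when the values have zero variance.
#' @examples
#' intensity_skewness(c(1, 2, 3)) # 0 (symmetric)
#' @export
intensity_skewness <- function(x) {
  ms <- population_moments(x)
  sum((x - ms$mu)^3) / (length(x) * ms$sigma^3)
}

#' @rdname intensity_skewness
#' @export
intensity_kurtosis <- function(x) {
  ms <- population_moments(x)
  sum((x - ms$mu)^4) / (length(x) * ms$sigma^4)
}

population_moments <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    abort("Need at least two pixel values.", class = "tonguetherm_error_input")
  }
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) {
    abort(paste(
      "Zero variance: the ROI is constant, so skewness/kurtosis are",
      "undefined. Enlarge the ROI or check the segmentation fallback."
    ), class = "tonguetherm_error_degenerate")
  }
  list(mu = mu, sigma = sqrt(s2))
}

#' Extract the full texture-feature vector from a grayscale ROI
#'
#' Computes the GLCM of the (quantized) ROI and all ten texture features,
#' plus the mean ROI temperature when the matching temperature-field crop is
#' supplied. Features of a degenerate (constant) ROI that are undefined
#' (correlation, skewness, kurtosis) are returned as `NA` with
#' `degenerate = TRUE` -- never silently zeroed.
#'
#' @param gray_roi A `gray_image` crop (the ROI).
#' @param field_roi Optional matching [temperature_field()] crop; its mean
#'   becomes `roi_temp`.
#' @param cfg A [glcm_config()].
#' @return A one-row tibble: `contrast`, `correlation`, `energy`,
#'   `homogeneity`, `glcm_mean`, `std_dev`, `entropy`, `skewness`,
#'   `variance`, `kurtosis`, `roi_temp`, `degenerate`.
#' @export
extract_features <- function(gray_roi, field_roi = NULL, cfg = glcm_config()) {
  m <- as_gray_matrix(gray_roi)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("ROI too small for texture extraction.",
          class = "tonguetherm_error_input")
  }
  q <- quantize(m, cfg$n_levels)
  p <- compute_glcm(q, cfg)
  x <- as.vector(m)
  degenerate <- (stats::var(x) == 0)
  skw <- krt <- NA_real_
  if (!degenerate) {
    skw <- intensity_skewness(x)
    krt <- intensity_kurtosis(x)
  } else {
    warn("Constant ROI: correlation, skewness and kurtosis are undefined.",
         class = "tonguetherm_warning_degenerate")
  }
  corr <- if (degenerate) NA_real_ else {
    withCallingHandlers(
      glcm_correlation(p),
      tonguetherm_warning_degenerate = function(w) invokeRestart("muffleWarning")
    )
  }
  roi_temp <- if (is.null(field_roi)) NA_real_ else mean(as_field_matrix(field_roi))
  tibble::tibble(
    contrast = glcm_contrast(p),
    correlation = corr,
    energy = glcm_energy(p),
    homogeneity = glcm_homogeneity(p),
    glcm_mean = glcm_mean(p),
    std_dev = glcm_std(p),
    entropy = glcm_entropy(p, literal = cfg$literal_entropy),
    skewness = skw,
    variance = glcm_variance(p),
    kurtosis = krt,
    roi_temp = roi_temp,
    degenerate = degenerate
  )
}

#' Dump a GLCM as CSV (debugging aid)
#'
#' @param p A `glcm`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_glcm_csv <- function(p, path) {
  utils::write.table(unclass(p), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
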