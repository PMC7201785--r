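#' Morphology preset for synthetic tongue temperature fields
#'
#' Controls the spatial structure of a generated field: tongue ellipse size,
#' number/shape/strength of warm and cold spots, ambient background and pixel
#' noise. The two presets encode the qualitative morphology reported for the
#' two groups: diabetic tongues show heat concentrated at the centre and no
#' cold spots; normal tongues show diffuse warm patterns plus one or more
#' cold spots.
#'
#' Spot amplitudes are calibrated to the rendering scale: under the default
#' 28-38 deg C palette a pixel only enters the blue component band of the
#' default [threshold_table()] roughly 5 deg C below the tongue base
#' temperature, and the red (hot-spot) band roughly 1.5 deg C above it. The
#' normal preset therefore uses deep cold spots (-7 deg C) and mild scattered
#' warmth (+1 deg C, rarely red), while the diabetic preset uses a compact
#' intense centre spot (+2.5 deg C, reliably red) and no cold spots --
#' reproducing the reported group morphology: diabetic heat concentrated at
#' the tongue centre with no cold spots, normal tongues diffusely warm with
#' cold spots. Scattered spots are placed with a minimum separation of two
#' sigma so amplitudes do not stack.
#'
#' @param group `"normal"` or `"diabetic"` (selects the preset), or `NULL`
#'   with all fields given explicitly.
#' @param ellipse_axes Full tongue-ellipse axes as fractions of frame
#'   height/width (each in (0, 1]).
#' @param hot_n,hot_amp,hot_sigma Warm-spot count, amplitude (deg C) and
#'   Gaussian sigma (fraction of the smaller frame dimension).
#' @param cold_n,cold_amp,cold_sigma Cold-spot count, amplitude (deg C,
#'   negative) and sigma.
#' @param ambient_c Background (ambient) temperature, deg C.
#' @param noise_sd Pixel noise SD inside the tongue, deg C.
#' @param edge_drop Smooth temperature drop from tongue centre to rim, deg C.
#' @return An object of class `phenotype_spec`.
#' @examples
#' phenotype_spec("diabetic")$cold_n  # 0
#' phenotype_spec("normal")$cold_n    # >= 1
#' @export
phenotype_spec <- function(group = NULL,
                           ellipse_axes = c(0.70, 0.76),
                           hot_n = NULL, hot_amp = NULL, hot_sigma = NULL,
                           cold_n = NULL, cold_amp = -7, cold_sigma = 0.05,
                           ambient_c = 22.5, noise_sd = 0.15,
                           edge_drop = 0.8) {
  if (!is.null(group)) {
    group <- match.arg(group, c("normal", "diabetic"))
    if (group == "diabetic") {
      if (is.null(hot_n)) hot_n <- 1L
      if (is.null(hot_amp)) hot_amp <- 2.5
      if (is.null(hot_sigma)) hot_sigma <- 0.035
      if (is.null(cold_n)) cold_n <- 0L
    } else {
      if (is.null(hot_n)) hot_n <- 3L
      if (is.null(hot_amp)) hot_amp <- 1.0
      if (is.null(hot_sigma)) hot_sigma <- 0.06
      if (is.null(cold_n)) cold_n <- 2L
    }
  }
  if (is.null(hot_amp)) hot_amp <- 1.5
  if (is.null(hot_n) || is.null(cold_n) || is.null(hot_sigma)) {
    abort("Without a `group` preset, hot_n, hot_sigma and cold_n are required.",
          class = "tonguetherm_error_input")
  }
  if (length(ellipse_axes) != 2L || any(ellipse_axes <= 0)) {
    abort("`ellipse_axes` must be two positive fractions.",
          class = "tonguetherm_error_input")
  }
  structure(
    list(group = group, ellipse_axes = as.numeric(ellipse_axes),
         hot_n = as.integer(hot_n), hot_amp = hot_amp, hot_sigma = hot_sigma,
         cold_n = as.integer(cold_n), cold_amp = cold_amp,
         cold_sigma = cold_sigma, ambient_c = ambient_c,
         noise_sd = noise_sd, edge_drop = edge_drop),
    class = "phenotype_spec"
  )
}

# Default centre-ROI size: 40 x 48 px at the 256 x 256 working resolution
# (the documented stand-in for the 10 x 12 mm physical ROI), scaled with the
# frame.
default_roi_size <- function(h, w) {
  c(max(2L, round(40 * h / 256)), max(2L, round(48 * w / 256)))
}

#' Generate a synthetic tongue temperature field
#'
#' Builds an elliptical tongue region on an ambient background: a smooth base
#' field (subject's tongue-surface temperature with a gentle drop toward the
#' rim), group-appropriate warm and cold Gaussian spots, and pixel noise.
#' The field is then shifted inside the tongue so that the mean over the
#' centre ROI equals the record's `tst` value exactly -- by construction the
#' measured ROI temperature reproduces the subject record.
#'
#' @param record A single subject record: a one-row data frame or list with
#'   at least `group` and `tst`.
#' @param shape Frame size `c(height, width)` in pixels, each >= 64.
#' @param phenotype A [phenotype_spec()]; defaults to the preset for the
#'   record's group.
#' @param seed Integer seed; identical seed and configuration give a
#'   bitwise-identical field.
#' @return A [temperature_field()] with attributes `roi` (the centre
#'   [roi_spec()]), `tongue` (logical mask of the ellipse) and `phenotype`.
#' @examples
#' rec <- list(group = "diabetic", tst = 35.23)
#' f <- sample_temperature_field(rec, shape = c(96, 96), seed = 1)
#' mean_roi_temperature(f, attr(f, "roi")) # exactly 35.23
#' @export
sample_temperature_field <- function(record, shape = c(256L, 256L),
                                     phenotype = NULL, seed = NULL) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) {
      abort("`record` must be a single subject (one row).",
            class = "tonguetherm_error_input")
    }
    record <- as.list(record)
  }
  grp <- as.character(record$group)
  tst <- record$tst
  stopifnot_scalar_number(tst, "record$tst", min = 20, max = 42)
  if (length(shape) != 2L || any(shape < 64)) {
    abort("`shape` must be at least 64 x 64 pixels.",
          class = "tonguetherm_error_input")
  }
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (is.null(phenotype)) phenotype <- phenotype_spec(grp)
  if (any(phenotype$ellipse_axes > 1)) {
    abort("Tongue ellipse is larger than the frame.",
          class = "tonguetherm_error_input")
  }

  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  ar <- phenotype$ellipse_axes[1] * h / 2
  ac <- phenotype$ellipse_axes[2] * w / 2
  rr <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  # normalized elliptical radius (0 centre, 1 rim)
  rad2 <- ((rr - cr) / ar)^2 + ((cols - cc) / ac)^2
  tongue <- rad2 <= 1
  smin <- min(h, w)

  field <- with_seed(seed, {
    base <- matrix(phenotype$ambient_c, h, w)
    base[tongue] <- tst - phenotype$edge_drop * rad2[tongue]
    place_spots <- function(n, amp, sigma_frac, centre) {
      if (n == 0L) return(0)
      sig <- sigma_frac * smin
      if (centre) {
        pr <- cr; pc <- cc
      } else {
        # scatter in an annulus well inside the ellipse: away from the rim,
        # and away from the centre ROI (whose mean is pinned to the record's
        # temperature -- a spot sitting on it would be cancelled by the
        # renormalization). Spots stay >= 2 sigma apart so amplitudes do
        # not stack.
        pr <- pc <- numeric(0)
        for (i in seq_len(n)) {
          for (try in 1:25) {
            u <- sqrt(stats::runif(1, 0.35^2, 0.7^2))
            th <- stats::runif(1, 0, 2 * pi)
            r_i <- cr + u * ar * sin(th)
            c_i <- cc + u * ac * cos(th)
            if (length(pr) == 0L ||
                min(sqrt((pr - r_i)^2 + (pc - c_i)^2)) >= 2 * sig) break
          }
          pr <- c(pr, r_i); pc <- c(pc, c_i)
        }
      }
      bump <- matrix(0, h, w)
      for (i in seq_len(length(pr))) {
        bump <- bump + amp *
          exp(-((rr - pr[i])^2 + (cols - pc[i])^2) / (2 * sig^2))
      }
      bump
    }
    hot <- place_spots(phenotype$hot_n, phenotype$hot_amp,
                       phenotype$hot_sigma,
                       centre = identical(grp, "diabetic"))
    cold <- place_spots(phenotype$cold_n, phenotype$cold_amp,
                        phenotype$cold_sigma, centre = FALSE)
    spots <- (hot + cold) * tongue
    noise <- matrix(stats::rnorm(h * w, sd = phenotype$noise_sd), h, w)
    noise[!tongue] <- noise[!tongue] / 3
    base + spots + noise
  })

  rs <- default_roi_size(h, w)
  roi <- roi_spec(floor((h - rs[1]) / 2), floor((w - rs[2]) / 2), rs[1], rs[2])
  # shift the tongue so the centre-ROI mean equals the record's value exactly
  delta <- tst - mean(field[roi_rows(roi), roi_cols(roi)])
  field[tongue] <- field[tongue] + delta

  out <- temperature_field(field)
  attr(out, "roi") <- roi
  attr(out, "tongue") <- tongue
  attr(out, "phenotype") <- phenotype
  attr(out, "group") <- grp
  out
}

#' Interior tongue mask of a generated field
#'
#' The generator's known ellipse shrunk to `frac` of its axes; used to
#' measure color-component fractions "inside the tongue" away from the
#' rendered tongue/background boundary band.
#'
#' @param field A field from [sample_temperature_field()].
#' @param frac Axis shrink factor in (0, 1].
#' @return A logical H x W matrix.
#' @export
tongue_interior <- function(field, frac = 0.9) {
  tongue <- attr(field, "tongue")
  if (is.null(tongue)) {
    abort("`field` must come from `sample_temperature_field()`.",
          class = "tonguetherm_error_input")
  }
  m <- as_field_matrix(field)
  ph <- attr(field, "phenotype")
  ellipse_interior_mask(nrow(m), ncol(m), ph$ellipse_axes, frac)
}

# Centered elliptical interior mask at an arbitrary resolution (the axes are
# frame fractions, so the mask scales with the image it is applied to).
ellipse_interior_mask <- function(h, w, ellipse_axes, frac = 0.9) {
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  ar <- ellipse_axes[1] * h / 2 * frac
  ac <- ellipse_axes[2] * w / 2 * frac
  rr <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - cr) / ar)^2 + ((cols - cc) / ac)^2 <= 1
}
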