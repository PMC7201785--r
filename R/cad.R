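# End-to-end pipeline: preprocess -> segment -> texture features -> predict,
# plus the printed-table metric reproduction and run manifests.

#' Pipeline configuration
#'
#' Bundles every tunable of the image-processing chain and the evaluation so
#' a run is fully described (and replayable) by one object.
#'
#' @param palette Rendering/inversion palette ([rainbow_palette()]).
#' @param thresholds Color-component [threshold_table()].
#' @param roi_size Centre-ROI size `c(height, width)` in pixels at the
#'   256 x 256 working resolution.
#' @param glcm A [glcm_config()].
#' @param smooth_sigma Gaussian preprocessing sigma (pixels).
#' @param tongue_min_c Minimum inverted temperature (deg C) for a pixel to
#'   count as tongue when locating the ROI centre.
#' @param model Classifier for evaluation: `"svm"`, `"nb"` or `"cnn"`.
#' @param cv A [cv_config()].
#' @param image_shape Rendered synthetic image size.
#' @param seed Master seed for simulation runs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(palette = rainbow_palette(),
                            thresholds = threshold_table(),
                            roi_size = c(40L, 48L),
                            glcm = glcm_config(),
                            smooth_sigma = 1,
                            tongue_min_c = 30,
                            model = "svm",
                            cv = cv_config(k = 10L, seed = 7L),
                            image_shape = c(256L, 256L),
                            seed = 7L) {
  structure(
    list(palette = palette, thresholds = thresholds,
         roi_size = as.integer(roi_size), glcm = glcm,
         smooth_sigma = smooth_sigma, tongue_min_c = tongue_min_c,
         model = model, cv = cv, image_shape = as.integer(image_shape),
         seed = seed),
    class = "pipeline_config"
  )
}

# The shared image chain: resize -> smooth -> segment -> red-to-gray ->
# centre ROI -> texture features. Returns the feature row plus intermediates.
process_thermogram <- function(img, cfg, keep_intermediates = FALSE) {
  img <- resize_256(img)
  img <- gaussian_smooth(img, cfg$smooth_sigma)
  seg <- segment_all(img, cfg$thresholds)
  field <- rgb_to_temp(img, cfg$palette)
  tongue <- (unclass(field) >= cfg$tongue_min_c) * 1L
  roi <- center_roi(field, cfg$roi_size[1], cfg$roi_size[2],
                    tongue_mask = tongue)
  red_mask <- seg$masks$red
  red_in_roi <- sum(unclass(red_mask)[roi_rows(roi), roi_cols(roi)])
  fallback <- red_in_roi == 0L
  gray <- if (fallback) {
    warn(paste(
      "Red (hot-spot) component is empty over the ROI;",
      "falling back to whole-tongue grayscale."
    ), class = "tonguetherm_warning_fallback")
    rgb_to_gray(img)
  } else {
    red_to_gray(img, red_mask)
  }
  gray_roi <- structure(unclass(gray)[roi_rows(roi), roi_cols(roi)],
                        class = c("gray_image", "matrix"))
  field_roi <- unclass(field)[roi_rows(roi), roi_cols(roi)]
  feats <- extract_features(gray_roi, temperature_field(field_roi), cfg$glcm)
  feats$red_fallback <- fallback
  out <- list(features = feats, roi = roi, fractions = seg$fractions,
              masks = seg$masks)
  if (keep_intermediates) {
    out$image <- img
    out$field <- field
    out$gray <- gray
  }
  out
}

#' Render a subject's synthetic thermogram
#'
#' Generates the subject's latent temperature field from the group's
#' morphology preset and renders it under the pipeline palette.
#'
#' @param record One cohort row (or list with `group` and `tst`).
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed for the field.
#' @return A `color_thermogram` with the latent field attached as attribute
#'   `latent_field`.
#' @export
render_subject <- function(record, cfg = pipeline_config(), seed = NULL) {
  field <- sample_temperature_field(record, shape = cfg$image_shape,
                                    seed = seed)
  img <- temp_to_rgb(field, cfg$palette)
  attr(img, "latent_field") <- field
  img
}

#' Run the full CAD chain on one subject
#'
#' Accepts a thermogram (array or PNG/TIFF path) or a temperature-matrix CSV,
#' runs preprocess -> segment (hot-spot component) -> centre ROI -> texture
#' features, and classifies with the supplied trained model. When the red
#' component is empty over the ROI the chain falls back to whole-tongue
#' grayscale with a warning.
#'
#' @param input A `color_thermogram`, an image/CSV path, or a
#'   [temperature_field()].
#' @param cfg A [pipeline_config()].
#' @param model A trained classifier (`therm_svm`, `therm_nb`) expecting the
#'   [classifier_features()] columns, or `NULL` for features only.
#' @param covariates Optional named list/one-row data frame with the
#'   non-image features (waist, hip, sbp, dbp); defaults to `NA`, which
#'   restricts a prediction to models trained without them.
#' @param subject_id Identifier recorded in the report.
#' @return A `cad_report`: one-row tibble with the subject id, mean ROI
#'   temperature, the ten texture features, predicted class and score, and
#'   model metadata.
#' @export
run_subject <- function(input, cfg = pipeline_config(), model = NULL,
                        covariates = NULL, subject_id = "subject") {
  img <- resolve_input_image(input, cfg)
  res <- process_thermogram(img, cfg)
  feats <- res$features
  report <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id),
    feats[, c("roi_temp", "contrast", "correlation", "energy", "homogeneity",
              "glcm_mean", "std_dev", "entropy", "skewness", "variance",
              "kurtosis", "red_fallback")]
  )
  names(report)[names(report) == "roi_temp"] <- "tst"
  if (!is.null(covariates)) {
    report <- dplyr::bind_cols(report, tibble::as_tibble(as.list(covariates)))
  }
  if (!is.null(model)) {
    want <- setdiff(feat_cols_of(model), names(report))
    if (length(want) > 0L) {
      abort(sprintf("Model needs missing features: %s",
                    paste(want, collapse = ", ")),
            class = "tonguetherm_error_input")
    }
    p <- stats::predict(
      model,
      impute_undefined_features(report)[, feat_cols_of(model), drop = FALSE]
    )
    report$predicted_class <- as.character(p$.pred_class)
    report$score <- p$.score
    report$model <- class(model)[1]
  }
  class(report) <- c("cad_report", class(report))
  report
}

feat_cols_of <- function(model) model$features

resolve_input_image <- function(input, cfg) {
  if (inherits(input, "color_thermogram") || is_rgb_array(input)) {
    return(input)
  }
  if (inherits(input, "thermo_field")) {
    return(temp_to_rgb(input, cfg$palette))
  }
  if (is.character(input) && length(input) == 1L) {
    ext <- tolower(tools::file_ext(input))
    if (ext == "csv") {
      return(temp_to_rgb(read_field_csv(input), cfg$palette))
    }
    return(read_thermogram(input))
  }
  abort("`input` must be a thermogram, temperature field, or file path.",
        class = "tonguetherm_error_input")
}

#' Simulate a full study: cohort, thermograms and extracted features
#'
#' Draws a cohort, renders each subject's synthetic thermogram, runs the
#' image chain on every image and returns the cohort joined with the
#' extracted texture features (columns named as in [classifier_features()];
#' the image-measured ROI temperature replaces the latent `tst` draw, to
#' which it is equal by construction up to palette quantization).
#'
#' @param n_normal,n_diabetic Group sizes.
#' @param cfg A [pipeline_config()].
#' @param seed Master seed (cohort and every per-subject field derive their
#'   seeds from it).
#' @param keep_images Also return the rendered images (memory permitting).
#' @return A list with `cohort` (features joined), `fractions`
#'   (per-subject component pixel fractions) and optionally `images`.
#' @export
simulate_study <- function(n_normal = 70L, n_diabetic = 70L,
                           cfg = pipeline_config(), seed = cfg$seed,
                           keep_images = FALSE) {
  cohort <- sample_cohort(n_normal, n_diabetic, seed = seed)
  n <- nrow(cohort)
  feats <- vector("list", n)
  fracs <- vector("list", n)
  images <- if (keep_images) vector("list", n) else NULL
  for (i in seq_len(n)) {
    img <- render_subject(cohort[i, ], cfg, seed = derive_seed(seed, i))
    res <- withCallingHandlers(
      process_thermogram(img, cfg),
      tonguetherm_warning_fallback = function(w) invokeRestart("muffleWarning")
    )
    feats[[i]] <- res$features
    fr <- res$fractions
    fr$subject_id <- cohort$subject_id[i]
    # component fractions restricted to the tongue interior (90% of the
    # ellipse axes, avoiding the rendered tongue/background boundary band)
    ph <- attr(attr(img, "latent_field"), "phenotype")
    blue <- res$masks$blue
    interior <- ellipse_interior_mask(nrow(blue), ncol(blue),
                                      ph$ellipse_axes)
    fr$blue_interior <- mean(unclass(blue)[interior])
    fracs[[i]] <- fr
    if (keep_images) images[[i]] <- img
  }
  feats <- dplyr::bind_rows(feats)
  out <- dplyr::bind_cols(cohort, feats[, setdiff(names(feats), "roi_temp")])
  out$tst_measured <- feats$roi_temp
  res <- list(
    cohort = out,
    fractions = dplyr::bind_rows(fracs) |>
      tidyr::pivot_wider(names_from = "component", values_from = "fraction")
  )
  if (keep_images) res$images <- images
  res
}

# ---- printed-table reproduction --------------------------------------------

# The published per-classifier confusion counts and the printed metric
# values they should imply (used as fixed inputs by reproduce_metrics()).
printed_results <- function() {
  list(
    svm = list(
      confusion = new_confusion(tp = 63, fp = 3, tn = 67, fn = 7),
      printed = c(sensitivity = 90.00, specificity = 95.71, accuracy = 92.85,
                  ppv = 91.30, npv = 90.54)
    ),
    nb = list(
      confusion = new_confusion(tp = 67, fp = 12, tn = 58, fn = 3),
      printed = c(sensitivity = 95.71, specificity = 82.85, accuracy = 89.28,
                  ppv = 84.81, npv = 95.08)
    ),
    cnn = list(
      confusion = new_confusion(tp = 65, fp = 3, tn = 67, fn = 5),
      printed = c(sensitivity = 92.85, specificity = 95.71, accuracy = 94.28,
                  ppv = 95.58, npv = 93.05)
    )
  )
}

#' Recompute the published screening metrics from their confusion matrices
#'
#' For each classifier's published confusion matrix, recomputes sensitivity,
#' specificity, accuracy, PPV and NPV with [metrics_from_confusion()] and
#' compares every cell against the published value, flagging any
#' disagreement. (One published cell -- the SVM PPV -- is internally
#' inconsistent with its own confusion matrix: 63/66 = 95.45, not 91.30; it
#' is flagged, not replicated.)
#'
#' @return A tibble with `classifier`, `metric`, `computed`, `printed`,
#'   `consistent`.
#' @examples
#' rep <- reproduce_metrics()
#' subset(rep, !consistent) # the single inconsistent printed cell
#' @export
reproduce_metrics <- function() {
  res <- printed_results()
  purrr::map_dfr(names(res), function(cl) {
    computed <- metrics_from_confusion(res[[cl]]$confusion)
    metrics <- names(res[[cl]]$printed)
    got <- vapply(metrics, function(m) computed[[m]][1], numeric(1))
    tibble::tibble(
      classifier = cl,
      metric = metrics,
      computed = unname(got),
      printed = unname(res[[cl]]$printed),
      consistent = abs(got - res[[cl]]$printed) < 0.005
    )
  })
}

# ---- manifests --------------------------------------------------------------

#' Write a run manifest
#'
#' Records the seed and the full configuration (as a digest-stable JSON
#' structure) so any result can be replayed exactly. No timestamps are
#' stored: outputs are byte-reproducible under a fixed seed and config.
#'
#' @param cfg A [pipeline_config()].
#' @param seed The run seed.
#' @param path Output JSON path.
#' @param extra Optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, seed, path, extra = list()) {
  obj <- c(list(
    package = "tonguetherm",
    version = as.character(utils::packageVersion("tonguetherm")),
    seed = seed,
    config = serialize_config(cfg)
  ), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

serialize_config <- function(cfg) {
  list(
    palette = list(t_min = cfg$palette$t_min, t_max = cfg$palette$t_max),
    thresholds = purrr::map(cfg$thresholds$rows,
                            ~list(r = .x$r, g = .x$g, b = .x$b)),
    roi_size = cfg$roi_size,
    glcm = unclass(cfg$glcm),
    smooth_sigma = cfg$smooth_sigma,
    tongue_min_c = cfg$tongue_min_c,
    model = cfg$model,
    cv = unclass(cfg$cv),
    image_shape = cfg$image_shape
  )
}
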