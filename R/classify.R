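# Classifiers over tabular subject features, cross-validation, and the
# confusion-matrix screening metrics.

#' Feature columns fed to the tabular classifiers
#'
#' Body circumferences, blood pressure, the measured mean ROI temperature,
#' and the ten texture features.
#'
#' @return Character vector of column names.
#' @export
classifier_features <- function() {
  c("waist", "hip", "sbp", "dbp", "tst",
    "contrast", "correlation", "energy", "homogeneity", "glcm_mean",
    "std_dev", "entropy", "skewness", "variance", "kurtosis")
}

#' Impute undefined texture features for model input
#'
#' Feature extraction flags undefined values as `NA` rather than zeroing
#' them (a quantized ROI with a single gray level has no GLCM correlation;
#' a constant ROI has no skewness/kurtosis). Classifiers require complete
#' rows, so this step replaces them by explicit neutral values: correlation
#' 0 (no linear co-occurrence structure), skewness 0 and kurtosis 3 (the
#' Gaussian reference values).
#'
#' @param data A feature tibble (e.g. from [simulate_study()]).
#' @return The tibble with undefined feature cells imputed.
#' @export
impute_undefined_features <- function(data) {
  neutral <- c(correlation = 0, skewness = 0, kurtosis = 3)
  for (v in names(neutral)) {
    if (v %in% names(data)) {
      data[[v]][is.na(data[[v]])] <- neutral[[v]]
    }
  }
  data
}

check_labeled <- function(x, y) {
  if (!is.data.frame(x) && !is.matrix(x)) {
    abort("`x` must be a data frame or matrix of features.",
          class = "tonguetherm_error_input")
  }
  x <- as.matrix(x)
  if (anyNA(x)) {
    abort("Features contain missing values.", class = "tonguetherm_error_input")
  }
  y <- as_label_factor(y)
  if (length(y) != nrow(x)) {
    abort("Feature rows and labels differ in length.",
          class = "tonguetherm_error_input")
  }
  if (nlevels(droplevels(y)) < 2L) {
    abort("Both classes must be present for training.",
          class = "tonguetherm_error_input")
  }
  list(x = x, y = y)
}

as_label_factor <- function(y) {
  if (is.factor(y)) {
    factor(as.character(y), levels = c("normal", "diabetic"))
  } else if (is.numeric(y)) {
    factor(ifelse(y > 0, "diabetic", "normal"), levels = c("normal", "diabetic"))
  } else {
    factor(as.character(y), levels = c("normal", "diabetic"))
  }
}

standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(as.matrix(x), 2, std$center, "-"), 2, std$scale, "/")
}

#' Linear soft-margin support vector machine
#'
#' A maximum-margin linear separator with soft margin (regularization `C`),
#' trained on internally z-scored features. Predictions return the signed
#' decision score (positive toward the diabetic class) and the class label.
#'
#' @param x Feature data frame or matrix (no missing values).
#' @param y Labels: factor with levels normal/diabetic, or +/-1 numeric
#'   (+1 = diabetic).
#' @param cost Soft-margin regularization constant C (default 1).
#' @return An object of class `therm_svm`.
#' @examples
#' fit <- fit_svm_linear(data.frame(a = c(0, 1), b = c(0, 1)), c(-1, 1))
#' predict(fit, data.frame(a = c(0, 1), b = c(0, 1)))
#' @export
fit_svm_linear <- function(x, y, cost = 1) {
  d <- check_labeled(x, y)
  std <- standardizer(d$x)
  xs <- apply_standardizer(std, d$x)
  fit <- e1071::svm(xs, d$y, kernel = "linear", cost = cost, scale = FALSE)
  structure(
    list(fit = fit, std = std, cost = cost,
         features = colnames(d$x), levels = levels(d$y)),
    class = "therm_svm"
  )
}

#' @export
predict.therm_svm <- function(object, newdata, ...) {
  xs <- apply_standardizer(object$std, as.matrix(newdata))
  pred <- stats::predict(object$fit, xs, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # orient the score so positive means diabetic, whatever libsvm's ordering
  flip <- grepl("^normal", colnames(attr(pred, "decision.values"))[1])
  score <- if (flip) -dv else dv
  tibble::tibble(
    .pred_class = factor(as.character(pred), levels = object$levels),
    .score = unname(score)
  )
}

#' Gaussian naive Bayes classifier
#'
#' Class-conditional independent Gaussians with empirical class priors and
#' Bayes-rule posteriors. Per-class per-feature variances are smoothed by
#' `epsilon = 1e-9 * max(variance)` so constant features degrade gracefully
#' (an everywhere-constant feature contributes nothing and the posterior
#' falls back to the priors).
#'
#' @inheritParams fit_svm_linear
#' @param epsilon_frac Variance-smoothing fraction of the largest feature
#'   variance.
#' @return An object of class `therm_nb`.
#' @export
fit_nb_gaussian <- function(x, y, epsilon_frac = 1e-9) {
  d <- check_labeled(x, y)
  classes <- levels(d$y)
  max_var <- max(apply(d$x, 2, stats::var), 1e-300)
  eps <- epsilon_frac * max_var
  stats_by_class <- lapply(classes, function(cl) {
    xi <- d$x[d$y == cl, , drop = FALSE]
    list(
      prior = nrow(xi) / nrow(d$x),
      mean = colMeans(xi),
      var = apply(xi, 2, function(v) max(stats::var(v), 0)) + eps
    )
  })
  names(stats_by_class) <- classes
  smoothed <- any(vapply(stats_by_class,
                         function(s) any(s$var <= eps * (1 + 1e-12)),
                         logical(1)))
  if (smoothed) {
    inform("Degenerate per-class variance smoothed with epsilon.",
           class = "tonguetherm_message_smoothing")
  }
  structure(
    list(classes = classes, stats = stats_by_class,
         features = colnames(d$x), epsilon = eps),
    class = "therm_nb"
  )
}

#' @export
predict.therm_nb <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  loglik <- vapply(object$classes, function(cl) {
    s <- object$stats[[cl]]
    rowSums(
      -0.5 * log(2 * pi * matrix(s$var, nrow(x), ncol(x), byrow = TRUE)) -
        sweep(x, 2, s$mean, "-")^2 /
        (2 * matrix(s$var, nrow(x), ncol(x), byrow = TRUE))
    ) + log(s$prior)
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x))
  colnames(loglik) <- object$classes
  # stable softmax for posteriors
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  cls <- object$classes[max.col(post, ties.method = "first")]
  tibble::tibble(
    .pred_class = factor(cls, levels = object$classes),
    .score = post[, "diabetic"] - post[, "normal"],
    .posterior_diabetic = post[, "diabetic"]
  )
}

#' Confusion matrix of a binary screening test
#'
#' The diabetic class is the positive class: TP are diabetics identified as
#' diabetic, TN normals identified as normal.
#'
#' @param truth,predicted Label vectors (factors or characters with values
#'   normal/diabetic).
#' @return An object of class `confusion` with counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c("diabetic", "normal"), c("diabetic", "diabetic"))
#' @export
confusion_counts <- function(truth, predicted) {
  t <- as_label_factor(truth); p <- as_label_factor(predicted)
  if (length(t) != length(p)) {
    abort("`truth` and `predicted` differ in length.",
          class = "tonguetherm_error_input")
  }
  new_confusion(
    tp = sum(t == "diabetic" & p == "diabetic"),
    fp = sum(t == "normal" & p == "diabetic"),
    tn = sum(t == "normal" & p == "normal"),
    fn = sum(t == "diabetic" & p == "normal")
  )
}

#' @rdname confusion_counts
#' @param tp,fp,tn,fn Non-negative counts.
#' @export
new_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "tonguetherm_error_input")
  }
  structure(as.list(counts), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Screening metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, PPV `TP/(TP+FP)` and NPV `TN/(TN+FN)`, reported as
#' percentages. By convention the percentages are truncated (not rounded) to
#' two decimals, matching the usual printed style (130/140 -> 92.85); set
#' `rounding = "round"` for half-up rounding or `"none"` for full precision.
#' A zero denominator yields a flagged `NA`, never a silent `NaN`.
#'
#' @param cm A `confusion` object.
#' @param rounding `"truncate"` (default), `"round"` or `"none"`.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `ppv`, `npv` (percent), plus `undefined` listing any flagged metrics.
#' @examples
#' metrics_from_confusion(new_confusion(63, 3, 67, 7))
#' @export
metrics_from_confusion <- function(cm, rounding = "truncate") {
  rounding <- match.arg(rounding, c("truncate", "round", "none"))
  if (!inherits(cm, "confusion")) {
    abort("`cm` must be a `confusion` object.",
          class = "tonguetherm_error_input")
  }
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  raw <- c(
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    accuracy = ratio(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn)
  )
  vals <- switch(rounding,
    truncate = truncate_decimals(raw, 2L),
    round = round(raw, 2L),
    none = raw
  )
  out <- tibble::as_tibble(as.list(vals))
  out$undefined <- paste(names(raw)[is.na(raw)], collapse = ",")
  out
}

#' ROC curve and area under the curve
#'
#' Threshold sweep over the unique scores (higher score = more diabetic):
#' each threshold yields one (FPR, TPR) point; the AUC is the trapezoidal
#' area, which handles tied scores by averaging.
#'
#' @param scores Continuous prediction scores.
#' @param labels True labels (normal/diabetic factor, or +/-1).
#' @return A list of class `thermo_roc`: `curve` (tibble with `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.8), c("normal", "normal", "diabetic"))$auc # 1
#' @export
roc_auc <- function(scores, labels) {
  y <- as_label_factor(labels)
  if (length(scores) != length(y)) {
    abort("`scores` and `labels` differ in length.",
          class = "tonguetherm_error_input")
  }
  npos <- sum(y == "diabetic"); nneg <- sum(y == "normal")
  if (npos == 0L || nneg == 0L) {
    abort("ROC needs both classes present.", class = "tonguetherm_error_input")
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores >= t & y == "diabetic") / npos,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & y == "normal") / nneg,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    list(curve = tibble::tibble(threshold = th, fpr = fpr, tpr = tpr),
         auc = auc),
    class = "thermo_roc"
  )
}

#' Cross-validation configuration
#'
#' @param k Number of folds (default 10).
#' @param stratified Keep class proportions per fold (default `TRUE`).
#' @param seed Shuffle seed for fold assignment.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k = 10L, stratified = TRUE, seed = 1L) {
  stopifnot_scalar_number(k, "k", min = 2)
  structure(list(k = as.integer(k), stratified = isTRUE(stratified),
                 seed = seed),
            class = "cv_config")
}

# Seeded (stratified) fold assignment; returns an integer vector in 1..k.
assign_folds <- function(y, cv) {
  n <- length(y)
  with_seed(cv$seed, {
    folds <- integer(n)
    if (cv$stratified) {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        if (length(idx) < cv$k) {
          abort(sprintf(
            "k = %d exceeds the size (%d) of class '%s' for stratified folds.",
            cv$k, length(idx), cl), class = "tonguetherm_error_cv")
        }
        folds[sample(idx)] <- rep_len(seq_len(cv$k), length(idx))
      }
    } else {
      if (n < cv$k) {
        abort("k exceeds the number of observations.",
              class = "tonguetherm_error_cv")
      }
      folds[sample.int(n)] <- rep_len(seq_len(cv$k), n)
    }
    folds
  })
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into seeded (stratified) folds, trains the model
#' specification inside each training fold (feature standardization happens
#' inside the fit functions, so no information leaks from held-out folds),
#' and pools the held-out predictions into a single confusion matrix.
#'
#' @param x Feature data frame/matrix, or a list of image arrays for
#'   `model = "cnn"`.
#' @param y Labels.
#' @param model `"svm"`, `"nb"`, `"cnn"`, or a list with `fit(x, y)` and
#'   standard `predict` support.
#' @param cv A [cv_config()].
#' @param ... Passed to the fit function (e.g. `cost`, or `cfg` for the CNN).
#' @return An object of class `thermo_cv`: pooled `confusion`, `metrics`
#'   (via [metrics_from_confusion()]), `fold_accuracy`, pooled `scores`
#'   and `truth`, and `auc`.
#' @examples
#' cohort <- sample_cohort(30, 30, seed = 3)
#' res <- crossvalidate(cohort[, c("tst", "hba1c")], cohort$group,
#'                      model = "svm", cv = cv_config(k = 5, seed = 3))
#' res$metrics$accuracy
#' @export
crossvalidate <- function(x, y, model = "svm", cv = cv_config(), ...) {
  y <- as_label_factor(y)
  is_images <- is.list(x) && !is.data.frame(x)
  n <- if (is_images) length(x) else nrow(x)
  if (n != length(y)) {
    abort("Features and labels differ in length.",
          class = "tonguetherm_error_input")
  }
  fit_fun <- if (is.character(model)) {
    switch(match.arg(model, c("svm", "nb", "cnn")),
           svm = fit_svm_linear, nb = fit_nb_gaussian, cnn = fit_cnn)
  } else {
    model$fit
  }
  folds <- assign_folds(y, cv)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  scores <- numeric(n)
  fold_acc <- numeric(cv$k)
  for (f in seq_len(cv$k)) {
    tr <- folds != f; te <- folds == f
    xtr <- if (is_images) x[tr] else x[tr, , drop = FALSE]
    xte <- if (is_images) x[te] else x[te, , drop = FALSE]
    fit <- fit_fun(xtr, y[tr], ...)
    p <- stats::predict(fit, xte)
    pred[te] <- p$.pred_class
    scores[te] <- p$.score
    fold_acc[f] <- mean(p$.pred_class == y[te])
  }
  cm <- confusion_counts(y, pred)
  structure(
    list(confusion = cm, metrics = metrics_from_confusion(cm),
         fold_accuracy = fold_acc, folds = folds,
         truth = y, predicted = pred, scores = scores,
         auc = roc_auc(scores, y)$auc, cv = cv),
    class = "thermo_cv"
  )
}

#' @export
print.thermo_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (pooled):\n", x$cv$k))
  print(x$confusion)
  cat(sprintf("accuracy %.2f%%, AUC %.3f\n", x$metrics$accuracy, x$auc))
  invisible(x)
}
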