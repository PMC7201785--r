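# broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a test result
#'
#' @param x A `thermo_test`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value` and `n`.
#' @export
tidy.thermo_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    df = x$df %||% NA_real_,
    n = paste(x$group_sizes, collapse = "/")
  )
}

#' @rdname tidy.thermo_test
#' @export
glance.thermo_test <- function(x, ...) tidy.thermo_test(x, ...)

#' Tidy a correlation matrix into long format
#'
#' @param x A `thermo_corrmat`.
#' @param ... Unused.
#' @return A tibble with one row per unordered variable pair: `var1`,
#'   `var2`, `r`, `p`, and `stars` (`**` p < 0.01, `*` p < 0.05).
#' @export
tidy.thermo_corrmat <- function(x, ...) {
  k <- length(x$variables)
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$variables[idx[, 2]],
    var2 = x$variables[idx[, 1]],
    r = x$r[idx],
    p = x$p[idx],
    stars = dplyr::case_when(
      is.na(x$p[idx]) ~ NA_character_,
      x$p[idx] < 0.01 ~ "**",
      x$p[idx] < 0.05 ~ "*",
      .default = ""
    )
  )
}

#' @rdname tidy.thermo_corrmat
#' @export
glance.thermo_corrmat <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variables),
    n = x$n,
    n_significant_05 = sum(x$sig_05[lower.tri(x$sig_05)]),
    n_significant_01 = sum(x$sig_01[lower.tri(x$sig_01)])
  )
}

#' Tidy cross-validation results
#'
#' @param x A `thermo_cv`.
#' @param ... Unused.
#' @return `tidy()`: one row per fold with its held-out accuracy.
#'   `glance()`: one row with the pooled confusion counts, the five
#'   screening metrics and the AUC.
#' @export
tidy.thermo_cv <- function(x, ...) {
  tibble::tibble(
    fold = seq_along(x$fold_accuracy),
    accuracy = x$fold_accuracy
  )
}

#' @rdname tidy.thermo_cv
#' @export
glance.thermo_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(tp = x$confusion$tp, fp = x$confusion$fp,
                   tn = x$confusion$tn, fn = x$confusion$fn),
    x$metrics[, c("sensitivity", "specificity", "accuracy", "ppv", "npv")],
    tibble::tibble(auc = x$auc, k = x$cv$k)
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion`.
#' @param ... Unused.
#' @return A four-row tibble with `cell` and `count`.
#' @export
tidy.confusion <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "tn", "fn"),
                 count = c(x$tp, x$fp, x$tn, x$fn))
}

#' @rdname tidy.confusion
#' @export
glance.confusion <- function(x, ...) metrics_from_confusion(x)

#' Summaries of fitted classifiers
#'
#' @param x A fitted `therm_nb`, `therm_svm` or `therm_cnn`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.therm_nb <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    s <- x$stats[[cl]]
    tibble::tibble(class = cl, feature = x$features,
                   mean = unname(s$mean), variance = unname(s$var),
                   prior = s$prior)
  })
}

#' @rdname tidy.therm_nb
#' @export
glance.therm_svm <- function(x, ...) {
  tibble::tibble(cost = x$cost, n_support = x$fit$tot.nSV,
                 n_features = length(x$features))
}

#' @rdname tidy.therm_nb
#' @export
glance.therm_cnn <- function(x, ...) {
  tibble::tibble(
    epochs = x$cfg$epochs,
    learning_rate = x$cfg$learning_rate,
    n_blocks = length(x$cfg$blocks),
    final_loss = if (length(x$history)) x$history[length(x$history)] else NA_real_
  )
}
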