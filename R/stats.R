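# Group statistics: normality, two-group tests, nonparametric test,
# correlation matrix, and the simple r-squared of the HbA1c/temperature fit.

new_thermo_test <- function(method, statistic, p_value, group_sizes,
                            extra = list()) {
  structure(
    c(list(method = method, statistic = unname(statistic),
           p_value = unname(p_value), group_sizes = group_sizes), extra),
    class = "thermo_test"
  )
}

#' @export
print.thermo_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Two-sample Student's t test (pooled variance)
#'
#' The equal-variance pooled test with `df = n_a + n_b - 2` and a two-sided
#' p value (the default "Student's t" of standard statistical software);
#' Welch's unequal-variance form is available behind `welch = TRUE`.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param welch Use the Welch unequal-variance test instead.
#' @return A `thermo_test` with `statistic` (t), `p_value`, `df`.
#' @examples
#' students_t(c(1, 2, 3), c(4, 5, 6)) # t = -3.674, p = 0.0214
#' @export
students_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each sample needs at least two observations.",
          class = "tonguetherm_error_input")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  new_thermo_test(
    if (welch) "Welch t-test" else "Student's t-test (pooled)",
    ht$statistic, ht$p.value, c(length(a), length(b)),
    extra = list(df = unname(ht$parameter), estimate = unname(diff(rev(ht$estimate))))
  )
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, `3 <= length(x) <= 5000`.
#' @return A `thermo_test` with the W statistic and p value.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L) {
    abort("Shapiro-Wilk needs at least three observations.",
          class = "tonguetherm_error_input")
  }
  ht <- stats::shapiro.test(x)
  new_thermo_test("Shapiro-Wilk", ht$statistic, ht$p.value, length(x))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with the chi-square approximation, for two or
#' more groups (with exactly two groups it is equivalent to a Mann-Whitney
#' test).
#'
#' @param groups A list of numeric samples (>= 2 groups).
#' @return A `thermo_test` with H, p value and df.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6))) # H = 3.857
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort("Provide a list of at least two groups.",
          class = "tonguetherm_error_input")
  }
  ht <- stats::kruskal.test(groups)
  new_thermo_test("Kruskal-Wallis", ht$statistic, ht$p.value,
                  lengths(groups), extra = list(df = unname(ht$parameter)))
}

#' Pearson correlation test
#'
#' Product-moment correlation with the t-based two-sided p value.
#'
#' @param x,y Equal-length numeric samples, `n >= 3`, nonzero variances.
#' @return A `thermo_test` with `statistic` (r), `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must be equal-length samples with n >= 3.",
          class = "tonguetherm_error_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation undefined for a zero-variance sample.",
          class = "tonguetherm_error_degenerate")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  new_thermo_test("Pearson correlation", unname(ht$estimate), ht$p.value,
                  length(x), extra = list(t = unname(ht$statistic)))
}

#' Coefficient of determination of the simple linear fit
#'
#' The square of the Pearson correlation, equal to the OLS r-squared of a
#' simple linear regression of `y` on `x`.
#'
#' @param x,y Equal-length numeric samples.
#' @return A scalar in `[0, 1]`.
#' @examples
#' r_squared(1:10, 2 * (1:10) + 1) # 1
#' @export
r_squared <- function(x, y) {
  pearson_r(x, y)$statistic^2
}

#' Pairwise Pearson correlation matrix over cohort variables
#'
#' Applies [pearson_r()] to every variable pair; zero-variance variables get
#' flagged `NA` entries rather than an error.
#'
#' @param data A data frame (e.g. a [sample_cohort()] tibble, possibly
#'   filtered to one group).
#' @param vars Variable names to correlate (default: all numeric columns).
#' @return An object of class `thermo_corrmat`: list with matrices `r`, `p`
#'   and significance flags at the 0.05 / 0.01 levels.
#' @examples
#' cm <- correlation_matrix(sample_cohort(0, 70, seed = 1),
#'                          vars = c("hba1c", "fbs", "tst"))
#' cm$r["hba1c", "tst"]
#' @export
correlation_matrix <- function(data, vars = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "tonguetherm_error_input")
  }
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      res <- tryCatch(
        pearson_r(data[[vars[i]]], data[[vars[j]]]),
        tonguetherm_error_degenerate = function(e) NULL
      )
      if (!is.null(res)) {
        r[i, j] <- r[j, i] <- res$statistic
        p[i, j] <- p[j, i] <- res$p_value
      }
    }
  }
  structure(
    list(variables = vars, r = r, p = p,
         sig_05 = !is.na(p) & p < 0.05, sig_01 = !is.na(p) & p < 0.01,
         n = nrow(data)),
    class = "thermo_corrmat"
  )
}

#' Group summary table with two-group tests
#'
#' The baseline-characteristics view: per-variable group mean and SD, the
#' pooled Student's t p value and a significance tag (`"s"` when p < 0.05,
#' else `"ns"`). No multiple-testing correction is applied by default (raw
#' p values, as in the source analysis); pass `adjust = "bonferroni"` or
#' `"BH"` to correct.
#'
#' @param data Cohort (plus optionally feature) tibble with a `group` column.
#' @param vars Variables to summarize (default: all numeric columns).
#' @param adjust P-value adjustment method (`"none"`, `"bonferroni"`, `"BH"`).
#' @return A tibble: `variable`, `normal_mean`, `normal_sd`,
#'   `diabetic_mean`, `diabetic_sd`, `p_value`, `significance`.
#' @export
group_summary <- function(data, vars = NULL, adjust = "none") {
  adjust <- match.arg(adjust, c("none", "bonferroni", "BH"))
  if (!"group" %in% names(data)) {
    abort("`data` needs a `group` column.", class = "tonguetherm_error_input")
  }
  if (is.null(vars)) {
    vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    "degenerate")
  }
  rows <- purrr::map_dfr(vars, function(v) {
    a <- data[[v]][data$group == "normal"]
    b <- data[[v]][data$group == "diabetic"]
    ok <- sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2
    p <- if (ok) students_t(a[!is.na(a)], b[!is.na(b)])$p_value else NA_real_
    tibble::tibble(
      variable = v,
      normal_mean = mean(a, na.rm = TRUE), normal_sd = stats::sd(a, na.rm = TRUE),
      diabetic_mean = mean(b, na.rm = TRUE), diabetic_sd = stats::sd(b, na.rm = TRUE),
      p_value = p
    )
  })
  if (adjust != "none") {
    rows$p_value <- stats::p.adjust(rows$p_value, method = adjust)
  }
  rows$significance <- ifelse(is.na(rows$p_value), NA_character_,
                              ifelse(rows$p_value < 0.05, "s", "ns"))
  rows
}

#' Write a correlation matrix as a starred CSV
#'
#' Long-format CSV with `var1`, `var2`, `r`, `p` and a `stars` column
#' (`**` at the 0.01 level, `*` at 0.05).
#'
#' @param cm A `thermo_corrmat`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(cm, path) {
  readr::write_csv(tidy(cm), path)
  invisible(path)
}
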