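# Tabular classifiers, confusion metrics, ROC and cross-validation.

test_that("linear SVM separates a trivial pair symmetrically", {
  x <- data.frame(a = c(0, 1), b = c(0, 1))
  fit <- fit_svm_linear(x, c(-1, 1))
  p <- predict(fit, x)
  expect_equal(as.character(p$.pred_class), c("normal", "diabetic"))
  # the margin midpoint lies on x + y = 1: score there is ~0
  mid <- predict(fit, data.frame(a = 0.5, b = 0.5))
  expect_lt(abs(mid$.score), 1e-6)
  expect_error(fit_svm_linear(x, c(1, 1)), class = "tonguetherm_error_input")
})

test_that("flipping labels negates the SVM decision function", {
  set.seed(6)
  x <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- rep(c(-1, 1), 20)
  s1 <- predict(fit_svm_linear(x, y), x)$.score
  s2 <- predict(fit_svm_linear(x, -y), x)$.score
  expect_equal(s1, -s2, tolerance = 1e-6)
})

test_that("a linear kernel cannot separate XOR", {
  x <- data.frame(a = c(0, 1, 0, 1), b = c(0, 1, 1, 0))
  y <- c(1, 1, -1, -1)
  fit <- fit_svm_linear(x, y)
  acc <- mean(predict(fit, x)$.pred_class == ifelse(y > 0, "diabetic", "normal"))
  expect_lte(acc, 0.75)
})

test_that("Gaussian NB places the boundary at the likelihood midpoint", {
  set.seed(10)
  n <- 2000
  x <- data.frame(v = c(rnorm(n, -1), rnorm(n, 1)))
  y <- rep(c("normal", "diabetic"), each = n)
  fit <- fit_nb_gaussian(x, y)
  grid <- data.frame(v = seq(-2, 2, by = 0.001))
  sc <- predict(fit, grid)$.score
  boundary <- grid$v[which.min(abs(sc))]
  expect_lt(abs(boundary), 0.1)
  # unbalanced priors shift the boundary toward the rare class by ln(9)/2
  x2 <- data.frame(v = c(rnorm(9 * n, -1), rnorm(n, 1)))
  y2 <- rep(c("normal", "diabetic"), c(9 * n, n))
  fit2 <- fit_nb_gaussian(x2, y2)
  sc2 <- predict(fit2, grid)$.score
  boundary2 <- grid$v[which.min(abs(sc2))]
  expect_lt(abs(boundary2 - log(9) / 2), 0.12)
})

test_that("a feature constant in both classes leaves the posterior at the priors", {
  set.seed(11)
  x <- data.frame(flat = rep(1, 60))
  y <- rep(c("normal", "diabetic"), c(40, 20))
  fit <- suppressMessages(fit_nb_gaussian(x, y))
  p <- predict(fit, data.frame(flat = c(1, 1)))
  expect_equal(p$.posterior_diabetic, c(1 / 3, 1 / 3), tolerance = 1e-6)
})

test_that("confusion metrics reproduce the printed-table arithmetic", {
  m_svm <- metrics_from_confusion(new_confusion(63, 3, 67, 7))
  expect_equal(m_svm$sensitivity, 90.00)
  expect_equal(m_svm$specificity, 95.71)
  expect_equal(m_svm$accuracy, 92.85)
  expect_equal(m_svm$npv, 90.54)
  expect_equal(m_svm$ppv, 95.45)  # formula value; the printed 91.30 is wrong
  m_cnn <- metrics_from_confusion(new_confusion(65, 3, 67, 5))
  expect_equal(m_cnn$accuracy, 94.28)
  expect_equal(m_cnn$ppv, 95.58)
  expect_equal(m_cnn$sensitivity, 92.85)
  perfect <- metrics_from_confusion(new_confusion(70, 0, 70, 0))
  expect_true(all(perfect[1, c("sensitivity", "specificity", "accuracy",
                               "ppv", "npv")] == 100))
})

test_that("zero denominators are flagged, not propagated as NaN", {
  m <- metrics_from_confusion(new_confusion(0, 0, 5, 5))
  expect_true(is.na(m$ppv))
  expect_match(m$undefined, "ppv")
  expect_false(is.nan(m$ppv))
})

test_that("metrics identity links accuracy to sensitivity and specificity", {
  set.seed(14)
  for (rep in 1:20) {
    cm <- new_confusion(sample(1:50, 1), sample(1:50, 1),
                        sample(1:50, 1), sample(1:50, 1))
    m <- metrics_from_confusion(cm, rounding = "none")
    total <- cm$tp + cm$fp + cm$tn + cm$fn
    lhs <- m$accuracy
    rhs <- (m$sensitivity * (cm$tp + cm$fn) +
              m$specificity * (cm$tn + cm$fp)) / total
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("truncation (not rounding) reproduces the printed two-decimal style", {
  m <- metrics_from_confusion(new_confusion(63, 3, 67, 7))
  expect_equal(m$accuracy, 92.85)  # 92.857... truncated
  mr <- metrics_from_confusion(new_confusion(63, 3, 67, 7), rounding = "round")
  expect_equal(mr$accuracy, 92.86)
})

test_that("ROC/AUC handles perfect, inverted, tied and random scores", {
  y <- c("normal", "normal", "diabetic", "diabetic")
  expect_equal(roc_auc(c(1, 2, 3, 4), y)$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), y)$auc, 0)
  # tied scores average via the trapezoid, matching the pairwise oracle
  set.seed(18)
  for (rep in 1:10) {
    sc <- sample(1:5, 30, replace = TRUE)
    yy <- sample(c("normal", "diabetic"), 30, replace = TRUE,
                 prob = c(0.5, 0.5))
    if (length(unique(yy)) < 2) next
    expect_equal(roc_auc(sc, yy)$auc, brute_auc(sc, yy), tolerance = 1e-12)
  }
  set.seed(19)
  auc_null <- roc_auc(rnorm(1000), rep(c("normal", "diabetic"), 500))$auc
  expect_lt(abs(auc_null - 0.5), 0.05)
  expect_error(roc_auc(1:3, rep("normal", 3)),
               class = "tonguetherm_error_input")
})

test_that("cross-validation pools held-out predictions deterministically", {
  co <- sample_cohort(30, 30, seed = 3)
  x <- co[, c("hba1c", "tst", "fbs")]
  r1 <- crossvalidate(x, co$group, model = "svm", cv = cv_config(10, seed = 3))
  r2 <- crossvalidate(x, co$group, model = "svm", cv = cv_config(10, seed = 3))
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$predicted, r2$predicted)
  total <- r1$confusion$tp + r1$confusion$fp + r1$confusion$tn + r1$confusion$fn
  expect_equal(total, 60)
  # stratified folds keep class balance
  expect_true(all(table(r1$folds, co$group) == 3))
  # the biochemical margins separate most subjects (diabetic HbA1c has a
  # long lower tail overlapping the normal range, so not perfectly)
  expect_gt(r1$metrics$accuracy, 80)
  expect_error(crossvalidate(x, co$group, cv = cv_config(40, seed = 1)),
               class = "tonguetherm_error_cv")
})

test_that("perfectly separable data yields zero pooled errors", {
  x <- data.frame(v = c(rnorm(30, -5), rnorm(30, 5)))
  y <- rep(c("normal", "diabetic"), each = 30)
  res <- crossvalidate(x, y, model = "svm", cv = cv_config(5, seed = 2))
  expect_equal(res$confusion$fp, 0L)
  expect_equal(res$confusion$fn, 0L)
})

test_that("random labels drive pooled accuracy to chance", {
  set.seed(23)
  accs <- vapply(1:10, function(s) {
    x <- data.frame(a = rnorm(60), b = rnorm(60))
    y <- sample(rep(c("normal", "diabetic"), 30))
    crossvalidate(x, y, model = "nb",
                  cv = cv_config(5, seed = s))$metrics$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 10)
})
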