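# Synthetic cohort generator: marginals, copula dependence, determinism.

test_that("defaults cover every study variable with positive SDs", {
  gp <- group_params()
  expect_equal(sort(unique(gp$variable)), sort(cohort_variables()))
  expect_true(all(gp$sd > 0))
  # spot-check two anchor entries of the default table
  expect_equal(gp$mean[gp$variable == "tst" & gp$group == "diabetic"], 35.23)
  expect_equal(gp$sd[gp$variable == "hba1c" & gp$group == "normal"], 0.15)
})

test_that("the default correlation target is symmetric and repairable", {
  cs <- correlation_spec()
  expect_equal(cs$r, t(cs$r))
  expect_equal(unname(diag(cs$r)), rep(1, length(cs$variables)))
  expect_equal(cs$r["hba1c", "tst"], 0.662)
  expect_equal(cs$r["fbs", "eag"], 0.834)
  # the printed matrix is indefinite; the repair must fix exactly that
  expect_lt(min(eigen(cs$r, symmetric = TRUE)$values), 0)
  rpd <- nearest_pd(cs$r)
  expect_gt(min(eigen(rpd, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(rpd)), rep(1, nrow(rpd)))
  # repair barely moves the key anchor entry
  expect_lt(abs(rpd["hba1c", "tst"] - 0.662), 0.01)
  # already-PD matrices pass through unchanged
  m <- diag(3) * 1
  expect_equal(nearest_pd(m), m)
})

test_that("structured errors for invalid inputs", {
  expect_error(sample_cohort(-1, 10), class = "tonguetherm_error_input")
  bad <- matrix(c(1, 0.5, 0.4, 1), 2, 2)  # not symmetric
  expect_error(correlation_spec(c("a", "b"), bad),
               class = "tonguetherm_error_corr")
  expect_error(correlation_spec(c("a", "b", "c"), diag(2)),
               class = "tonguetherm_error_corr")
})

test_that("cohort shape, empty case and determinism", {
  co <- sample_cohort(70, 70, seed = 42)
  expect_equal(nrow(co), 140L)
  expect_equal(sum(co$group == "diabetic"), 70L)
  expect_false(anyNA(co))
  empty <- sample_cohort(0, 0, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_identical(sample_cohort(25, 25, seed = 9),
                   sample_cohort(25, 25, seed = 9))
  expect_false(identical(sample_cohort(25, 25, seed = 9),
                         sample_cohort(25, 25, seed = 10)))
})

test_that("diabetic HbA1c sample mean lands within 3 standard errors", {
  co <- sample_cohort(70, 70, seed = 42)
  hb <- co$hba1c[co$group == "diabetic"]
  se <- 2.30 / sqrt(70)
  expect_lt(abs(mean(hb) - 8.58), 3 * se)
})

test_that("physical clipping respects the hard bounds", {
  co <- sample_cohort(200, 200, seed = 5)
  expect_true(all(co$spo2 <= 100))
  expect_true(all(co$tst >= 20 & co$tst <= 42))
  expect_true(all(co$core_temp >= 20 & co$core_temp <= 42))
  expect_true(all(co[cohort_variables()] >= 0))
})

test_that("consistent-labels mode enforces the HbA1c diagnostic rule", {
  co <- sample_cohort(150, 150, seed = 3, consistent_labels = TRUE)
  expect_true(all(co$hba1c[co$group == "diabetic"] >= 6.5))
  expect_true(all(co$hba1c[co$group == "normal"] <= 6.4))
})

test_that("increasing the configured correlation increases the sample correlation", {
  mean_r <- vapply(c(0, 0.4, 0.8), function(rho) {
    cs <- correlation_spec(c("hba1c", "tst"),
                           matrix(c(1, rho, rho, 1), 2, 2))
    rs <- vapply(1:60, function(s) {
      co <- sample_cohort(0, 50, corr = cs, seed = s)
      cor(co$hba1c, co$tst)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0.2))
  expect_lt(abs(mean_r[1]), 0.1)
  expect_gt(mean_r[3], 0.7)
})

test_that("variables outside the correlation spec stay uncorrelated", {
  rs <- vapply(1:40, function(s) {
    co <- sample_cohort(0, 60, seed = s)
    cor(co$height, co$hba1c)  # height is not in the Table-4 subset
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.08)
})

test_that("the pooled association mode recovers its configured correlation", {
  r2 <- vapply(1:30, function(s) {
    co <- sample_cohort(70, 70, seed = s, pooled_hba1c_tst_r = sqrt(0.5688))
    r_squared(co$hba1c, co$tst)
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.5688), 0.05)
})

test_that("cohorts survive a CSV round trip", {
  co <- sample_cohort(5, 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12,
               ignore_attr = TRUE)
})
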