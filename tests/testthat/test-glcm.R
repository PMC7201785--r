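# GLCM construction and texture features against brute-force oracles.

test_that("quantization bins the 8-bit range uniformly", {
  expect_equal(unclass(quantize(matrix(0:255, 16, 16), 256)),
               matrix(0:255, 16, 16))
  expect_equal(as.vector(quantize(matrix(c(0, 255), 1, 2), 2)), c(0L, 1L))
  expect_equal(quantize(matrix(255, 1, 1), 8)[1, 1], 7L)
  expect_equal(quantize(matrix(31, 1, 1), 8)[1, 1], 0L)
  expect_equal(quantize(matrix(32, 1, 1), 8)[1, 1], 1L)
  expect_error(quantize(matrix(0, 2, 2), 1), class = "tonguetherm_error_input")
})

test_that("constant images give a single-cell GLCM with the expected features", {
  q <- matrix(3L, 6, 6)
  p <- compute_glcm(q, glcm_config(n_levels = 8))
  expect_equal(sum(p), 1)
  expect_equal(p[4, 4], 1)
  expect_equal(glcm_contrast(p), 0)
  expect_equal(glcm_energy(p), 1)
  expect_equal(glcm_homogeneity(p), 1)
  expect_equal(glcm_variance(p), 0)
  expect_equal(glcm_mean(p), 3)
  expect_warning(expect_true(is.na(glcm_correlation(p))),
                 class = "tonguetherm_warning_degenerate")
})

test_that("checkerboard co-occurrence matches the closed form", {
  q <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  p <- compute_glcm(q, glcm_config(n_levels = 2))
  expect_equal(glcm_mat(p), matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(glcm_contrast(p), 1)
  expect_equal(glcm_energy(p), 0.5)
  expect_equal(glcm_correlation(p), -1)
  # Eq. as printed: sum P / (1 + (i - j)^2)
  expect_equal(glcm_homogeneity(p), 0.5)
})

test_that("a worked 4 x 4 image matches exhaustive pair enumeration", {
  img <- rbind(c(0L, 0L, 1L, 2L),
               c(0L, 0L, 1L, 2L),
               c(2L, 2L, 3L, 3L),
               c(2L, 2L, 3L, 3L))
  cfg <- glcm_config(n_levels = 4)
  p <- compute_glcm(img, cfg)
  expect_equal(glcm_mat(p), brute_glcm(img, 4, 0, 1))
  got <- brute_glcm_features(glcm_mat(p))
  expect_equal(glcm_contrast(p), got$contrast)
  expect_equal(glcm_correlation(p), got$correlation)
  expect_equal(glcm_energy(p), got$energy)
  expect_equal(glcm_homogeneity(p), got$homogeneity)
  expect_equal(glcm_mean(p), got$glcm_mean)
  expect_equal(glcm_std(p), got$std_dev)
  expect_equal(glcm_variance(p), got$variance)
  expect_equal(glcm_entropy(p), got$entropy)
})

test_that("GLCM respects offset, symmetry and normalization options", {
  set.seed(5)
  img <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 2L))) {
    for (sym in c(TRUE, FALSE)) {
      cfg <- glcm_config(n_levels = 4, offset = off, symmetric = sym)
      p <- compute_glcm(img, cfg)
      expect_equal(glcm_mat(p), brute_glcm(img, 4, off[1], off[2],
                                           symmetric = sym))
      expect_equal(sum(p), 1)
      if (sym) expect_identical(glcm_mat(p), t(glcm_mat(p)))
    }
  }
  counts <- compute_glcm(img, glcm_config(n_levels = 4, normalize = FALSE))
  expect_equal(sum(counts), 2 * 8 * 7)  # symmetric doubles the pair count
  expect_error(compute_glcm(matrix(0L, 1, 1), glcm_config()),
               class = "tonguetherm_error_glcm")
  expect_error(glcm_contrast(matrix(2, 2, 2)),
               class = "tonguetherm_error_glcm")
})

test_that("feature bounds hold on random images", {
  set.seed(13)
  for (rep in 1:25) {
    img <- matrix(sample(0:7, 49, replace = TRUE), 7, 7)
    p <- compute_glcm(img, glcm_config(n_levels = 8))
    expect_gt(glcm_energy(p), 0); expect_lte(glcm_energy(p), 1)
    expect_gt(glcm_homogeneity(p), 0); expect_lte(glcm_homogeneity(p), 1)
    expect_gte(glcm_contrast(p), 0)
    expect_gte(glcm_variance(p), 0)
    r <- glcm_correlation(p)
    if (!is.na(r)) expect_lte(abs(r), 1 + 1e-12)
  }
})

test_that("intensity skewness and kurtosis follow the population formulas", {
  expect_equal(intensity_skewness(c(1, 2, 3)), 0)
  # hand-computed oracle for {0, 0, 0, 1}
  x <- c(0, 0, 0, 1)
  mu <- 0.25; s2 <- 0.1875
  expect_equal(intensity_skewness(x), 0.375 / (4 * s2^1.5))
  expect_equal(intensity_kurtosis(x),
               (3 * 0.25^4 + 0.75^4) / (4 * s2^2))
  # Monte-Carlo: a large standard normal sample has kurtosis near 3
  set.seed(2)
  z <- rnorm(1e5)
  expect_lt(abs(intensity_kurtosis(z) - 3), 0.1)
  expect_lt(abs(intensity_skewness(z)), 0.05)
  expect_error(intensity_skewness(c(2, 2, 2)),
               class = "tonguetherm_error_degenerate")
})

test_that("literal entropy option applies the printed summed-negative-log form", {
  q <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  p <- compute_glcm(q, glcm_config(n_levels = 2))
  expect_equal(glcm_entropy(p, literal = TRUE), 2 * -log(0.5))
  expect_equal(glcm_entropy(p), -2 * 0.5 * log(0.5))
})

test_that("extract_features returns the full flagged vector", {
  set.seed(31)
  gray <- matrix(sample(0:255, 20 * 24, replace = TRUE), 20, 24)
  field <- temperature_field(matrix(35.1, 20, 24))
  fv <- extract_features(gray, field)
  expect_equal(nrow(fv), 1L)
  expect_named(fv, c("contrast", "correlation", "energy", "homogeneity",
                     "glcm_mean", "std_dev", "entropy", "skewness",
                     "variance", "kurtosis", "roi_temp", "degenerate"))
  expect_equal(fv$roi_temp, 35.1)
  expect_false(fv$degenerate)
  # constant ROI: defined features take their degenerate values, undefined
  # ones are flagged NA -- not silently zeroed
  const <- matrix(128, 8, 8)
  fvc <- suppressWarnings(extract_features(const))
  expect_equal(fvc$contrast, 0)
  expect_equal(fvc$energy, 1)
  expect_equal(fvc$homogeneity, 1)
  expect_equal(fvc$variance, 0)
  expect_true(is.na(fvc$correlation))
  expect_true(is.na(fvc$skewness))
  expect_true(is.na(fvc$kurtosis))
  expect_true(fvc$degenerate)
})

test_that("diabetic morphology yields higher GLCM standard deviation than normal", {
  cfg <- pipeline_config(image_shape = c(128L, 128L))
  sd_of <- function(group, tst, seed) {
    img <- render_subject(list(group = group, tst = tst), cfg, seed = seed)
    res <- suppressWarnings(
      tonguetherm:::process_thermogram(img, cfg)
    )
    res$features$std_dev
  }
  set.seed(99)
  n_seeds <- 12
  d <- vapply(seq_len(n_seeds), function(s)
    sd_of("diabetic", rnorm(1, 35.23, 0.61), 300 + s), numeric(1))
  n <- vapply(seq_len(n_seeds), function(s)
    sd_of("normal", rnorm(1, 34.62, 0.77), 400 + s), numeric(1))
  expect_gt(mean(d), mean(n))
})
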