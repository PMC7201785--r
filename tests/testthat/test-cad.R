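# End-to-end CAD pipeline, printed-table reproduction, manifests and CLI.

test_that("run_subject classifies generator presets correctly", {
  cfg <- pipeline_config(image_shape = c(128L, 128L))
  sim <- simulate_study(15, 15, cfg, seed = 7)
  data <- impute_undefined_features(sim$cohort)
  model <- fit_svm_linear(data[, classifier_features()], data$group)
  rep_d <- suppressWarnings(run_subject(
    render_subject(list(group = "diabetic", tst = 35.4), cfg, seed = 501),
    cfg, model = model,
    covariates = list(waist = 84.5, hip = 91.8, sbp = 122.9, dbp = 76.1),
    subject_id = "d1"
  ))
  expect_s3_class(rep_d, "cad_report")
  expect_equal(rep_d$predicted_class, "diabetic")
  rep_n <- suppressWarnings(run_subject(
    render_subject(list(group = "normal", tst = 34.5), cfg, seed = 502),
    cfg, model = model,
    covariates = list(waist = 79.6, hip = 87.2, sbp = 122, dbp = 76.4),
    subject_id = "n1"
  ))
  expect_equal(rep_n$predicted_class, "normal")
})

test_that("temperature-CSV input takes the same path as images", {
  cfg <- pipeline_config(image_shape = c(96L, 96L))
  f <- sample_temperature_field(list(group = "diabetic", tst = 35.3),
                                shape = c(96, 96), seed = 9)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, csv)
  rep <- suppressWarnings(run_subject(csv, cfg))
  expect_true(is.finite(rep$tst))
  expect_lt(abs(rep$tst - 35.3), 0.3)  # resize + palette quantization
})

test_that("corrupted image files produce a structured error", {
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(run_subject(bad, pipeline_config()),
               class = "tonguetherm_error_io")
})

test_that("reproduce_metrics confirms all derivable printed cells but one", {
  rep <- reproduce_metrics()
  expect_equal(nrow(rep), 15L)
  bad <- rep[!rep$consistent, ]
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$classifier, "svm")
  expect_equal(bad$metric, "ppv")
  expect_equal(bad$computed, 95.45)
  expect_equal(bad$printed, 91.30)
  # NB and CNN rows are fully consistent
  expect_true(all(rep$consistent[rep$classifier %in% c("nb", "cnn")]))
})

test_that("manifest serializes the full configuration without timestamps", {
  cfg <- pipeline_config()
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(cfg, seed = 11, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$seed, 11L)
  expect_equal(obj$config$glcm$n_levels, 8L)
  expect_equal(unlist(obj$config$thresholds$red$r), c(222L, 252L))
  expect_false(any(grepl("time|date", names(obj), ignore.case = TRUE)))
})

test_that("simulated features join the cohort with stable measured temperatures", {
  cfg <- pipeline_config(image_shape = c(96L, 96L))
  sim <- simulate_study(6, 6, cfg, seed = 3)
  expect_equal(nrow(sim$cohort), 12L)
  expect_true(all(classifier_features() %in% names(sim$cohort)))
  # measured ROI temperature tracks the latent draw: palette quantization
  # (~0.02 deg C) plus resize-to-256 and smoothing at the ROI boundary
  expect_lt(max(abs(sim$cohort$tst_measured - sim$cohort$tst)), 0.15)
  # byte-stable reruns
  sim2 <- simulate_study(6, 6, cfg, seed = 3)
  expect_identical(sim$cohort, sim2$cohort)
})

cli_path <- function() {
  system.file("cli", "thermocad.R", package = "tonguetherm")
}

run_cli <- function(args) {
  res <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(cli_path(), args),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status")
  list(output = res, status = if (is.null(status)) 0L else status)
}

test_that("CLI commands run and are byte-reproducible under a fixed seed", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  for (o in c(out1, out2)) {
    res <- run_cli(c("simulate", "--n-normal", "4", "--n-diabetic", "4",
                     "--seed", "11", "--out", o))
    expect_equal(res$status, 0L)
  }
  f1 <- file.path(out1, "cohort.csv"); f2 <- file.path(out2, "cohort.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(file.path(out1, "fractions.csv")),
                   readLines(file.path(out2, "fractions.csv")))
  expect_identical(readLines(file.path(out1, "manifest.json")),
                   readLines(file.path(out2, "manifest.json")))

  rm1 <- run_cli("reproduce-metrics")
  expect_equal(rm1$status, 0L)
  expect_true(any(grepl("ppv", rm1$output)))

  bad <- run_cli(c("features", "--image", "does-not-exist.png",
                   "--out", file.path(out1, "f.csv")))
  expect_gt(bad$status, 0L)
})
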