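test_that("evaluation statistics match hand-computed values", {
  perfect <- metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unclass(perfect)[c("r2", "rmse", "mae", "mbd", "mspe")],
               list(r2 = 1, rmse = 0, mae = 0, mbd = 0, mspe = 0))
  # predicting the mean gives R2 = 0
  y <- c(2, 4, 9)
  expect_equal(metrics(y, rep(mean(y), 3))$r2, 0)
  m <- metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-9)
  expect_equal(m$mae, 1 / 3, tolerance = 1e-9)
  expect_equal(m$mbd, -1 / 3, tolerance = 1e-9)
  expect_equal(m$mspe, 1 / 3, tolerance = 1e-9)
  expect_equal(m$r2, 0.5, tolerance = 1e-9)
  expect_warning(z <- metrics(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.na(z$r2))
  expect_equal(z$rmse, sqrt(2 / 3))
  expect_error(metrics(1:3, 1:4), class = "chlorospec_input_error")
})

test_that("metric identities hold on random inputs", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    y <- rnorm(n, sd = runif(1, 0.1, 100))
    p <- y + rnorm(n, sd = runif(1, 0.01, 50))
    m <- metrics(y, p)
    expect_equal(m$mspe, m$rmse^2, tolerance = 1e-9)
    expect_gte(m$rmse, m$mae - 1e-12)
    expect_gte(m$mae, abs(m$mbd) - 1e-12)
    expect_lte(m$r2, 1)
  }
})

test_that("every-third split takes positions 3, 6, 9, ...", {
  sp <- split_every_third(1:10)
  expect_equal(sp$validation, c(3, 6, 9))
  expect_equal(sp$training, setdiff(1:10, c(3, 6, 9)))
  expect_equal(sort(c(sp$training, sp$validation)), 1:10)
  expect_equal(split_every_third(1:3)$validation, 3)
  expect_equal(length(split_every_third(1:540)$validation), 180)
  expect_error(split_every_third(1:2), class = "chlorospec_split_error")
  # |validation| = floor(n/3) for assorted n
  for (n in c(3, 4, 5, 17, 100, 271)) {
    expect_length(split_every_third(seq_len(n))$validation, floor(n / 3))
  }
})

test_that("random splits are seeded, sized and disjoint", {
  s1 <- split_random(1:100, fraction = 0.3, seed = 5)
  s2 <- split_random(1:100, fraction = 0.3, seed = 5)
  expect_length(s1$validation, 30)
  expect_identical(s1$validation, s2$validation)
  expect_equal(sort(c(s1$training, s1$validation)), 1:100)
  # extreme fraction leaves at least one training record
  s3 <- split_random(1:10, fraction = 0.999, seed = 1)
  expect_length(s3$validation, 9)
  expect_length(s3$training, 1)
  expect_error(split_random(1:10, fraction = 1.2), class = "chlorospec_config_error")
  # different seeds virtually always differ
  vals <- lapply(1:5, function(s) split_random(1:100, 0.3, seed = s)$validation)
  expect_gt(length(unique(vals)), 1)
})

test_that("splits subset spectra sets and feature tables consistently", {
  set <- generate_dataset(fast_config(n_samples = 9, seed = 31))
  sp <- split_every_third(set)
  expect_s3_class(sp$validation, "spectra_set")
  expect_length(sp$validation, 3)
  ids <- vapply(set$records, `[[`, character(1), "sample_id")
  got <- vapply(sp$validation$records, `[[`, character(1), "sample_id")
  expect_equal(got, ids[c(3, 6, 9)])
  ft <- compute_feature_table(set)
  spf <- split_random(ft, fraction = 0.3, seed = 2)
  expect_s3_class(spf$training, "feature_table")
  expect_equal(nrow(spf$validation), 2)
})

test_that("simple linear calibration recovers exact and noisy lines", {
  x <- c(1, 2, 3, 4, 5)
  up <- simple_linear_calibration(x, 2 * x + 1)
  expect_equal(up$r, 1)
  down <- simple_linear_calibration(x, -2 * x + 5)
  expect_equal(down$slope, -2)
  expect_equal(down$intercept, 5)
  expect_equal(down$r, -1)
  # noisy recovery within the analytic standard-error band
  set.seed(72)
  xv <- rnorm(100)
  yv <- 3 * xv + rnorm(100)
  cal <- simple_linear_calibration(xv, yv)
  se <- summary(lm(yv ~ xv))$coefficients[2, 2]
  expect_lt(abs(cal$slope - 3), 4 * se)
  expect_error(simple_linear_calibration(rep(1, 5), rnorm(5)),
               class = "chlorospec_fit_error")
  # r^2 equals the R2 of the fitted line's predictions
  m <- metrics(yv, cal$fitted)
  expect_equal(cal$r^2, m$r2, tolerance = 1e-12)
})

test_that("the pipeline produces a complete, reproducible report", {
  cfg <- list(seed = 11,
              generator = list(n_samples = 90, wavelength_step = 3),
              models = c("robust_linear", "gpr_matern52"))
  rep <- run_pipeline(cfg)
  expect_s3_class(rep, "run_report")
  expect_named(rep$models, c("robust_linear", "gpr_matern52"))
  for (m in rep$models) {
    for (stage in c("training", "validation")) {
      expect_s3_class(m[[stage]], "metrics_bundle")
      expect_true(all(is.finite(unlist(unclass(m[[stage]])))))
    }
  }
  expect_equal(rep$n_training + rep$n_validation, 90)
  expect_s3_class(rep$mrmr, "mrmr_ranking")
  expect_s3_class(rep$collinearity, "collinearity_report")
  expect_length(rep$index_calibration, 11)

  # restricting the model list restricts the report
  rep1 <- run_pipeline(utils::modifyList(cfg, list(models = "gpr_matern52")))
  expect_named(rep1$models, "gpr_matern52")

  # identical configs give byte-identical serialized reports
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_run_report(run_pipeline(cfg), d1)
  write_run_report(rep, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "model_metrics.csv")),
                   readLines(file.path(d2, "model_metrics.csv")))
})

test_that("the pipeline accepts a JSON config file and a spectra CSV source", {
  set <- generate_dataset(fast_config(n_samples = 60, seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(set, csv)
  cfgfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 2, spectra_csv = csv,
                            models = "robust_linear"),
                       cfgfile, auto_unbox = TRUE)
  rep <- run_pipeline(cfgfile)
  expect_named(rep$models, "robust_linear")
  expect_equal(rep$n_training + rep$n_validation, 60)
})
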