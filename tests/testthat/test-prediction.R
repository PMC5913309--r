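test_that("the reference equation reproduces its published form", {
  eq <- histi_equation()
  zero <- c(health_infrastructure = 0, surface_transport_infrastructure = 0)
  expect_identical(histi_predict(eq, zero), -2639.6)

  vals <- c(health_infrastructure = 1e7, surface_transport_infrastructure = 1e6)
  expect_equal(histi_predict(eq, vals), -2639.6 + 2570 + 2630)

  # affine identity to float precision
  expect_equal(histi_predict(eq, 2 * vals) + histi_predict(eq, 0 * vals),
               2 * histi_predict(eq, vals))

  expect_error(histi_predict(eq, c(health_infrastructure = 1)),
               class = "abx_schema_error")
  expect_error(affine_equation(0, c(1, 2)), class = "abx_schema_error")
  expect_error(affine_equation(0, c(a = 1, a = 2)), class = "abx_schema_error")
})

test_that("histi_predict vectorizes over data-frame rows", {
  eq <- histi_equation()
  df <- tibble::tibble(year = 2011:2012,
                       health_infrastructure = c(1e7, 2e7),
                       surface_transport_infrastructure = c(1e6, 2e6))
  out <- histi_predict(eq, df)
  expect_equal(out, c(2560.4, 7760.4))
})

test_that("equations derived from fits agree with model predictions", {
  set.seed(6)
  x <- matrix(rnorm(22), 11, 2, dimnames = list(NULL, c("a", "b")))
  y <- 3 + x %*% c(2, -1) + rnorm(11, 0, .1)
  fit <- fit_pls1(x, y, ncomp = 2)
  eq <- as_equation(fit)
  v <- c(a = 0.3, b = -1.2)
  expect_equal(histi_predict(eq, v),
               predict(fit, matrix(v, 1, dimnames = list(NULL, c("a", "b")))))
})

test_that("bootstrap intervals are seeded, nested across levels and tight at zero noise", {
  set.seed(8)
  x <- matrix(rnorm(22), 11, 2, dimnames = list(NULL, c("a", "b")))
  y_clean <- as.numeric(10 + x %*% c(3, 1))
  cand <- candidate_model("pair", c("a", "b"))
  x_new <- c(a = 0.5, b = 0.5)

  pi_clean <- prediction_interval(x, y_clean, cand, x_new, n_boot = 300,
                                  seed = 4)
  expect_lt(pi_clean$ci_high - pi_clean$ci_low, 1e-6 * abs(pi_clean$point))

  y <- y_clean + rnorm(11, 0, 1)
  p1 <- prediction_interval(x, y, cand, x_new, n_boot = 300, seed = 9)
  p2 <- prediction_interval(x, y, cand, x_new, n_boot = 300, seed = 9)
  expect_identical(p1, p2)
  expect_lte(p1$ci_low, p1$point)
  expect_gte(p1$ci_high, p1$point)

  p90 <- prediction_interval(x, y, cand, x_new, level = 0.90, n_boot = 300,
                             seed = 9)
  p99 <- prediction_interval(x, y, cand, x_new, level = 0.99, n_boot = 300,
                             seed = 9)
  expect_lte(p99$ci_low, p90$ci_low)
  expect_gte(p99$ci_high, p90$ci_high)

  expect_error(prediction_interval(x, y, cand, x_new, n_boot = 100, seed = 1),
               class = "abx_config_error")
  expect_error(prediction_interval(x, y, cand, x_new, level = 1.5,
                                   n_boot = 300, seed = 1),
               class = "abx_config_error")
})

test_that("degenerate bootstrap resamples are skipped and counted", {
  # with only 3 distinct rows, some resamples have constant response
  x <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(1, 2, 4)
  pi <- prediction_interval(x, y, candidate_model("one", "a"),
                            c(a = 2), n_boot = 300, seed = 12)
  expect_lt(pi$n_boot_used, 300)
  expect_gte(pi$n_boot_used, 150)
})

test_that("state disaggregation scales determinants, floors and flags", {
  eq <- histi_equation()
  national <- c(health_infrastructure = 2e7,
                surface_transport_infrastructure = 5e6)
  ones <- c(health_infrastructure = 1, surface_transport_infrastructure = 1)

  st <- disaggregate_state(eq, national, ones, population = 1e6,
                           state = "whole country")
  expect_equal(st$per_1000, histi_predict(eq, national))
  expect_equal(st$total, st$per_1000 * 1e6 / 1000)
  expect_true(is.na(st$data_flags))

  floor0 <- disaggregate_state(eq, national, 0 * ones, state = "zero")
  expect_identical(floor0$per_1000, 0)
  expect_match(floor0$data_flags, "floored")

  missing_share <- disaggregate_state(
    eq, national, c(health_infrastructure = 0.1), state = "no rail data")
  expect_true(is.na(missing_share$per_1000))
  expect_match(missing_share$data_flags, "missing share")
  expect_match(missing_share$data_flags, "surface_transport_infrastructure")

  expect_error(disaggregate_state(eq, national, ones * 2),
               class = "abx_input_error")

  scaled <- disaggregate_state(eq, national, 0.5 * ones, population = 1e6,
                               method = "scale_prediction")
  expect_equal(scaled$per_1000, 0.5 * histi_predict(eq, national))
})

test_that("total consumption matches the published national projection", {
  expect_equal(total_consumption(1000, 1e6), 1e6)

  # the implied 2014 population reproduces the published national total
  per_1000 <- 11597
  published_total <- 14367372539
  population <- published_total / per_1000 * 1000
  expect_equal(signif(total_consumption(per_1000, population), 4),
               signif(published_total, 4))

  expect_error(total_consumption(0, 1e6), class = "abx_input_error")
  expect_error(total_consumption(100, 0), class = "abx_input_error")
})

test_that("reports render deterministically with optional sections", {
  cv <- tibble::tibble(label = c("m1", "m2"),
                       rmsep_cv = c(583.2, 376.0),
                       rmsep_adjcv = c(572.2, 365.5))
  forecasts <- tibble::tibble(year = 2011:2014,
                              point = c(10787, 11308, 10220, 11597),
                              ci_low = c(9153, 9432, 9715, 7545),
                              ci_high = c(12421, 13184, 10724, 15650),
                              ci_level = 0.95, n_boot_used = 2000L)
  states <- dplyr::bind_rows(
    disaggregate_state(histi_equation(),
                       c(health_infrastructure = 5e7,
                         surface_transport_infrastructure = 5e6),
                       c(health_infrastructure = 0.6,
                         surface_transport_infrastructure = 0.8),
                       population = 1e8, state = "big state"))

  dir1 <- withr::local_tempdir()
  files <- render_reports(cv, forecasts, states, dir1, plots = FALSE)
  expect_setequal(basename(files),
                  c("model_comparison.csv", "model_comparison.txt",
                    "forecasts.csv", "forecasts.txt",
                    "state_estimates.csv", "state_estimates.txt"))

  fc_lines <- readLines(file.path(dir1, "forecasts.csv"))
  expect_length(fc_lines, 5)
  expect_match(fc_lines[5], "11597 \\(7545, 15650\\)")

  # byte-identical on repeat; state table omitted when no states
  dir2 <- withr::local_tempdir()
  render_reports(cv, forecasts, states, dir2, plots = FALSE)
  for (f in c("model_comparison.csv", "forecasts.csv", "state_estimates.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }

  dir3 <- withr::local_tempdir()
  files3 <- render_reports(cv, forecasts, NULL, dir3, plots = FALSE)
  expect_false(any(grepl("state", basename(files3))))
})

test_that("plot builders return ggplot objects", {
  inst <- random_instance(5, n = 10, p = 3)
  fit <- fit_pls1(inst$x, inst$y, ncomp = 2)
  expect_s3_class(plot_loadings(fit), "ggplot")
  expect_s3_class(autoplot(fit, type = "fitted"), "ggplot")
  expect_s3_class(
    plot_measured_vs_predicted(tibble::tibble(measured = inst$y,
                                              predicted = fit$fitted)),
    "ggplot"
  )
  # plots materialize without error
  built <- ggplot2::ggplot_build(plot_loadings(fit))
  expect_identical(nrow(built$data[[1]]), 6L)
})
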