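test_that("each model form evaluates its stated functional shape", {
  expect_equal(predict_optical(list(form = "ndvi_exp", a = 1, b = 0), 0), 1)
  expect_equal(predict_optical(list(form = "rtvi_linear", a = 2, b = 3), 0.5), 4)
  expect_equal(predict_optical(list(form = "sr_log", a = 3, b = 1), 1), 1)
  expect_equal(predict_optical(list(form = "srre_linear", a = -1, b = 2), 2), 0)
  expect_error(predict_optical(list(form = "sr_log", a = 1, b = 0), -2),
               "positive")
})

test_that("iterative fits agree with closed-form least squares on all forms", {
  cal <- fix_parts$calibration
  for (f in c("ndvi_exp", "rtvi_linear", "sr_log", "srre_linear")) {
    fit <- calibrate_optical(cal, f, seed = 3)
    x <- wcmbiomass:::vi_transform(f, cal$ndvi)
    ols <- stats::coef(stats::lm(cal$wet_biomass ~ x))
    expect_lt(abs(fit$a - ols[[2]]), 1e-8)
    expect_lt(abs(fit$b - ols[[1]]), 1e-8)
    expect_lt(fit$fit_sse, fit$initial_sse)
  }
})

test_that("noise-free synthetic curves are recovered exactly", {
  nd <- withr::with_seed(1, runif(30, 0.1, 0.9))
  d <- tibble::tibble(ndvi = nd, wet_biomass = 2 * exp(nd) - 1)
  fit <- calibrate_optical(d, "ndvi_exp", seed = 4)
  expect_lt(abs(fit$a - 2), 1e-6)
  expect_lt(abs(fit$b + 1), 1e-6)
  expect_lt(max(abs(predict_optical(fit, nd) - d$wet_biomass)), 1e-6)

  # two points, linear form: the interpolating line, SSE 0
  d2 <- tibble::tibble(ndvi = c(0.2, 0.6), wet_biomass = c(1, 3))
  f2 <- calibrate_optical(d2, "rtvi_linear", seed = 1)
  expect_equal(f2$a, 5, tolerance = 1e-6)
  expect_equal(f2$b, 0, tolerance = 1e-6)
  expect_lt(f2$fit_sse, 1e-12)
})

test_that("degenerate calibration inputs are rejected", {
  d <- tibble::tibble(ndvi = rep(0.5, 10), wet_biomass = runif(10))
  expect_error(calibrate_optical(d, "ndvi_exp"), "rank-deficien")
  expect_error(calibrate_optical(tibble::tibble(ndvi = 0.5, wet_biomass = 1),
                                 "ndvi_exp"), "two points")
  d3 <- tibble::tibble(ndvi = c(-0.1, 0.5), wet_biomass = c(1, 2))
  expect_error(calibrate_optical(d3, "sr_log"), "positive")
  expect_error(calibrate_optical(fix_parts$calibration, "ndvi_exp",
                                 vi_col = "missing"), "missing")
})

test_that("vegetation indices follow their band formulas", {
  refl <- tibble::tibble(green = 0.1, red = 0.1, red_edge = 0.3, nir = 0.4)
  expect_equal(compute_index(refl, "ndvi"), 0.6)
  expect_equal(compute_index(dplyr::mutate(refl, red = nir), "ndvi"), 0)
  expect_equal(compute_index(refl, "sr"), 4)
  expect_equal(compute_index(refl, "srre"), 4 / 3)
  expect_equal(compute_index(refl, "rtvi"), 100 * 0.1 - 10 * 0.3)

  expect_error(compute_index(refl[, c("red", "nir")], "rtvi"), "green")
  expect_error(compute_index(tibble::tibble(red = 0, nir = 0), "ndvi"),
               "denominator")
  # NDVI stays within [-1, 1] for non-negative reflectance
  r <- withr::with_seed(2, tibble::tibble(red = runif(100), nir = runif(100)))
  nd <- compute_index(r, "ndvi")
  expect_true(all(nd >= -1 & nd <= 1))
})

test_that("optical models serialize to text and back", {
  fit <- calibrate_optical(fix_parts$calibration, "ndvi_exp", seed = 3)
  tmp <- withr::local_tempfile(fileext = ".yml")
  write_optical_model(fit, tmp)
  back <- read_optical_model(tmp)
  expect_equal(back$a, fit$a, tolerance = 1e-12)
  expect_equal(back$b, fit$b, tolerance = 1e-12)
  expect_identical(back$form, "ndvi_exp")
  expect_equal(predict_optical(back, 0.8), predict_optical(fit, 0.8),
               tolerance = 1e-10)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(tidy(fit)$term, c("a", "b"))
})
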