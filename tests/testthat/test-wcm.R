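test_that("the forward model reduces to the soil term when the canopy vanishes", {
  cf0 <- wcm_coefficients(A = 0.4, B = 0, C = 0.7, D = 0.03, E1 = 0.5, E2 = 0.5)
  # B = 0: attenuation is 1 and the canopy term vanishes for any biomass
  expect_equal(wcm_forward(cf0, 3.2, 0.25, 27), 0.7 * 0.25 + 0.03)

  cf <- default_true_coefs("hh")
  # L -> 0 limit with positive exponents
  expect_equal(wcm_forward(cf, 0, 0.25, 27), cf$C * 0.25 + cf$D)
  expect_equal(wcm_forward(cf, 1e-14, 0.25, 27), cf$C * 0.25 + cf$D,
               tolerance = 1e-6)
})

test_that("the forward model enforces its domain", {
  cf <- default_true_coefs("hh")
  expect_error(wcm_forward(cf, -1, 0.2, 27), "non-negative")
  expect_error(wcm_forward(cf, 1, 0.2, 0), "incidence")
  expect_error(wcm_forward(cf, 1, 0.2, 90), "incidence")
  bad <- wcm_coefficients(0.2, 0.3, 0.5, 0.05, E1 = -0.5, E2 = 0.5)
  expect_error(wcm_forward(bad, 0, 0.2, 27), "positive exponents")
  expect_error(wcm_coefficients(Inf, 1, 1, 1, 1, 1), "finite")
})

test_that("backscatter increases with soil moisture at fixed biomass", {
  for (seed in 1:5) {
    cf <- withr::with_seed(seed, {
      v <- runif(6, 0.05, 0.95)
      wcm_coefficients(v[1], v[2], v[3], v[4], v[5], v[6])
    })
    for (L in c(0.05, 0.8, 3, 7)) {
      mv <- seq(0.03, 0.4, length.out = 25)
      sig <- wcm_forward(cf, L, mv, 27)
      expect_true(all(diff(sig) > 0))
    }
  }
})

test_that("calibration validates its inputs", {
  expect_error(calibrate_wcm(fix_parts$calibration[1:5, ], "hh"),
               "at least six")
  const <- fix_parts$calibration
  const$wet_biomass <- 1.5
  const$dry_biomass <- 0.2
  expect_warning(calibrate_wcm(const, "hh", n_restarts = 2, max_iter = 5),
                 "rank-deficient")
  neg <- fix_parts$calibration
  neg$hh_backscatter[3] <- -neg$hh_backscatter[3]
  expect_error(calibrate_wcm(neg, "hh"), "positive")
})

test_that("noise-free calibration reproduces the generating backscatter", {
  tab <- nf_sim$table
  for (pol in c("hh", "hv")) {
    fit <- calibrate_wcm(tab, pol, seed = 5, n_restarts = 20)
    y <- tab[[paste0(pol, "_backscatter")]]
    expect_lt(max(abs(fit$fitted - y) / y), 1e-6)
    expect_equal(fit$sse, sum(fit$residuals^2), tolerance = 1e-12)
  }
})

test_that("calibration is deterministic given the seed and improves on every start", {
  a <- calibrate_wcm(fix_parts$calibration, "hv", seed = 42, n_restarts = 3,
                     max_iter = 40)
  b <- calibrate_wcm(fix_parts$calibration, "hv", seed = 42, n_restarts = 3,
                     max_iter = 40)
  expect_identical(unclass(a$coefficients), unclass(b$coefficients))
  expect_identical(a$restarts, b$restarts)

  # best SSE strictly beats the best random initial draw
  expect_lt(fix_hh$sse, min(fix_hh$restarts$initial_sse))
  expect_lt(fix_hv$sse, min(fix_hv$restarts$initial_sse))
  expect_true(all(fix_hh$restarts$sse <= fix_hh$restarts$initial_sse))
  expect_lte(fix_hh$iterations, 100)
})

test_that("fitted-model predictions at a study point match an independent re-fit", {
  # compare at the best restart that reached a stationary point: polish that
  # solution with minpack.lm and require the same prediction at point 1
  fit <- calibrate_wcm(fix_parts$calibration, "hh", seed = 7, tol = 1e-14,
                       max_iter = 600, n_restarts = 20)
  att <- dplyr::filter(fit$restarts, reason != "max_iter")
  best <- att[which.min(att$sse), ]
  par <- unlist(best[, c("A", "B", "C", "D", "E1", "E2")])
  fn <- wcm_objective(fix_parts$calibration, "hh")
  oracle <- suppressWarnings(minpack.lm::nls.lm(
    par, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 0, ptol = 0,
                                         gtol = 0)))
  r1 <- fix_parts$calibration[1, ]
  mine <- wcmbiomass:::.wcm_eval(par, r1$wet_biomass, r1$soil_moisture,
                                 r1$incidence_angle)
  theirs <- wcmbiomass:::.wcm_eval(oracle$par, r1$wet_biomass, r1$soil_moisture,
                                   r1$incidence_angle)
  expect_lt(abs(mine - theirs), 1e-6)
  # and the modelled value is the observation's order of magnitude
  expect_gt(mine, 0.1 * r1$hh_backscatter)
  expect_lt(mine, 10 * r1$hh_backscatter)
})

test_that("inversion is the right inverse of the forward model", {
  cf_hh <- default_true_coefs("hh")
  cf_hv <- default_true_coefs("hv")
  grid <- expand.grid(L = c(0.1, 0.9, 2.5, 5.5), Mv = c(0.06, 0.2, 0.35),
                      theta = c(22, 27, 31))
  sig <- tibble::tibble(
    hh_backscatter = wcm_forward(cf_hh, grid$L, grid$Mv, grid$theta),
    hv_backscatter = wcm_forward(cf_hv, grid$L, grid$Mv, grid$theta),
    incidence_angle = grid$theta
  )
  inv <- invert_wcm(sig, cf_hh, cf_hv)
  ok <- inv$converged
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(inv$biomass[ok] - grid$L[ok])), 1e-4)
  expect_lt(max(abs(inv$soil_moisture[ok] - grid$Mv[ok])), 1e-4)

  # forward ∘ invert ∘ forward = forward on converged points
  back <- wcm_forward(cf_hh, inv$biomass[ok], inv$soil_moisture[ok],
                      grid$theta[ok])
  expect_lt(max(abs(back - sig$hh_backscatter[ok])), 1e-6)
})

test_that("with no canopy attenuation the soil moisture is recovered but biomass is not identified", {
  cf_hh <- wcm_coefficients(0.3, 0, 0.8, 0.05, 0.5, 0.5, "hh")
  cf_hv <- wcm_coefficients(0.1, 0, 0.2, 0.01, 0.5, 0.5, "hv")
  mv_true <- 0.27
  d <- tibble::tibble(hh_backscatter = 0.8 * mv_true + 0.05,
                      hv_backscatter = 0.2 * mv_true + 0.01,
                      incidence_angle = 27)
  inv <- invert_wcm(d, cf_hh, cf_hv)
  expect_equal(inv$soil_moisture, mv_true, tolerance = 1e-8)
  # biomass stays at its (arbitrary) starting value: unidentifiable
  expect_equal(inv$biomass, 1.0, tolerance = 1e-6)
})

test_that("all validation points are inverted, each with a convergence flag", {
  inv <- invert_wcm(fix_parts$validation, fix_hh, fix_hv)
  expect_equal(nrow(inv), 43)
  expect_type(inv$converged, "logical")
  expect_identical(inv$point_no, fix_parts$validation$point_no)
  expect_true(all(is.finite(inv$biomass)))
  expect_true(all(inv$iterations <= 400))
  expect_true(all(inv$residual_norm[inv$converged] <= 1e-6))
})

test_that("coefficients serialize to text and back", {
  tmp <- withr::local_tempfile(fileext = ".yml")
  write_wcm_coefficients(fix_hh, tmp)
  back <- read_wcm_coefficients(tmp)
  expect_s3_class(back, "wcm_coefficients")
  expect_equal(unclass(back)[1:6], unclass(fix_hh$coefficients)[1:6],
               tolerance = 1e-12)
  expect_identical(back$polarization, "hh")
})

test_that("fit accessors expose the model in tabular form", {
  td <- tidy(fix_hh)
  expect_equal(td$term, c("A", "B", "C", "D", "E1", "E2"))
  gl <- glance(fix_hh)
  expect_equal(gl$n, 23)
  expect_s3_class(autoplot(fix_hh), "ggplot")
})
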