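# Shared objects for the test suite. Helpers are sourced once per run, so the
# heavier fixture calibrations live here and are reused across files.

fix_obs <- corn_observations()
fix_parts <- split_observations(fix_obs)

# fixture Water Cloud Model fits under the study's defaults
fix_hh <- calibrate_wcm(fix_parts$calibration, "hh", seed = 7)
fix_hv <- calibrate_wcm(fix_parts$calibration, "hv", seed = 7)

# noise-free synthetic table over the study ranges, with its generating truth
nf_sim <- simulate_observations(synthetic_config(noise_cv = 0, ndvi_noise_sd = 0,
                                                 seed = 11))

# least-squares WCM objective for one polarization of a record table, for
# hand-rolled oracle comparisons
wcm_objective <- function(records, polarization, biomass_kind = "wet") {
  y <- records[[paste0(polarization, "_backscatter")]]
  L <- records[[paste0(biomass_kind, "_biomass")]]
  Mv <- records$soil_moisture
  theta <- records$incidence_angle
  function(par) wcmbiomass:::.wcm_eval(par, L, Mv, theta) - y
}

expect_tibble_identical <- function(a, b) {
  norm <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "class", "row.names")]
    x
  }
  expect_identical(norm(a), norm(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
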