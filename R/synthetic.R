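#' Configuration for synthetic observation tables
#'
#' Describes the statistical structure the retrieval method assumes: biomass,
#' soil moisture and incidence angle drawn uniformly over the spans the corn
#' study covered, backscatter generated by the Water Cloud Model forward
#' computation with multiplicative lognormal (speckle-like) noise, and NDVI
#' consistent with a configurable vegetation-index model plus small additive
#' noise. The defaults mirror the study's calibration conditions: 23 points,
#' wet biomass 0.04–7.1 kg m^-2, soil moisture 0.039–0.379 m^3 m^-3,
#' incidence 21.025–31.9592 degrees.
#'
#' Dry biomass is linked to wet biomass by a fixed ratio (default 0.15,
#' within the range the corn observations exhibit). The generating
#' coefficients default to values that reproduce the magnitudes of the
#' observed HH (~0.07–0.6) and HV (~0.004–0.03) power, with all six
#' coefficients inside (0, 1).
#'
#' @param n_points Number of observation points (at least 6).
#' @param biomass_range Wet-biomass span, kg m^-2.
#' @param soil_moisture_range Volumetric soil-moisture span, m^3 m^-3.
#' @param incidence_range Incidence-angle span, degrees.
#' @param true_coefs_hh,true_coefs_hv Generating [wcm_coefficients()].
#' @param noise_cv Coefficient of variation of the multiplicative backscatter
#'   noise (0 = noise-free).
#' @param optical_true Generating vegetation-index model (an `optical_fit` or
#'   list with `form`, `a`, `b`); NDVI is obtained by inverting it at the
#'   drawn biomass.
#' @param ndvi_noise_sd Additive NDVI noise standard deviation.
#' @param dry_wet_ratio Fixed dry:wet biomass ratio.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_points = 23L,
                             biomass_range = c(0.04, 7.1),
                             soil_moisture_range = c(0.039, 0.379),
                             incidence_range = c(21.025, 31.9592),
                             true_coefs_hh = default_true_coefs("hh"),
                             true_coefs_hv = default_true_coefs("hv"),
                             noise_cv = 0.05,
                             optical_true = default_true_optical(),
                             ndvi_noise_sd = 0.005,
                             dry_wet_ratio = 0.15,
                             seed = 1L) {
  cfg <- list(n_points = as.integer(n_points), biomass_range = biomass_range,
              soil_moisture_range = soil_moisture_range,
              incidence_range = incidence_range,
              true_coefs_hh = true_coefs_hh, true_coefs_hv = true_coefs_hv,
              noise_cv = noise_cv, optical_true = optical_true,
              ndvi_noise_sd = ndvi_noise_sd, dry_wet_ratio = dry_wet_ratio,
              seed = as.integer(seed))
  for (r in c("biomass_range", "soil_moisture_range", "incidence_range")) {
    if (length(cfg[[r]]) != 2 || cfg[[r]][1] >= cfg[[r]][2]) {
      abort(paste0("`", r, "` must be an ordered (min, max) pair"))
    }
  }
  if (cfg$n_points < 6) abort("`n_points` must be at least 6 (one per model coefficient)")
  if (cfg$noise_cv < 0) abort("`noise_cv` must be non-negative")
  if (cfg$dry_wet_ratio <= 0 || cfg$dry_wet_ratio > 1) {
    abort("`dry_wet_ratio` must lie in (0, 1]")
  }
  stopifnot(inherits(cfg$true_coefs_hh, "wcm_coefficients"),
            inherits(cfg$true_coefs_hv, "wcm_coefficients"))
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @param polarization Which channel's generating coefficients to return.
#' @export
default_true_coefs <- function(polarization = c("hh", "hv")) {
  polarization <- match.arg(polarization)
  if (polarization == "hh") {
    wcm_coefficients(A = 0.25, B = 0.35, C = 0.9, D = 0.05,
                     E1 = 0.25, E2 = 0.5, polarization = "hh")
  } else {
    wcm_coefficients(A = 0.02, B = 0.25, C = 0.01, D = 0.003,
                     E1 = 0.3, E2 = 0.45, polarization = "hv")
  }
}

#' @rdname synthetic_config
#' @export
default_true_optical <- function() {
  structure(list(form = "ndvi_exp", a = 4.9, b = -5.9, biomass_kind = "wet"),
            class = "optical_fit")
}

#' Generate a synthetic observation table
#'
#' Draws (biomass, soil moisture, incidence angle) uniformly over the
#' configured ranges, computes HH and HV backscatter with the Water Cloud
#' Model forward computation, multiplies by unit-mean lognormal noise with
#' coefficient of variation `noise_cv` (multiplicative noise keeps power
#' strictly positive, as radar speckle does), and derives NDVI by inverting
#' the configured vegetation-index model at the drawn wet biomass with small
#' additive noise, clipped to \[-1, 1\].
#'
#' @param config A [synthetic_config()].
#' @return A list with `table` (a validated `obs_table` whose rows are all
#'   calibration points) and `truth` (the generating parameters plus the
#'   noise-free backscatter), for parameter-recovery scoring.
#' @examples
#' sim <- simulate_observations(synthetic_config(noise_cv = 0, seed = 42))
#' head(sim$table, 3)
#' @export
simulate_observations <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config()")
  }
  n <- config$n_points
  draws <- withr::with_seed(config$seed, {
    wet <- runif(n, config$biomass_range[1], config$biomass_range[2])
    mv <- runif(n, config$soil_moisture_range[1], config$soil_moisture_range[2])
    theta <- runif(n, config$incidence_range[1], config$incidence_range[2])
    noise_hh <- lognormal_noise(n, config$noise_cv)
    noise_hv <- lognormal_noise(n, config$noise_cv)
    ndvi_eps <- rnorm(n, 0, config$ndvi_noise_sd)
    list(wet = wet, mv = mv, theta = theta, noise_hh = noise_hh,
         noise_hv = noise_hv, ndvi_eps = ndvi_eps)
  })

  sigma_hh <- wcm_forward(config$true_coefs_hh, draws$wet, draws$mv, draws$theta)
  sigma_hv <- wcm_forward(config$true_coefs_hv, draws$wet, draws$mv, draws$theta)
  ndvi <- invert_optical(config$optical_true, draws$wet) + draws$ndvi_eps
  ndvi <- pmin(pmax(ndvi, -1), 1)

  table <- as_obs_table(
    tibble(point_no = seq_len(n),
           dry_biomass = config$dry_wet_ratio * draws$wet,
           wet_biomass = draws$wet,
           soil_moisture = draws$mv,
           hh_backscatter = sigma_hh * draws$noise_hh,
           hv_backscatter = sigma_hv * draws$noise_hv,
           incidence_angle = draws$theta,
           ndvi = ndvi),
    n_calibration = n)
  truth <- list(wet_biomass = draws$wet, soil_moisture = draws$mv,
                incidence_angle = draws$theta,
                sigma_hh_clean = sigma_hh, sigma_hv_clean = sigma_hv,
                coefs_hh = config$true_coefs_hh, coefs_hv = config$true_coefs_hv,
                optical = config$optical_true, config = config)
  list(table = table, truth = truth)
}

# unit-mean multiplicative lognormal noise with the requested CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# vegetation index at which the model predicts the given biomass
invert_optical <- function(model, biomass) {
  switch(model$form,
         ndvi_exp = log((biomass - model$b) / model$a),
         rtvi_linear = (biomass - model$b) / model$a,
         sr_log = exp((biomass - model$b) / model$a),
         srre_linear = (biomass - model$b) / model$a,
         abort(paste0("unknown optical model form: ", model$form)))
}

#' Write the ground truth of a synthetic table to a sidecar file
#'
#' @param truth The `truth` element returned by [simulate_observations()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  cfg <- truth$config
  yaml::write_yaml(
    list(coefs_hh = unclass(truth$coefs_hh), coefs_hv = unclass(truth$coefs_hv),
         optical = unclass(truth$optical)[c("form", "a", "b")],
         noise_cv = cfg$noise_cv, seed = cfg$seed, n_points = cfg$n_points,
         wet_biomass = truth$wet_biomass, soil_moisture = truth$soil_moisture,
         incidence_angle = truth$incidence_angle),
    path, precision = 17)
  invisible(path)
}
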