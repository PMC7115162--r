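#' End-to-end biomass retrieval pipeline
#'
#' Runs the full method on one observation table:
#' 1. calibrate the Water Cloud Model for HH and HV on the calibration rows;
#' 2. invert the calibrated pair for biomass and soil moisture at every point
#'    (calibration and validation);
#' 3. fit the requested vegetation-index biomass models on the calibration
#'    rows;
#' 4. train the transfer network on the calibration-row pairs (radar estimate
#'    as input, optical estimate as target);
#' 5. apply the network (with a final absolute value) to the validation-row
#'    radar estimates.
#'
#' When `output_dir` is given, the per-validation-point estimates are written
#' to `estimates.csv`, the fitted models to key-value text files, the network
#' to JSON, and the seeds plus all solver diagnostics to `run_log.yml`; two
#' runs with identical configuration produce byte-identical outputs.
#'
#' @param input An `obs_table`, a data frame with the canonical columns, or a
#'   path to a CSV in the canonical layout.
#' @param output_dir Directory for output files, created if needed; `NULL`
#'   (default) skips writing.
#' @param n_calibration Leading calibration rows (used when `input` is a path
#'   or plain data frame).
#' @param biomass_kind Which biomass the Water Cloud Model and optical models
#'   target, `"wet"` or `"dry"`.
#' @param optical_forms Vegetation-index model forms to fit; the first one
#'   (fitted on the `vi_col` index) supplies the optical estimates the
#'   transfer network is trained against.
#' @param vi_col Vegetation-index column used for the optical fits.
#' @param seed_calibration,seed_nn Seeds for the model calibrations and the
#'   network split/initialisation.
#' @param cal_tol,cal_max_iter,n_restarts Calibration solver settings.
#' @param inv_tol,inv_max_iter Inversion solver settings.
#' @param nn_hidden,nn_max_iter Transfer-network settings.
#' @return Invisibly, a list with `estimates` (tibble over validation points:
#'   `point_no`, `sar_biomass`, `sar_soil_moisture`, `sar_converged`,
#'   `optical_biomass`, `adjusted_biomass`), `calibration_estimates`,
#'   `wcm_hh`, `wcm_hv`, `optical` (named list of fits), `network`, and `log`.
#' @examples
#' \donttest{
#' res <- run_pipeline(corn_observations(), seed_calibration = 7, n_restarts = 5)
#' head(res$estimates)
#' }
#' @export
run_pipeline <- function(input, output_dir = NULL, n_calibration = 23,
                         biomass_kind = c("wet", "dry"),
                         optical_forms = "ndvi_exp", vi_col = "ndvi",
                         seed_calibration = 1L, seed_nn = 1L,
                         cal_tol = 1e-8, cal_max_iter = 100L, n_restarts = 20L,
                         inv_tol = 1e-6, inv_max_iter = 400L,
                         nn_hidden = 10L, nn_max_iter = 1000L) {
  biomass_kind <- match.arg(biomass_kind)
  if (cal_tol <= 0 || inv_tol <= 0) abort("tolerances must be positive")
  if (cal_max_iter < 1 || inv_max_iter < 1 || nn_max_iter < 1) {
    abort("iteration caps must be at least 1")
  }

  obs <- if (is.character(input)) {
    read_observations(input, n_calibration = n_calibration)
  } else if (inherits(input, "obs_table")) {
    input
  } else {
    as_obs_table(input, n_calibration = n_calibration)
  }
  parts <- split_observations(obs)
  cal <- parts$calibration
  val <- parts$validation
  if (nrow(val) == 0) abort("the table has no validation rows to adjust")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  fit_hh <- stage("calibrate-wcm-hh",
                  calibrate_wcm(cal, "hh", biomass_kind, seed = seed_calibration,
                                tol = cal_tol, max_iter = cal_max_iter,
                                n_restarts = n_restarts))
  fit_hv <- stage("calibrate-wcm-hv",
                  calibrate_wcm(cal, "hv", biomass_kind, seed = seed_calibration,
                                tol = cal_tol, max_iter = cal_max_iter,
                                n_restarts = n_restarts))

  inv_cal <- stage("invert-calibration",
                   invert_wcm(cal, fit_hh, fit_hv, tol = inv_tol,
                              max_iter = inv_max_iter))
  inv_val <- stage("invert-validation",
                   invert_wcm(val, fit_hh, fit_hv, tol = inv_tol,
                              max_iter = inv_max_iter))

  biomass_col <- paste0(biomass_kind, "_biomass")
  optical <- stage("fit-optical", {
    fits <- lapply(optical_forms, function(f) {
      calibrate_optical(cal, f, vi_col = vi_col, biomass_col = biomass_col,
                        seed = seed_calibration, tol = cal_tol,
                        max_iter = cal_max_iter)
    })
    setNames(fits, optical_forms)
  })
  lead_optical <- optical[[1]]

  opt_cal <- predict_optical(lead_optical, cal[[vi_col]])
  opt_val <- predict_optical(lead_optical, val[[vi_col]])

  net <- stage("train-transfer",
               train_transfer(NULL, sar = inv_cal$biomass, optical = opt_cal,
                              hidden = nn_hidden, seed = seed_nn,
                              max_iter = nn_max_iter))
  adjusted <- stage("apply-transfer", apply_transfer(net, inv_val$biomass))

  estimates <- tibble(point_no = val$point_no,
                      sar_biomass = inv_val$biomass,
                      sar_soil_moisture = inv_val$soil_moisture,
                      sar_converged = inv_val$converged,
                      optical_biomass = opt_val,
                      adjusted_biomass = adjusted)
  calibration_estimates <- tibble(point_no = cal$point_no,
                                  sar_biomass = inv_cal$biomass,
                                  sar_soil_moisture = inv_cal$soil_moisture,
                                  sar_converged = inv_cal$converged,
                                  optical_biomass = opt_cal)

  log <- list(
    n_records = nrow(obs), n_calibration = nrow(cal), n_validation = nrow(val),
    biomass_kind = biomass_kind,
    seed_calibration = as.integer(seed_calibration), seed_nn = as.integer(seed_nn),
    cal_tol = cal_tol, cal_max_iter = as.integer(cal_max_iter),
    n_restarts = as.integer(n_restarts),
    inv_tol = inv_tol, inv_max_iter = as.integer(inv_max_iter),
    wcm_hh = list(sse = fit_hh$sse, converged = fit_hh$converged,
                  restarts = as.data.frame(fit_hh$restarts)),
    wcm_hv = list(sse = fit_hv$sse, converged = fit_hv$converged,
                  restarts = as.data.frame(fit_hv$restarts)),
    inversion = list(n_converged_validation = sum(inv_val$converged),
                     n_converged_calibration = sum(inv_cal$converged)),
    optical = lapply(optical, function(f) list(form = f$form, a = f$a, b = f$b,
                                               sse = f$fit_sse)),
    transfer = list(n_train = net$n_train, n_holdout = net$n_holdout,
                    train_mse = net$train_mse, holdout_mse = net$holdout_mse,
                    iterations = net$iterations, reason = net$reason)
  )

  result <- list(estimates = estimates,
                 calibration_estimates = calibration_estimates,
                 wcm_hh = fit_hh, wcm_hv = fit_hv, optical = optical,
                 network = net, log = log)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(estimates, file.path(output_dir, "estimates.csv"),
                     progress = FALSE)
    write_wcm_coefficients(fit_hh, file.path(output_dir, "wcm_hh.yml"))
    write_wcm_coefficients(fit_hv, file.path(output_dir, "wcm_hv.yml"))
    for (f in names(optical)) {
      write_optical_model(optical[[f]],
                          file.path(output_dir, paste0("optical_", f, ".yml")))
    }
    write_transfer_network(net, file.path(output_dir, "transfer_network.json"))
    yaml::write_yaml(log, file.path(output_dir, "run_log.yml"), precision = 17)
  }
  invisible(result)
}

#' Compare radar, optical and adjusted biomass estimates
#'
#' Scatter of the validation-point estimates before and after the transfer
#' function against the optical estimates they are transferred towards.
#'
#' @param result The bundle returned by [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_estimates <- function(result) {
  est <- result$estimates
  df <- dplyr::bind_rows(
    tibble(optical = est$optical_biomass, estimate = est$sar_biomass,
           which = "SAR (raw)"),
    tibble(optical = est$optical_biomass, estimate = est$adjusted_biomass,
           which = "SAR (adjusted)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$optical, y = .data$estimate,
                                   colour = .data$which)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "optical biomass estimate (kg m⁻²)",
                  y = "radar-derived estimate (kg m⁻²)", colour = NULL,
                  title = "Transfer of SAR biomass onto the optical scale")
}
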