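#' Water Cloud Model coefficients
#'
#' Bundles the six coefficients of the Water Cloud Model for one polarization.
#' `A` scales canopy volume scattering, `B` the canopy attenuation, `C` the
#' soil-moisture sensitivity of the bare-soil term, `D` the soil backscatter
#' offset, and `E1`/`E2` are the biomass exponents of the canopy and
#' attenuation terms respectively.
#'
#' @param A,B,C,D,E1,E2 Finite numeric coefficients.
#' @param polarization `"hh"` or `"hv"`.
#' @param biomass_kind Which biomass enters the model: `"wet"` or `"dry"`.
#' @return An object of class `wcm_coefficients`.
#' @export
wcm_coefficients <- function(A, B, C, D, E1, E2,
                             polarization = c("hh", "hv"),
                             biomass_kind = c("wet", "dry")) {
  polarization <- match.arg(polarization)
  biomass_kind <- match.arg(biomass_kind)
  vals <- c(A = A, B = B, C = C, D = D, E1 = E1, E2 = E2)
  if (!all(is.finite(vals))) abort("all six coefficients must be finite")
  structure(list(A = A, B = B, C = C, D = D, E1 = E1, E2 = E2,
                 polarization = polarization, biomass_kind = biomass_kind),
            class = "wcm_coefficients")
}

#' @export
print.wcm_coefficients <- function(x, ...) {
  cat("Water Cloud Model coefficients (", toupper(x$polarization),
      ", ", x$biomass_kind, " biomass)\n", sep = "")
  print(round(unlist(x[c("A", "B", "C", "D", "E1", "E2")]), 6))
  invisible(x)
}

#' Water Cloud Model forward computation
#'
#' Total backscatter of a vegetated surface modelled as a uniform water cloud
#' over soil:
#' \deqn{\sigma^0 = A L^{E_1} \cos\theta \left(1 - e^{-2 B L^{E_2}/\cos\theta}\right)
#'       + (C M_v + D)\, e^{-2 B L^{E_2}/\cos\theta}}
#' where `L` is biomass (kg m^-2), `Mv` volumetric soil moisture (m^3 m^-3)
#' and `theta` the incidence angle. The first term is canopy volume
#' scattering, the second the soil contribution attenuated by the two-way
#' canopy transmissivity.
#'
#' @param coefs A [wcm_coefficients()] object.
#' @param biomass Biomass `L`, kg m^-2, non-negative. Vectorized.
#' @param soil_moisture Volumetric soil moisture `Mv`, m^3 m^-3. Vectorized.
#' @param incidence_angle Incidence angle in degrees, in (0, 90). Vectorized.
#' @return Backscatter in linear power units.
#' @examples
#' cf <- wcm_coefficients(0.25, 0.35, 0.9, 0.05, 0.25, 0.5, "hh")
#' wcm_forward(cf, biomass = 2, soil_moisture = 0.2, incidence_angle = 27)
#' @export
wcm_forward <- function(coefs, biomass, soil_moisture, incidence_angle) {
  stopifnot(inherits(coefs, "wcm_coefficients"))
  if (any(!is.finite(biomass)) || any(biomass < 0)) {
    abort("`biomass` must be finite and non-negative")
  }
  if (any(incidence_angle <= 0) || any(incidence_angle >= 90)) {
    abort("`incidence_angle` must lie strictly between 0 and 90 degrees")
  }
  if (any(biomass == 0) && (coefs$E1 <= 0 || coefs$E2 <= 0)) {
    abort("zero biomass requires positive exponents E1 and E2")
  }
  .wcm_eval(unlist(coefs[c("A", "B", "C", "D", "E1", "E2")]),
            biomass, soil_moisture, incidence_angle)
}

# bare evaluation used in optimization loops (par = c(A,B,C,D,E1,E2));
# returns NaN rather than erroring outside the domain so the damped solver
# can reject the step
.wcm_eval <- function(par, L, Mv, theta_deg) {
  par <- unname(par)
  ct <- cos(theta_deg * pi / 180)
  Le1 <- ifelse(L > 0, L^par[5], ifelse(L == 0 & par[5] > 0, 0, NaN))
  Le2 <- ifelse(L > 0, L^par[6], ifelse(L == 0 & par[6] > 0, 0, NaN))
  tau2 <- exp(-2 * par[2] * Le2 / ct)
  par[1] * Le1 * ct * (1 - tau2) + (par[3] * Mv + par[4]) * tau2
}

#' Calibrate the Water Cloud Model for one polarization
#'
#' Estimates the six model coefficients by nonlinear least squares on a set of
#' calibration points: minimises the sum of squared differences between
#' modelled and observed backscatter with a damped (Levenberg-Marquardt)
#' iteration. Initial coefficients are drawn uniformly on (0, 1); because a
#' single random start can land in a local minimum, `n_restarts` independent
#' starts are run and the fit with the smallest SSE is returned. Iteration
#' stops when the SSE improvement falls below `tol` or after `max_iter`
#' iterations.
#'
#' @param data Data frame of calibration records with the canonical
#'   observation columns (at least the chosen backscatter column, both biomass
#'   columns, `soil_moisture` and `incidence_angle`). At least six records are
#'   required — one per coefficient.
#' @param polarization Which backscatter channel to calibrate, `"hh"` or `"hv"`.
#' @param biomass_kind Which biomass column enters the model, `"wet"` (default)
#'   or `"dry"`.
#' @param seed Integer seed for the random initial coefficients.
#' @param tol Stop when the SSE decrease of an iteration falls below this.
#' @param max_iter Maximum iterations per restart.
#' @param n_restarts Number of random starts; the best (lowest SSE) fit wins.
#' @return An object of class `wcm_fit`: the fitted [wcm_coefficients()],
#'   residuals (model minus observation, power units), `sse`, iteration count,
#'   convergence flag, the seed, and a per-restart diagnostic tibble.
#' @seealso [invert_wcm()] to retrieve biomass and soil moisture from the
#'   calibrated pair of models; [tidy()] and [glance()] methods are provided.
#' @examples
#' cal <- split_observations(corn_observations())$calibration
#' fit <- calibrate_wcm(cal, "hh", seed = 7, n_restarts = 5)
#' glance(fit)
#' @export
calibrate_wcm <- function(data, polarization = c("hh", "hv"),
                          biomass_kind = c("wet", "dry"),
                          seed = 1L, tol = 1e-8, max_iter = 100L,
                          n_restarts = 20L) {
  polarization <- match.arg(polarization)
  biomass_kind <- match.arg(biomass_kind)
  if (!is.data.frame(data)) abort("`data` must be a data frame of observation records")
  if (nrow(data) < 6) {
    abort("calibration requires at least six points (one per coefficient)")
  }
  y <- data[[paste0(polarization, "_backscatter")]]
  L <- data[[paste0(biomass_kind, "_biomass")]]
  Mv <- data[["soil_moisture"]]
  theta <- data[["incidence_angle"]]
  if (is.null(y) || is.null(L) || is.null(Mv) || is.null(theta)) {
    abort("`data` is missing required observation columns")
  }
  if (any(y <= 0)) abort("backscatter must be strictly positive linear power")
  if (length(unique(L)) == 1) {
    warn("all biomass values are identical; the fit is rank-deficient")
  }

  fn <- function(par) .wcm_eval(par, L, Mv, theta) - y

  starts <- withr::with_seed(seed, matrix(runif(6 * n_restarts), n_restarts, 6))
  best <- NULL
  diag_rows <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    res <- lm_least_squares(fn, starts[i, ], tol = tol, max_iter = max_iter,
                            stop_rule = "sse_decrease", damping = "marquardt")
    diag_rows[[i]] <- tibble(restart = i, initial_sse = res$sse0,
                             sse = res$sse, iterations = res$iterations,
                             converged = res$converged, reason = res$reason,
                             A = res$par[1], B = res$par[2], C = res$par[3],
                             D = res$par[4], E1 = res$par[5], E2 = res$par[6])
    if (is.null(best) || res$sse < best$sse) best <- res
  }
  restarts <- dplyr::bind_rows(diag_rows)

  coefs <- wcm_coefficients(best$par[1], best$par[2], best$par[3],
                            best$par[4], best$par[5], best$par[6],
                            polarization = polarization,
                            biomass_kind = biomass_kind)
  structure(list(coefficients = coefs,
                 residuals = best$residuals,
                 fitted = best$residuals + y,
                 observed = y,
                 sse = best$sse,
                 iterations = best$iterations,
                 converged = best$converged,
                 seed = as.integer(seed),
                 n = nrow(data),
                 n_restarts = as.integer(n_restarts),
                 restarts = restarts),
            class = "wcm_fit")
}

#' @export
print.wcm_fit <- function(x, ...) {
  cat("Water Cloud Model fit (", toupper(x$coefficients$polarization), ", ",
      x$coefficients$biomass_kind, " biomass)\n", sep = "")
  cat("  points: ", x$n, "   SSE: ", format(x$sse, digits = 6),
      "   iterations: ", x$iterations,
      "   converged: ", x$converged, "\n", sep = "")
  print(round(unlist(x$coefficients[c("A", "B", "C", "D", "E1", "E2")]), 6))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wcm_fit <- function(x, ...) {
  tibble(term = c("A", "B", "C", "D", "E1", "E2"),
         estimate = unlist(x$coefficients[c("A", "B", "C", "D", "E1", "E2")],
                           use.names = FALSE))
}

#' @exportS3Method generics::glance
glance.wcm_fit <- function(x, ...) {
  tibble(polarization = x$coefficients$polarization,
         biomass_kind = x$coefficients$biomass_kind,
         sse = x$sse, iterations = x$iterations, converged = x$converged,
         n = x$n, n_restarts = x$n_restarts, seed = x$seed)
}

#' @export
predict.wcm_fit <- function(object, newdata, ...) {
  kind <- object$coefficients$biomass_kind
  wcm_forward(object$coefficients, newdata[[paste0(kind, "_biomass")]],
              newdata[["soil_moisture"]], newdata[["incidence_angle"]])
}

#' Retrieve biomass and soil moisture from dual-polarized backscatter
#'
#' With the Water Cloud Model calibrated for both HH and HV, each observation
#' point gives a system of two equations in the two unknowns (biomass `L`,
#' soil moisture `Mv`). The system is solved per point by the
#' Levenberg-Marquardt algorithm starting from (`init_biomass`,
#' `init_soil_moisture`); iteration stops when the step between iterates drops
#' below `tol` or after `max_iter` iterations. Solutions are reported raw —
#' not clamped to physical ranges — together with convergence diagnostics; a
#' point where no root is found is flagged, not dropped.
#'
#' @param data Data frame with columns `hh_backscatter`, `hv_backscatter`
#'   (linear power) and `incidence_angle` (degrees); a `point_no` column is
#'   carried through if present.
#' @param coefs_hh,coefs_hv Calibrated [wcm_coefficients()] for the two
#'   polarizations (same `biomass_kind`). A `wcm_fit` is also accepted.
#' @param init_biomass,init_soil_moisture Starting values, default 1 kg m^-2
#'   and 0.2 m^3 m^-3.
#' @param tol Step-size stopping tolerance.
#' @param max_iter Maximum iterations per point.
#' @return A tibble with one row per input point: `biomass`, `soil_moisture`,
#'   `converged`, `iterations`, `residual_norm`. `converged` requires both the
#'   step criterion and a residual norm at most `tol` (i.e. an actual root,
#'   not a stall).
#' @examples
#' obs <- corn_observations()
#' parts <- split_observations(obs)
#' hh <- calibrate_wcm(parts$calibration, "hh", seed = 7, n_restarts = 5)
#' hv <- calibrate_wcm(parts$calibration, "hv", seed = 7, n_restarts = 5)
#' invert_wcm(head(parts$validation, 3), hh, hv)
#' @export
invert_wcm <- function(data, coefs_hh, coefs_hv,
                       init_biomass = 1.0, init_soil_moisture = 0.2,
                       tol = 1e-6, max_iter = 400L) {
  coefs_hh <- as_wcm_coefficients(coefs_hh)
  coefs_hv <- as_wcm_coefficients(coefs_hv)
  if (coefs_hh$biomass_kind != coefs_hv$biomass_kind) {
    abort("HH and HV coefficients must be calibrated for the same biomass kind")
  }
  s_hh <- data[["hh_backscatter"]]
  s_hv <- data[["hv_backscatter"]]
  theta <- data[["incidence_angle"]]
  if (is.null(s_hh) || is.null(s_hv) || is.null(theta)) {
    abort("`data` must contain hh_backscatter, hv_backscatter and incidence_angle")
  }
  if (any(s_hh <= 0) || any(s_hv <= 0)) {
    abort("backscatter inputs must be strictly positive linear power")
  }
  p_hh <- unlist(coefs_hh[c("A", "B", "C", "D", "E1", "E2")])
  p_hv <- unlist(coefs_hv[c("A", "B", "C", "D", "E1", "E2")])

  one <- function(i) {
    fn <- function(v) {
      c(.wcm_eval(p_hh, v[1], v[2], theta[i]) - s_hh[i],
        .wcm_eval(p_hv, v[1], v[2], theta[i]) - s_hv[i])
    }
    res <- lm_least_squares(fn, c(init_biomass, init_soil_moisture),
                            tol = tol, max_iter = max_iter,
                            stop_rule = "step", damping = "marquardt")
    rnorm_final <- sqrt(sum(res$residuals^2))
    tibble(biomass = res$par[1], soil_moisture = res$par[2],
           converged = res$converged && rnorm_final <= tol,
           iterations = res$iterations, residual_norm = rnorm_final)
  }
  out <- purrr::map_dfr(seq_along(s_hh), one)
  if (!is.null(data[["point_no"]])) {
    out <- dplyr::bind_cols(tibble(point_no = data[["point_no"]]), out)
  }
  out
}

as_wcm_coefficients <- function(x) {
  if (inherits(x, "wcm_fit")) return(x$coefficients)
  if (inherits(x, "wcm_coefficients")) return(x)
  abort("expected a wcm_coefficients or wcm_fit object")
}

#' Serialize Water Cloud Model coefficients to a text file
#'
#' Writes a small key-value (YAML) file with the polarization, biomass kind
#' and the six coefficients (plus fit diagnostics when a `wcm_fit` is given),
#' so calibration and inversion can run as separate steps.
#'
#' @param x A `wcm_coefficients` or `wcm_fit` object.
#' @param path Output file path.
#' @return `path` invisibly; `read_wcm_coefficients()` returns the
#'   [wcm_coefficients()] object.
#' @export
write_wcm_coefficients <- function(x, path) {
  extra <- if (inherits(x, "wcm_fit")) {
    list(sse = x$sse, seed = x$seed, n = x$n, n_restarts = x$n_restarts)
  } else {
    list()
  }
  cf <- as_wcm_coefficients(x)
  yaml::write_yaml(c(cf[c("polarization", "biomass_kind",
                          "A", "B", "C", "D", "E1", "E2")], extra),
                   path, precision = 17)
  invisible(path)
}

#' @rdname write_wcm_coefficients
#' @export
read_wcm_coefficients <- function(path) {
  v <- yaml::read_yaml(path)
  wcm_coefficients(v$A, v$B, v$C, v$D, v$E1, v$E2,
                   polarization = v$polarization,
                   biomass_kind = v$biomass_kind)
}

#' Diagnostic plot of a Water Cloud Model fit
#'
#' Observed versus modelled backscatter for the calibration points, with the
#' 1:1 line.
#'
#' @param object A `wcm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wcm_fit <- function(object, ...) {
  df <- tibble(observed = object$observed, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression("observed " * sigma^0 * " (power)"),
      y = expression("modelled " * sigma^0 * " (power)"),
      title = paste0("Water Cloud Model fit, ",
                     toupper(object$coefficients$polarization)),
      subtitle = paste0("SSE = ", signif(object$sse, 4), ", n = ", object$n)
    )
}
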