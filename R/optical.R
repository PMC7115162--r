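#' Vegetation-index biomass models
#'
#' Four empirical two-coefficient regressions of biomass on a vegetation
#' index, one functional form per index:
#'
#' * `ndvi_exp` — `biomass = a * exp(NDVI) + b`
#' * `rtvi_linear` — `biomass = a * RTVI + b`
#' * `sr_log` — `biomass = a * ln(SR) + b`
#' * `srre_linear` — `biomass = a * SRre + b`
#'
#' Separate coefficient sets are fitted for wet and dry biomass, giving eight
#' independent models in total. `calibrate_optical()` fits one form by the
#' same damped least-squares iteration used for the Water Cloud Model:
#' initial coefficients uniform on (0, 1), stopping when the SSE improvement
#' falls below `tol` or at `max_iter` iterations. All four forms are linear
#' in (a, b) after transforming the index, so the iterative fit must agree
#' with closed-form ordinary least squares; this is asserted in the test
#' suite, not assumed.
#'
#' @param data Data frame holding the index and biomass columns (typically
#'   the calibration split of an observation table).
#' @param form One of `"ndvi_exp"`, `"rtvi_linear"`, `"sr_log"`,
#'   `"srre_linear"`.
#' @param vi_col Name of the vegetation-index column (default `"ndvi"`, the
#'   index the packaged dataset supplies).
#' @param biomass_col Name of the biomass column; also recorded as the fit's
#'   biomass kind when it is one of the canonical columns.
#' @param seed Integer seed for the random initial coefficients.
#' @param tol SSE-improvement stopping tolerance.
#' @param max_iter Maximum iterations.
#' @return An object of class `optical_fit` with coefficients `a` and `b`,
#'   `fit_sse`, iteration count and convergence flag.
#' @examples
#' cal <- split_observations(corn_observations())$calibration
#' fit <- calibrate_optical(cal, "ndvi_exp", seed = 3)
#' predict_optical(fit, 0.8)
#' @export
calibrate_optical <- function(data, form = c("ndvi_exp", "rtvi_linear",
                                             "sr_log", "srre_linear"),
                              vi_col = "ndvi", biomass_col = "wet_biomass",
                              seed = 1L, tol = 1e-8, max_iter = 100L) {
  form <- match.arg(form)
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  vi <- data[[vi_col]]
  biomass <- data[[biomass_col]]
  if (is.null(vi)) abort(paste0("column '", vi_col, "' not found"))
  if (is.null(biomass)) abort(paste0("column '", biomass_col, "' not found"))
  if (length(vi) != length(biomass)) abort("index and biomass lengths differ")
  if (length(vi) < 2) abort("at least two points are required")
  if (form == "sr_log" && any(vi <= 0)) {
    abort("the log form requires strictly positive index values")
  }
  x <- vi_transform(form, vi)
  if (length(unique(x)) == 1) {
    abort("all index values are identical; the fit is rank-deficient")
  }

  fn <- function(par) par[1] * x + par[2] - biomass
  start <- withr::with_seed(seed, runif(2))
  res <- lm_least_squares(fn, start, tol = tol, max_iter = max_iter,
                          stop_rule = "sse_decrease", damping = "marquardt")

  kind <- switch(biomass_col, wet_biomass = "wet", dry_biomass = "dry",
                 biomass_col)
  structure(list(form = form, a = res$par[1], b = res$par[2],
                 biomass_kind = kind, fit_sse = res$sse,
                 iterations = res$iterations, converged = res$converged,
                 initial_sse = res$sse0, seed = as.integer(seed),
                 n = length(vi), vi = vi, observed = biomass,
                 fitted = res$residuals + biomass),
            class = "optical_fit")
}

vi_transform <- function(form, vi) {
  switch(form,
         ndvi_exp = exp(vi),
         rtvi_linear = vi,
         sr_log = log(vi),
         srre_linear = vi,
         abort(paste0("unknown optical model form: ", form)))
}

#' Predict biomass from a vegetation index
#'
#' Applies a fitted (or hand-constructed) vegetation-index model to index
#' values.
#'
#' @param model An `optical_fit` from [calibrate_optical()], or any list with
#'   elements `form`, `a`, `b`.
#' @param vi Vegetation-index values; must be strictly positive for the log
#'   form.
#' @return Predicted biomass, kg m^-2.
#' @export
predict_optical <- function(model, vi) {
  if (is.null(model$form) || is.null(model$a) || is.null(model$b)) {
    abort("`model` must carry `form`, `a` and `b`")
  }
  if (model$form == "sr_log" && any(vi <= 0)) {
    abort("the log form requires strictly positive index values")
  }
  model$a * vi_transform(model$form, vi) + model$b
}

#' @export
predict.optical_fit <- function(object, vi, ...) predict_optical(object, vi)

#' @export
print.optical_fit <- function(x, ...) {
  cat("Vegetation-index biomass model (", x$form, ", ", x$biomass_kind,
      " biomass)\n", sep = "")
  cat("  a = ", format(x$a, digits = 6), "  b = ", format(x$b, digits = 6),
      "  SSE = ", format(x$fit_sse, digits = 6), "  n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.optical_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @exportS3Method generics::glance
glance.optical_fit <- function(x, ...) {
  tibble(form = x$form, biomass_kind = x$biomass_kind, sse = x$fit_sse,
         iterations = x$iterations, converged = x$converged, n = x$n,
         seed = x$seed)
}

#' Compute a vegetation index from surface reflectance
#'
#' Literature-standard band-combination defaults (the source imagery supplied
#' the indices precomputed, so the exact variants are configurable via the
#' band mapping):
#' * NDVI  = (NIR - Red) / (NIR + Red)
#' * SR    = NIR / Red
#' * SRre  = NIR / RedEdge
#' * RTVI  = 100 (NIR - RedEdge) - 10 (NIR - Green)
#'
#' @param data Data frame of per-band surface reflectance.
#' @param index One of `"ndvi"`, `"rtvi"`, `"sr"`, `"srre"`.
#' @param green,red,red_edge,nir Column names for the bands the chosen index
#'   needs.
#' @return A numeric vector of index values, one per row of `data`.
#' @examples
#' refl <- tibble::tibble(green = 0.1, red = 0.1, red_edge = 0.3, nir = 0.4)
#' compute_index(refl, "rtvi")
#' @export
compute_index <- function(data, index = c("ndvi", "rtvi", "sr", "srre"),
                          green = "green", red = "red",
                          red_edge = "red_edge", nir = "nir") {
  index <- match.arg(index)
  need <- switch(index,
                 ndvi = c(red = red, nir = nir),
                 sr = c(red = red, nir = nir),
                 srre = c(red_edge = red_edge, nir = nir),
                 rtvi = c(green = green, red_edge = red_edge, nir = nir))
  for (b in names(need)) {
    if (is.null(data[[need[[b]]]])) {
      abort(paste0("missing reflectance band '", b, "' (column '",
                   need[[b]], "')"))
    }
  }
  val <- function(b) data[[need[[b]]]]
  out <- switch(index,
                ndvi = {
                  den <- val("nir") + val("red")
                  if (any(den == 0)) abort("NDVI denominator NIR + Red is zero")
                  (val("nir") - val("red")) / den
                },
                sr = {
                  if (any(val("red") == 0)) abort("SR denominator Red is zero")
                  val("nir") / val("red")
                },
                srre = {
                  if (any(val("red_edge") == 0)) abort("SRre denominator RedEdge is zero")
                  val("nir") / val("red_edge")
                },
                rtvi = 100 * (val("nir") - val("red_edge")) -
                  10 * (val("nir") - val("green")))
  out
}

#' Serialize a vegetation-index model to a text file
#'
#' @param model An `optical_fit` (or list with `form`, `a`, `b`,
#'   `biomass_kind`).
#' @param path Output file path.
#' @return `path` invisibly; `read_optical_model()` returns the model list.
#' @export
write_optical_model <- function(model, path) {
  yaml::write_yaml(list(form = model$form, biomass_kind = model$biomass_kind,
                        a = model$a, b = model$b,
                        fit_sse = model$fit_sse %||% NA_real_),
                   path, precision = 17)
  invisible(path)
}

#' @rdname write_optical_model
#' @export
read_optical_model <- function(path) {
  v <- yaml::read_yaml(path)
  structure(list(form = v$form, a = v$a, b = v$b,
                 biomass_kind = v$biomass_kind, fit_sse = v$fit_sse),
            class = "optical_fit")
}

#' Plot a fitted vegetation-index biomass model
#'
#' Calibration points and the fitted curve over the observed index range.
#'
#' @param object An `optical_fit` carrying its calibration data.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.optical_fit <- function(object, ...) {
  if (is.null(object$vi)) abort("this model was not fitted in-session; nothing to plot")
  pts <- tibble(vi = object$vi, biomass = object$observed)
  grid <- tibble(vi = seq(min(pts$vi), max(pts$vi), length.out = 200))
  grid$biomass <- predict_optical(object, grid$vi)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$vi, y = .data$biomass)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "vegetation index", y = "biomass (kg m⁻²)",
                  title = paste0("Optical biomass model (", object$form, ")"),
                  subtitle = paste0("a = ", signif(object$a, 4),
                                    ", b = ", signif(object$b, 4),
                                    ", SSE = ", signif(object$fit_sse, 4)))
}
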