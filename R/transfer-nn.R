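#' Train the SAR-to-optical biomass transfer network
#'
#' Radar- and optics-derived biomass estimates sit on different scales; a
#' small transfer function maps one onto the other so monitoring can mix
#' satellite sources. The transfer function is a two-layer feed-forward
#' network — one hidden layer of `hidden` tanh units and a linear output —
#' with a single input (the radar biomass estimate) and a single output (the
#' optical-scale estimate). Inputs and outputs are min-max normalized to
#' \[-1, 1\]; weights are trained by Levenberg-Marquardt minimisation of the
#' squared error on a random `train_fraction` of the pairs (`ceiling(0.7 n)`,
#' i.e. 17 of 23 pairs under the defaults), with the remainder held out for
#' reporting only. Training stops when the error gradient or step falls below
#' `1e-7` or at `max_iter` iterations.
#'
#' @param data Data frame holding the paired estimates, or `NULL` when `sar`
#'   and `optical` are given as numeric vectors.
#' @param sar,optical Column names in `data` (or bare numeric vectors when
#'   `data` is `NULL`): the radar-side input and optical-side target, kg m^-2.
#' @param hidden Number of hidden tanh units (default 10).
#' @param train_fraction Fraction of pairs used for weight fitting; the split
#'   takes `ceiling(train_fraction * n)` training points.
#' @param seed Integer seed controlling the split and the initial weights
#'   (uniform on (-1, 1)).
#' @param max_iter Maximum training iterations.
#' @return An object of class `transfer_network` holding the weights, the
#'   normalization ranges, the split indices, and training/holdout mean
#'   squared errors on the normalized scale.
#' @seealso [apply_transfer()]
#' @examples
#' x <- seq(0.1, 5, length.out = 23)
#' net <- train_transfer(NULL, sar = x, optical = x, seed = 2)
#' glance(net)
#' @export
train_transfer <- function(data, sar = "sar_biomass", optical = "optical_biomass",
                           hidden = 10L, train_fraction = 0.7, seed = 1L,
                           max_iter = 1000L) {
  if (is.null(data)) {
    x <- as.numeric(sar)
    y <- as.numeric(optical)
  } else {
    x <- data[[sar]]
    y <- data[[optical]]
    if (is.null(x)) abort(paste0("column '", sar, "' not found"))
    if (is.null(y)) abort(paste0("column '", optical, "' not found"))
  }
  if (length(x) != length(y)) abort("input and target lengths differ")
  if (length(x) < 2) abort("at least two pairs are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("inputs must be finite")
  n <- length(x)
  hidden <- as.integer(hidden)

  in_range <- range(x)
  out_range <- range(y)
  if (diff(in_range) == 0) abort("all input values are identical; cannot normalize")
  if (diff(out_range) == 0) abort("all target values are identical; cannot normalize")
  xn <- normalize_minmax(x, in_range)
  yn <- normalize_minmax(y, out_range)

  n_train <- min(n, as.integer(ceiling(train_fraction * n)))
  draws <- withr::with_seed(seed, {
    idx <- sample.int(n)
    w0 <- runif(3 * hidden + 1, -1, 1)
    list(idx = idx, w0 = w0)
  })
  train_idx <- sort(draws$idx[seq_len(n_train)])
  holdout_idx <- sort(draws$idx[setdiff(seq_len(n), seq_len(n_train))])

  xt <- xn[train_idx]
  yt <- yn[train_idx]
  fn <- function(w) nn_forward(w, xt, hidden) - yt
  res <- lm_least_squares(fn, draws$w0, tol = 1e-7, max_iter = max_iter,
                          stop_rule = "grad_or_step", damping = "identity")

  pred_h <- if (length(holdout_idx)) nn_forward(res$par, xn[holdout_idx], hidden)
            else numeric(0)
  structure(list(weights = res$par, hidden = hidden,
                 input_scaling = in_range, output_scaling = out_range,
                 seed = as.integer(seed),
                 train_idx = train_idx, holdout_idx = holdout_idx,
                 n_train = length(train_idx), n_holdout = length(holdout_idx),
                 train_mse = res$sse / length(train_idx),
                 initial_train_mse = res$sse0 / length(train_idx),
                 holdout_mse = if (length(holdout_idx))
                   mean((pred_h - yn[holdout_idx])^2) else NA_real_,
                 iterations = res$iterations, converged = res$converged,
                 reason = res$reason),
            class = "transfer_network")
}

# weight layout: w[1:h] hidden weights, w[h+1:2h] hidden biases,
# w[2h+1:3h] output weights, w[3h+1] output bias
nn_forward <- function(w, x, hidden) {
  w1 <- w[seq_len(hidden)]
  b1 <- w[hidden + seq_len(hidden)]
  w2 <- w[2 * hidden + seq_len(hidden)]
  b2 <- w[3 * hidden + 1]
  a <- tanh(outer(x, w1) + matrix(b1, length(x), hidden, byrow = TRUE))
  as.numeric(a %*% w2 + b2)
}

normalize_minmax <- function(x, range) 2 * (x - range[1]) / (range[2] - range[1]) - 1
denormalize_minmax <- function(z, range) (z + 1) / 2 * (range[2] - range[1]) + range[1]

#' Apply the transfer network to radar biomass estimates
#'
#' Normalizes the inputs with the scaling stored in the network, runs the
#' forward pass, denormalizes, and takes the absolute value — the final
#' estimates are therefore always non-negative.
#'
#' @param net A trained [train_transfer()] network.
#' @param sar_biomass Radar biomass estimates, kg m^-2.
#' @return Adjusted biomass estimates on the optical scale, kg m^-2, all
#'   non-negative, same length as the input.
#' @export
apply_transfer <- function(net, sar_biomass) {
  if (!inherits(net, "transfer_network") || is.null(net$weights)) {
    abort("`net` must be a trained transfer_network")
  }
  if (!all(is.finite(sar_biomass))) abort("inputs must be finite")
  z <- normalize_minmax(sar_biomass, net$input_scaling)
  abs(denormalize_minmax(nn_forward(net$weights, z, net$hidden),
                         net$output_scaling))
}

#' @export
predict.transfer_network <- function(object, sar_biomass, ...) {
  apply_transfer(object, sar_biomass)
}

#' @export
print.transfer_network <- function(x, ...) {
  cat("SAR→optical biomass transfer network (1–", x$hidden,
      "–1, tanh hidden layer)\n", sep = "")
  cat("  train/holdout: ", x$n_train, "/", x$n_holdout,
      "   train MSE: ", format(x$train_mse, digits = 4),
      "   holdout MSE: ", format(x$holdout_mse, digits = 4),
      " (normalized)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.transfer_network <- function(x, ...) {
  tibble(hidden = x$hidden, n_train = x$n_train, n_holdout = x$n_holdout,
         train_mse = x$train_mse, holdout_mse = x$holdout_mse,
         iterations = x$iterations, converged = x$converged, seed = x$seed)
}

#' Serialize a transfer network to JSON
#'
#' Stores topology, weights, normalization ranges, seed and split indices so
#' a network trained once can be applied in a later session.
#'
#' @param net A `transfer_network`.
#' @param path Output file path.
#' @return `path` invisibly; `read_transfer_network()` returns the network.
#' @export
write_transfer_network <- function(net, path) {
  jsonlite::write_json(
    list(hidden = net$hidden, weights = net$weights,
         input_scaling = net$input_scaling, output_scaling = net$output_scaling,
         seed = net$seed, train_idx = net$train_idx,
         holdout_idx = net$holdout_idx, train_mse = net$train_mse,
         holdout_mse = net$holdout_mse),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transfer_network
#' @export
read_transfer_network <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.numeric(v$weights), hidden = as.integer(v$hidden),
                 input_scaling = as.numeric(v$input_scaling),
                 output_scaling = as.numeric(v$output_scaling),
                 seed = as.integer(v$seed),
                 train_idx = as.integer(v$train_idx),
                 holdout_idx = as.integer(v$holdout_idx),
                 n_train = length(v$train_idx), n_holdout = length(v$holdout_idx),
                 train_mse = v$train_mse, holdout_mse = v$holdout_mse),
            class = "transfer_network")
}

#' Plot the transfer network response
#'
#' The learned input-output curve over the training range (after the final
#' absolute value), with the training and holdout pairs overlaid.
#'
#' @param object A trained `transfer_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.transfer_network <- function(object, ...) {
  grid <- tibble(sar = seq(object$input_scaling[1], object$input_scaling[2],
                           length.out = 200))
  grid$adjusted <- apply_transfer(object, grid$sar)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$sar, y = .data$adjusted)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "SAR biomass estimate (kg m⁻²)",
                  y = "adjusted biomass (kg m⁻²)",
                  title = "SAR→optical transfer function")
}
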