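# Damped least-squares (Levenberg-Marquardt) engine shared by WCM calibration,
# WCM inversion, optical-model fitting and neural-network training. Each caller
# pins a different stopping rule, so the engine takes the rule as an argument
# rather than hard-coding one.

# Numerical Jacobian of a residual function, central differences with one-sided
# fallback where a perturbed point leaves the residuals' domain (e.g. negative
# biomass raised to a fractional exponent).
num_jacobian <- function(fn, par, r0) {
  m <- length(r0)
  p <- length(par)
  J <- matrix(NA_real_, m, p)
  h <- 1e-7 * pmax(abs(par), 1)
  for (j in seq_len(p)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    ru <- fn(up)
    rd <- fn(dn)
    col <- (ru - rd) / (2 * h[j])
    if (!all(is.finite(col))) {
      col <- if (all(is.finite(ru))) (ru - r0) / h[j] else (r0 - rd) / h[j]
    }
    J[, j] <- col
  }
  J
}

# Minimise sum(fn(par)^2) from par0.
#
# stop_rule:
#   "sse_decrease"  stop when the absolute SSE improvement of an accepted step
#                   falls below tol (nonlinear-regression calibration rule);
#   "step"          stop when the Euclidean norm of the accepted step falls
#                   below tol (root-finding rule);
#   "grad_or_step"  stop when either the SSE gradient max-norm or the step norm
#                   falls below tol (network training rule).
# damping: "marquardt" scales the damping by diag(J'J); "identity" adds
#   lambda * I, which keeps the system solvable when J'J is rank-deficient
#   (more parameters than residuals, as in network training).
#
# Returns par, residuals, sse, iterations, converged, reason, sse0.
lm_least_squares <- function(fn, par0, tol = 1e-8, max_iter = 100L,
                             stop_rule = c("sse_decrease", "step", "grad_or_step"),
                             damping = c("marquardt", "identity"),
                             lambda0 = 1e-3, lambda_max = 1e12) {
  stop_rule <- match.arg(stop_rule)
  damping <- match.arg(damping)
  par <- as.numeric(par0)
  r <- fn(par)
  if (!all(is.finite(r))) {
    abort("residuals are not finite at the initial parameters")
  }
  sse <- sum(r * r)
  sse0 <- sse
  lambda <- lambda0
  iter <- 0L
  converged <- FALSE
  reason <- "max_iter"

  while (iter < max_iter) {
    iter <- iter + 1L
    J <- num_jacobian(fn, par, r)
    if (!all(is.finite(J))) {
      reason <- "singular_jacobian"
      break
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r) # gradient of SSE / 2

    if (stop_rule == "grad_or_step" && max(abs(2 * g)) < tol) {
      converged <- TRUE
      reason <- "gradient"
      break
    }

    d <- if (damping == "marquardt") diag(pmax(diag(JtJ), 1e-12)) else diag(nrow(JtJ))
    accepted <- FALSE
    step <- NULL
    while (lambda <= lambda_max) {
      step <- tryCatch(solve(JtJ + lambda * d, -g), error = function(e) NULL)
      if (!is.null(step)) {
        trial <- par + as.numeric(step)
        r_try <- fn(trial)
        if (all(is.finite(r_try)) && sum(r_try * r_try) < sse) {
          sse_new <- sum(r_try * r_try)
          par <- trial
          r <- r_try
          accepted <- TRUE
          lambda <- max(lambda / 10, 1e-12)
          break
        }
      }
      lambda <- lambda * 10
    }

    if (!accepted) {
      # No improving damped step exists at this iterate: the objective cannot
      # be decreased further at working precision.
      converged <- stop_rule == "sse_decrease"
      reason <- "stalled"
      break
    }

    improvement <- sse - sse_new
    step_norm <- sqrt(sum(step^2))
    sse <- sse_new

    if (stop_rule == "sse_decrease" && improvement < tol) {
      converged <- TRUE
      reason <- "sse_decrease"
      break
    }
    if (stop_rule %in% c("step", "grad_or_step") && step_norm < tol) {
      converged <- TRUE
      reason <- "step"
      break
    }
  }

  list(par = par, residuals = r, sse = sse, iterations = iter,
       converged = converged, reason = reason, sse0 = sse0)
}
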