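#' Simulation configuration
#'
#' Integration settings shared by all scenario kinds. The default integrator
#' is classical fixed-step RK4 (deterministic and 4th order); `method =
#' "adaptive-stepper"` switches to lsoda with tight tolerances, reporting on
#' the same output grid. The control input is evaluated inside every
#' derivative stage, i.e. the treatment law is applied in continuous time,
#' not zero-order-held.
#'
#' @param duration end time of the run (> 0; the grid starts at 0).
#' @param step integration/output step (> 0 and at most `duration / 100`).
#' @param method `"rk4-fixed"` (default) or `"adaptive-stepper"`.
#' @param initial_state numeric `(x1, x2)` at t = 0.
#' @param initial_estimate optional numeric triple, the initial parameter
#'   estimate for adaptive runs.
#' @param thin positive integer; keep every `thin`-th output row (the final
#'   time is always kept). Integration still proceeds at `step`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration, step = 1e-3,
                       method = c("rk4-fixed", "adaptive-stepper"),
                       initial_state = c(0.5, 0),
                       initial_estimate = NULL,
                       thin = 1L) {
  duration <- check_scalar(duration, "duration", positive = TRUE)
  step <- check_scalar(step, "step", positive = TRUE)
  if (step > duration / 100) {
    stop_invalid(sprintf(
      "`step` (%g) must be at most duration/100 (%g)", step, duration / 100
    ))
  }
  method <- match.arg(method)
  initial_state <- check_state(initial_state, "initial_state")
  if (!is.null(initial_estimate)) {
    initial_estimate <- check_theta(initial_estimate, "initial_estimate")
  }
  if (!is.numeric(thin) || length(thin) != 1L || !is.finite(thin) ||
      thin < 1 || thin != round(thin)) {
    stop_invalid("`thin` must be a positive integer")
  }
  structure(
    list(
      duration = duration, step = step, method = method,
      initial_state = initial_state, initial_estimate = initial_estimate,
      thin = as.integer(thin)
    ),
    class = "sim_config"
  )
}

check_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_invalid("`config` must be a sim_config object")
  }
  config
}

# States larger than this are treated as numerical blow-up.
OVERFLOW_GUARD <- 1e6

# Integrate dy/dt = deriv(t, y) over the config grid, with a blow-up guard
# inside the derivative and a post-hoc scan (lsoda can step past a guarded
# point before reporting). Returns the [time, y] matrix.
integrate_system <- function(deriv, y0, config) {
  times <- seq(0, config$duration, by = config$step)
  if (times[length(times)] < config$duration) {
    times <- c(times, config$duration)
  }
  guarded <- function(t, y, parms) {
    if (!all(is.finite(y)) || max(abs(y)) > OVERFLOW_GUARD) {
      stop_integration(t, sprintf(
        "state magnitude exceeded %g (blow-up)", OVERFLOW_GUARD
      ))
    }
    list(deriv(t, y))
  }
  out <- withCallingHandlers(
    if (config$method == "rk4-fixed") {
      deSolve::rk4(y0, times, guarded, parms = NULL)
    } else {
      deSolve::ode(y0, times, guarded, parms = NULL, method = "lsoda",
                   rtol = 1e-10, atol = 1e-12)
    },
    warning = function(w) invokeRestart("muffleWarning")
  )
  out <- unclass(out)
  bad <- !is.finite(out[, -1, drop = FALSE]) |
    abs(out[, -1, drop = FALSE]) > OVERFLOW_GUARD
  if (any(bad)) {
    stop_integration(out[which(rowSums(bad) > 0)[1], 1],
                     "non-finite or overflowing state in solver output")
  }
  out
}

thin_rows <- function(n, thin) {
  if (thin <= 1L) return(seq_len(n))
  unique(c(seq(1L, n, by = thin), n))
}

new_trajectory <- function(df, kind, model, gains = NULL, gamma = NULL,
                           config, law = NULL) {
  structure(
    df,
    class = c("mood_trajectory", "data.frame"),
    kind = kind, model = model, gains = gains, gamma = gamma,
    step = config$step, method = config$method, law = law
  )
}

#' Simulate the untreated mood swing
#'
#' Integrates the unforced oscillator (`u` identically zero). From any
#' nonzero initial mood the trajectory approaches the stable limit cycle: a
#' fixed-amplitude, fixed-period oscillation between hypomanic and
#' depressive phases.
#'
#' @param model a [mood_model()].
#' @param config a [sim_config()].
#' @return A `mood_trajectory` data frame with columns `t, x1, x2, u`.
#' @examples
#' m <- mood_model(1, 2, 9)
#' tr <- simulate_untreated(m, sim_config(duration = 5, step = 1e-3))
#' tail(tr, 2)
#' @export
simulate_untreated <- function(model, config) {
  if (!inherits(model, "mood_model")) stop_invalid("`model` must be a mood_model")
  config <- check_config(config)
  a <- model$a; b <- model$b; cc <- model$c
  deriv <- function(t, y) {
    c(y[2], -cc * y[1] + b * a * y[2] - b * y[1]^2 * y[2])
  }
  out <- integrate_system(deriv, config$initial_state, config)
  idx <- thin_rows(nrow(out), config$thin)
  df <- data.frame(t = out[idx, 1], x1 = out[idx, 2], x2 = out[idx, 3],
                   u = 0)
  new_trajectory(df, "untreated", model, config = config)
}

#' Simulate treatment with the exact-model-knowledge controller
#'
#' Closes the loop with [emk_control()], which uses the true patient
#' parameters. The recorded trajectory carries the control input and the
#' Lyapunov value \eqn{V = \tfrac12 x_1^2 + \tfrac12 h^2} at every output
#' time. Under the default corrected law the loop is exactly linear and
#' mood decays exponentially with no sign change: the swing is quenched
#' during treatment, not just at its end.
#'
#' @param model a [mood_model()].
#' @param gains a [control_gains()].
#' @param config a [sim_config()].
#' @param law `"corrected"` (default) or `"as-printed"`; see [emk_control()].
#' @return A `mood_trajectory` with columns `t, x1, x2, u, V`.
#' @export
simulate_emk <- function(model, gains, config,
                         law = c("corrected", "as-printed")) {
  if (!inherits(model, "mood_model")) stop_invalid("`model` must be a mood_model")
  gains <- check_gains(gains)
  config <- check_config(config)
  sgn <- law_sign(law)
  theta <- pack_parameters(model)
  k1 <- gains$k1; k2 <- gains$k2
  deriv <- function(t, y) {
    x1 <- y[1]; x2 <- y[2]
    wtheta <- -theta[1] * x1 + theta[2] * x2 - theta[3] * x1^2 * x2
    u <- u_backstepping(x1, x2, wtheta, k1, k2, sgn)
    c(x2, wtheta + u)
  }
  out <- integrate_system(deriv, config$initial_state, config)
  idx <- thin_rows(nrow(out), config$thin)
  x1 <- out[idx, 2]; x2 <- out[idx, 3]
  wtheta <- -theta[1] * x1 + theta[2] * x2 - theta[3] * x1^2 * x2
  h <- x2 + k1 * x1
  df <- data.frame(
    t = out[idx, 1], x1 = x1, x2 = x2,
    u = u_backstepping(x1, x2, wtheta, k1, k2, sgn),
    V = 0.5 * x1^2 + 0.5 * h^2
  )
  new_trajectory(df, "emk", model, gains = gains, config = config,
                 law = match.arg(law))
}

#' Simulate treatment with the adaptive controller
#'
#' Integrates the augmented five-state system `(x1, x2, theta_hat)`: the
#' plant evolves under the TRUE patient parameters, the controller
#' ([adaptive_control()]) sees only the estimate, and the estimate follows
#' the gradient [update_law()]. The trajectory records the control input,
#' the estimate triple, and the adaptive Lyapunov value
#' \eqn{V = \tfrac12 x_1^2 + \tfrac12 h^2 +
#'      \tfrac12 \tilde\theta^\top \Gamma^{-1} \tilde\theta}
#' (computable here because the simulator knows the true parameters).
#'
#' @param model a [mood_model()] (the true plant; never seen by the
#'   controller).
#' @param gains a [control_gains()].
#' @param gamma an [adaptation_gain()] (or scalar/matrix coercible to one).
#' @param config a [sim_config()]; must carry `initial_estimate`.
#' @param law `"corrected"` (default) or `"as-printed"`.
#' @return A `mood_trajectory` with columns
#'   `t, x1, x2, u, theta1_hat, theta2_hat, theta3_hat, V`.
#' @export
simulate_adaptive <- function(model, gains, gamma, config,
                              law = c("corrected", "as-printed")) {
  if (!inherits(model, "mood_model")) stop_invalid("`model` must be a mood_model")
  gains <- check_gains(gains)
  gamma <- check_gamma(gamma)
  config <- check_config(config)
  if (is.null(config$initial_estimate)) {
    stop_invalid("adaptive simulation requires `initial_estimate` in the config")
  }
  sgn <- law_sign(law)
  theta <- pack_parameters(model)
  k1 <- gains$k1; k2 <- gains$k2
  G <- unclass(gamma)
  deriv <- function(t, y) {
    x1 <- y[1]; x2 <- y[2]; th <- y[3:5]
    W <- c(-x1, x2, -x1^2 * x2)
    u <- u_backstepping(x1, x2, sum(W * th), k1, k2, sgn)
    h <- x2 + k1 * x1
    c(x2, sum(W * theta) + u, h * (G %*% W))
  }
  y0 <- c(config$initial_state, config$initial_estimate)
  out <- integrate_system(deriv, y0, config)
  idx <- thin_rows(nrow(out), config$thin)
  x1 <- out[idx, 2]; x2 <- out[idx, 3]
  th <- out[idx, 4:6, drop = FALSE]
  wth_hat <- -th[, 1] * x1 + th[, 2] * x2 - th[, 3] * x1^2 * x2
  h <- x2 + k1 * x1
  Ginv <- solve(G)
  tt <- sweep(-th, 2, theta, "+")              # theta_tilde rows
  quad <- rowSums((tt %*% Ginv) * tt)
  df <- data.frame(
    t = out[idx, 1], x1 = x1, x2 = x2,
    u = u_backstepping(x1, x2, wth_hat, k1, k2, sgn),
    theta1_hat = th[, 1], theta2_hat = th[, 2], theta3_hat = th[, 3],
    V = 0.5 * x1^2 + 0.5 * h^2 + 0.5 * quad
  )
  new_trajectory(df, "adaptive", model, gains = gains, gamma = gamma,
                 config = config, law = match.arg(law))
}

#' @export
print.mood_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<mood_trajectory> kind = %s, %d samples over t in [%g, %g]\n",
    attr(x, "kind"), n, if (n) x$t[1] else NA, if (n) x$t[n] else NA
  ))
  if (n) {
    cat(sprintf("  final state: x1 = %.6g, x2 = %.6g\n", x$x1[n], x$x2[n]))
    if (!is.null(x$theta1_hat)) {
      cat(sprintf("  final estimate: (%.6g, %.6g, %.6g)\n",
                  x$theta1_hat[n], x$theta2_hat[n], x$theta3_hat[n]))
    }
  }
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' Simple base-graphics panels of mood, change rate, control input and (for
#' adaptive runs) the parameter estimates against time, for visual
#' comparison of scenarios.
#'
#' @param x a `mood_trajectory`.
#' @param ... passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.mood_trajectory <- function(x, ...) {
  has_est <- !is.null(x$theta1_hat)
  old <- graphics::par(mfrow = c(if (has_est) 4 else 3, 1),
                       mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$t, x$x1, type = "l", xlab = "t", ylab = "x1 (mood)", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$t, x$x2, type = "l", xlab = "t", ylab = "x2 (mood rate)", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$t, x$u, type = "l", xlab = "t", ylab = "u (treatment)", ...)
  if (has_est) {
    graphics::matplot(x$t, cbind(x$theta1_hat, x$theta2_hat, x$theta3_hat),
                      type = "l", lty = 1, xlab = "t", ylab = "theta_hat")
  }
  invisible(x)
}
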