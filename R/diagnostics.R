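#' Lyapunov function of the exact-model-knowledge loop
#'
#' The energy-like certificate \eqn{V = \tfrac12 x_1^2 + \tfrac12 h^2} with
#' \eqn{h = x_2 + k_1 x_1}. Along the corrected closed loop
#' \eqn{\dot V = -k_1 x_1^2 - k_2 h^2 \le 0}, so V decays (exponentially)
#' and certifies quenching. Nonnegative everywhere, zero only at rest.
#'
#' @param state numeric `(x1, x2)`.
#' @param k1 backstepping gain (> 0).
#' @return Scalar V.
#' @export
lyapunov_emk <- function(state, k1) {
  s <- check_state(state)
  h <- backstepping_error(s, k1)
  0.5 * s[1]^2 + 0.5 * h^2
}

#' Lyapunov function of the adaptive loop
#'
#' Adds the estimation-error energy to [lyapunov_emk()]:
#' \eqn{V = \tfrac12 x_1^2 + \tfrac12 h^2 +
#'      \tfrac12 \tilde\theta^\top \Gamma^{-1} \tilde\theta}.
#' Along the adaptive loop the update law cancels the cross term and again
#' \eqn{\dot V = -k_1 x_1^2 - k_2 h^2}: the state energy decays while the
#' estimation error stays bounded (it settles, but need not vanish).
#'
#' @param state numeric `(x1, x2)`.
#' @param theta_tilde numeric triple, the estimation error
#'   \eqn{\theta - \hat\theta}.
#' @param gamma an [adaptation_gain()] (or coercible).
#' @param k1 backstepping gain (> 0).
#' @return Scalar V.
#' @export
lyapunov_adaptive <- function(state, theta_tilde, gamma, k1) {
  tt <- check_theta(theta_tilde, "theta_tilde")
  gamma <- check_gamma(gamma)
  lyapunov_emk(state, k1) + 0.5 * sum(tt * solve(unclass(gamma), tt))
}

#' Check the exponential decay envelope of a Lyapunov series
#'
#' Verifies \eqn{V(t) \le V(0)\, e^{-\beta t} (1 + \mathrm{slack})} along a
#' simulated trajectory, with the sharp rate \eqn{\beta = 2\min(k_1, k_2)}
#' implied by \eqn{\dot V = -k_1 x_1^2 - k_2 h^2 \le -2\min(k_1,k_2) V}.
#' A degenerate all-zero series passes with worst ratio 0.
#'
#' @param trajectory a `mood_trajectory` carrying a `V` column.
#' @param gains the [control_gains()] of the run.
#' @param slack relative tolerance on the envelope (default `1e-6`).
#' @return A list with `pass` (logical), `beta`, and `worst_ratio` -- the
#'   maximum of \eqn{V(t) / (V(0) e^{-\beta t})} over the run (0 when
#'   `V(0) = 0`).
#' @export
exponential_envelope_check <- function(trajectory, gains, slack = 1e-6) {
  gains <- check_gains(gains)
  if (is.null(trajectory$V)) {
    stop_invalid("trajectory carries no Lyapunov series (`V` column)")
  }
  if (nrow(trajectory) == 0L) stop_invalid("empty trajectory")
  beta <- 2 * min(gains$k1, gains$k2)
  V <- trajectory$V
  V0 <- V[1]
  if (V0 == 0) {
    worst <- if (all(V == 0)) 0 else Inf
  } else {
    worst <- max(V / (V0 * exp(-beta * trajectory$t)))
  }
  list(pass = worst <= 1 + slack, beta = beta, worst_ratio = worst)
}

final_window_rows <- function(trajectory, window) {
  t <- trajectory$t
  dur <- t[length(t)] - t[1]
  if (window <= 0 || window >= dur) {
    stop_invalid("`window` must lie strictly inside the trajectory duration")
  }
  which(t >= t[length(t)] - window)
}

#' Oscillation and quenching metrics of a trajectory
#'
#' Summarizes mood behaviour: the peak amplitude of `x1` over the final
#' window (the steady-state swing size for an untreated run, residual error
#' for a treated one), the number of mood sign changes over the whole run,
#' and when (if ever) `|x1|` settles permanently below `settle_tol`. A sign
#' change is a strict crossing between consecutive samples; touching zero
#' without crossing does not count as a mood change.
#'
#' @param trajectory a `mood_trajectory`.
#' @param window length of the final window used for the amplitude, in time
#'   units; defaults to 25\% of the run.
#' @param settle_tol threshold on `|x1|` defining "settled" (default `1e-3`).
#' @return An object of class `convergence_report` with fields `settled`,
#'   `settling_time`, `zero_crossings`, `peak_amplitude` (plus empty
#'   estimate fields for interface uniformity).
#' @export
oscillation_metrics <- function(trajectory, window = NULL, settle_tol = 1e-3) {
  if (nrow(trajectory) == 0L) stop_invalid("empty trajectory")
  t <- trajectory$t
  if (is.null(window)) window <- 0.25 * (t[length(t)] - t[1])
  rows <- final_window_rows(trajectory, window)
  x1 <- trajectory$x1
  crossings <- sum(x1[-length(x1)] * x1[-1] < 0)
  above <- which(abs(x1) >= settle_tol)
  if (length(above) == 0L) {
    settled <- TRUE; settling_time <- t[1]
  } else if (max(above) == length(x1)) {
    settled <- FALSE; settling_time <- NA_real_
  } else {
    settled <- TRUE; settling_time <- t[max(above) + 1L]
  }
  structure(
    list(
      settled = settled,
      settling_time = settling_time,
      zero_crossings = crossings,
      peak_amplitude = max(abs(x1[rows])),
      final_estimate = NULL,
      estimate_drift = NA_real_
    ),
    class = "convergence_report"
  )
}

#' Successive oscillation peaks
#'
#' The values of the strict local maxima of `x1` inside the final window,
#' in time order. On a settled limit cycle these are the per-period swing
#' amplitudes; their relative spread measures how steady the oscillation is.
#'
#' @inheritParams oscillation_metrics
#' @return Numeric vector of peak values (possibly empty).
#' @export
peak_sequence <- function(trajectory, window = NULL) {
  if (nrow(trajectory) == 0L) stop_invalid("empty trajectory")
  t <- trajectory$t
  if (is.null(window)) window <- 0.25 * (t[length(t)] - t[1])
  rows <- final_window_rows(trajectory, window)
  x <- trajectory$x1[rows]
  n <- length(x)
  if (n < 3L) return(numeric(0))
  i <- 2:(n - 1L)
  x[i][x[i] > x[i - 1L] & x[i] > x[i + 1L]]
}

#' Parameter-estimate convergence report
#'
#' Judges whether the estimate of an adaptive run has settled: each
#' component's total variation over the final window must fall below
#' `drift_tol`. The final estimate (and, when the true parameters are
#' supplied, the final estimation error) is reported but its closeness to
#' the truth is never asserted -- gradient adaptation guarantees a settled,
#' bounded estimate, not identification.
#'
#' @param trajectory a `mood_trajectory` with estimate columns
#'   (`theta*_hat`).
#' @param true_theta optional numeric triple of true parameters for the
#'   error report.
#' @param window final-window length in time units; defaults to 25\% of the
#'   run.
#' @param drift_tol total-variation threshold per component (default
#'   `1e-4`).
#' @return A `convergence_report` with `settled`, `estimate_drift` (max
#'   component total variation), `final_estimate`, and `final_error` when
#'   `true_theta` is given.
#' @export
estimate_convergence <- function(trajectory, true_theta = NULL,
                                 window = NULL, drift_tol = 1e-4) {
  if (is.null(trajectory$theta1_hat)) {
    stop_invalid("trajectory carries no estimate series")
  }
  t <- trajectory$t
  if (is.null(window)) window <- 0.25 * (t[length(t)] - t[1])
  rows <- final_window_rows(trajectory, window)
  th <- as.matrix(trajectory[, c("theta1_hat", "theta2_hat", "theta3_hat")])
  tv <- apply(abs(diff(th[rows, , drop = FALSE])), 2, sum)
  final <- unname(th[nrow(th), ])
  out <- list(
    settled = all(tv < drift_tol),
    settling_time = NA_real_,
    zero_crossings = NA_integer_,
    peak_amplitude = NA_real_,
    final_estimate = final,
    estimate_drift = max(tv)
  )
  if (!is.null(true_theta)) {
    out$final_error <- check_theta(true_theta, "true_theta") - final
  }
  structure(out, class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>\n")
  if (!is.na(x$settling_time) || !is.null(x$settled)) {
    cat(sprintf("  settled: %s", x$settled))
    if (!is.na(x$settling_time)) cat(sprintf(" (t = %.4g)", x$settling_time))
    cat("\n")
  }
  if (!is.na(x$zero_crossings)) {
    cat(sprintf("  mood sign changes: %d\n", x$zero_crossings))
  }
  if (!is.na(x$peak_amplitude)) {
    cat(sprintf("  peak |x1| over final window: %.6g\n", x$peak_amplitude))
  }
  if (!is.null(x$final_estimate)) {
    cat(sprintf("  final estimate: (%s)\n",
                paste(format(x$final_estimate, digits = 6), collapse = ", ")))
    cat(sprintf("  max estimate drift over final window: %.3g\n",
                x$estimate_drift))
    if (!is.null(x$final_error)) {
      cat(sprintf("  final estimation error: (%s)\n",
                  paste(format(x$final_error, digits = 6), collapse = ", ")))
    }
  }
  invisible(x)
}
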