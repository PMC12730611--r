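#' Backstepping control gains
#'
#' The two positive gains of the backstepping design: `k1` shapes the
#' virtual control \eqn{x_{2d} = -k_1 x_1} stabilizing the mood equation,
#' and `k2` stabilizes the backstepping variable \eqn{h = x_2 - x_{2d}}.
#' The closed loop targeted by both controllers is
#' \eqn{\dot x_1 = -k_1 x_1 + h}, \eqn{\dot h = -k_2 h - x_1}.
#'
#' @param k1 backstepping gain (> 0).
#' @param k2 stabilizing gain (> 0).
#' @return An object of class `control_gains`.
#' @export
control_gains <- function(k1, k2) {
  structure(
    list(
      k1 = check_scalar(k1, "k1", positive = TRUE),
      k2 = check_scalar(k2, "k2", positive = TRUE)
    ),
    class = "control_gains"
  )
}

#' @export
print.control_gains <- function(x, ...) {
  cat(sprintf("<control_gains> k1 = %g, k2 = %g\n", x$k1, x$k2))
  invisible(x)
}

#' Adaptation gain matrix
#'
#' The 3x3 symmetric positive-definite gain of the parameter update law
#' \eqn{\dot{\hat\theta} = \Gamma W^\top h}. A scalar `g` is shorthand for
#' `g * diag(3)`. Symmetry and positive-definiteness (all eigenvalues > 0)
#' are verified at construction; positive-definiteness is all the stability
#' argument needs, so any such matrix is admitted.
#'
#' @param gamma positive scalar or 3x3 symmetric positive-definite matrix.
#' @return A 3x3 matrix of class `adaptation_gain`.
#' @export
adaptation_gain <- function(gamma) {
  if (is.numeric(gamma) && length(gamma) == 1L) {
    check_scalar(gamma, "gamma", positive = TRUE)
    gamma <- diag(as.numeric(gamma), 3L)
  }
  if (!is.matrix(gamma) || !identical(dim(gamma), c(3L, 3L)) ||
      !is.numeric(gamma) || !all(is.finite(gamma))) {
    stop_invalid("`gamma` must be a positive scalar or a finite 3x3 matrix")
  }
  gamma <- unname(gamma)
  if (max(abs(gamma - t(gamma))) > 1e-12 * max(1, max(abs(gamma)))) {
    stop_invalid("`gamma` must be symmetric")
  }
  ev <- eigen((gamma + t(gamma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_invalid("`gamma` must be positive-definite (all eigenvalues > 0)")
  }
  structure(gamma, class = c("adaptation_gain", class(gamma)))
}

check_gains <- function(gains) {
  if (!inherits(gains, "control_gains")) {
    stop_invalid("`gains` must be a control_gains object")
  }
  gains
}

check_gamma <- function(gamma) {
  if (!inherits(gamma, "adaptation_gain")) gamma <- adaptation_gain(gamma)
  gamma
}

#' Backstepping variable
#'
#' The tracking error \eqn{h = x_2 - x_{2d}} between the mood change rate
#' and the virtual control \eqn{x_{2d} = -k_1 x_1}, i.e.
#' \eqn{h = x_2 + k_1 x_1}. Driving both \eqn{x_1} and \eqn{h} to zero
#' quenches the mood swing.
#'
#' @param state numeric `(x1, x2)`.
#' @param k1 backstepping gain (> 0).
#' @return Scalar `h`.
#' @export
backstepping_error <- function(state, k1) {
  s <- check_state(state)
  k1 <- check_scalar(k1, "k1", positive = TRUE)
  s[2] + k1 * s[1]
}

# Core backstepping law, vectorized over states. `wtheta` is the drift term
# W.theta (true parameters for EMK, estimates for adaptive), evaluated by the
# caller. sgn = +1 gives the corrected law whose closed loop is exactly
# dx1 = -k1 x1 + h, dh = -k2 h - x1; sgn = -1 gives the as-printed variant
# (sign-flipped k1^2/k1 terms) kept for comparison runs.
u_backstepping <- function(x1, x2, wtheta, k1, k2, sgn = 1) {
  h <- x2 + k1 * x1
  -wtheta + sgn * (k1^2 * x1 - k1 * h) - x1 - k2 * h
}

law_sign <- function(law) {
  law <- match.arg(law, c("corrected", "as-printed"))
  if (law == "corrected") 1 else -1
}

#' Exact-model-knowledge treatment law
#'
#' The backstepping control input for a patient whose parameters are known:
#' \deqn{u = -W\theta + k_1^2 x_1 - k_1 h - x_1 - k_2 h,}
#' with \eqn{h = x_2 + k_1 x_1}. The \eqn{-W\theta} term cancels the plant
#' drift exactly, so the closed loop is the linear, exponentially stable
#' system \eqn{\dot x_1 = -k_1 x_1 + h}, \eqn{\dot h = -k_2 h - x_1}.
#'
#' `law = "as-printed"` selects a variant with the signs of the
#' \eqn{k_1^2 x_1} and \eqn{k_1 h} terms flipped. It no longer achieves the
#' exact cancellation above but still yields a stable linear loop at the
#' reference gains; it is retained only for comparison runs.
#'
#' @param model a [mood_model()] (the true patient parameters).
#' @param state numeric `(x1, x2)`.
#' @param gains a [control_gains()].
#' @param law `"corrected"` (default) or `"as-printed"`.
#' @return Scalar treatment input `u`.
#' @examples
#' m <- mood_model(1, 2, 9)
#' emk_control(m, c(0.5, 0), control_gains(1.1, 10))  # -1.5
#' @export
emk_control <- function(model, state, gains, law = c("corrected", "as-printed")) {
  if (!inherits(model, "mood_model")) stop_invalid("`model` must be a mood_model")
  gains <- check_gains(gains)
  s <- check_state(state)
  wtheta <- sum(regressor(s) * pack_parameters(model))
  u_backstepping(s[1], s[2], wtheta, gains$k1, gains$k2, law_sign(law))
}

#' Adaptive treatment law
#'
#' The same backstepping structure as [emk_control()] with the unknown true
#' parameter vector replaced by its running estimate:
#' \deqn{u = -W\hat\theta + k_1^2 x_1 - k_1 h - x_1 - k_2 h.}
#' The imperfect cancellation leaves
#' \eqn{\dot h = -k_2 h - x_1 + W\tilde\theta} with estimation error
#' \eqn{\tilde\theta = \theta - \hat\theta}; paired with [update_law()] the
#' cross term cancels in the Lyapunov derivative and the loop remains
#' stable without parameter knowledge.
#'
#' @param theta_hat numeric triple, the current parameter estimate.
#' @param state numeric `(x1, x2)`.
#' @param gains a [control_gains()].
#' @param law `"corrected"` (default) or `"as-printed"`.
#' @return Scalar treatment input `u`.
#' @export
adaptive_control <- function(theta_hat, state, gains,
                             law = c("corrected", "as-printed")) {
  theta_hat <- check_theta(theta_hat, "theta_hat")
  gains <- check_gains(gains)
  s <- check_state(state)
  wtheta <- sum(regressor(s) * theta_hat)
  u_backstepping(s[1], s[2], wtheta, gains$k1, gains$k2, law_sign(law))
}

#' Gradient parameter update law
#'
#' The estimate dynamics \eqn{\dot{\hat\theta} = \Gamma\, W^\top h}: the
#' regressor scaled by the backstepping error and shaped by the adaptation
#' gain. Chosen so the \eqn{h\,W\tilde\theta} cross term of the closed loop
#' cancels against \eqn{-\tilde\theta^\top \Gamma^{-1} \dot{\hat\theta}} in
#' the Lyapunov derivative, leaving \eqn{\dot V = -k_1 x_1^2 - k_2 h^2}.
#' The estimate therefore settles to some constant; it is not guaranteed to
#' reach the true parameters (that would require persistent excitation,
#' which a quenched trajectory does not provide).
#'
#' @param state numeric `(x1, x2)`.
#' @param k1 backstepping gain (> 0).
#' @param gamma an [adaptation_gain()] (or scalar/matrix coercible to one).
#' @return Numeric triple, the estimate time-derivative.
#' @export
update_law <- function(state, k1, gamma) {
  s <- check_state(state)
  k1 <- check_scalar(k1, "k1", positive = TRUE)
  gamma <- check_gamma(gamma)
  h <- s[2] + k1 * s[1]
  as.numeric(h * (unclass(gamma) %*% regressor(s)))
}
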