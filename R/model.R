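#' Bipolar II mood oscillator model
#'
#' Constructs the patient model underlying the whole package: a Lienard
#' oscillator of van der Pol type,
#' \deqn{\ddot x - b\,(a - x^2)\,\dot x + c\,x = u(t),}
#' where \eqn{x} is the (dimensionless) emotional mood, \eqn{\dot x} its
#' change rate, and \eqn{u} the treatment input. In state-space form with
#' \eqn{x_1 = x}, \eqn{x_2 = \dot x}:
#' \deqn{\dot x_1 = x_2, \qquad
#'       \dot x_2 = -c\,x_1 + b\,a\,x_2 - b\,x_1^2 x_2 + u.}
#' Untreated (\eqn{u \equiv 0}), any nonzero initial mood settles onto a
#' stable limit cycle -- the mood swing alternating between hypomanic and
#' depressive phases. All quantities are dimensionless.
#'
#' @param a damping threshold: mood amplitudes with \eqn{x_1^2 < a} are
#'   anti-damped (pushed away from rest), larger amplitudes are damped.
#'   Must be > 0.
#' @param b nonlinear damping gain scaling how strongly that mechanism acts.
#'   Must be > 0.
#' @param c restoring stiffness pulling mood back toward neutral; the
#'   small-oscillation angular frequency is \eqn{\sqrt{c}}. Must be > 0.
#' @return An object of class `mood_model`.
#' @seealso [vector_field()], [pack_parameters()], [equilibrium()]
#' @examples
#' m <- mood_model(a = 1, b = 2, c = 9)
#' pack_parameters(m)
#' @export
mood_model <- function(a, b, c) {
  structure(
    list(
      a = check_scalar(a, "a", positive = TRUE),
      b = check_scalar(b, "b", positive = TRUE),
      c = check_scalar(c, "c", positive = TRUE)
    ),
    class = "mood_model"
  )
}

#' @export
print.mood_model <- function(x, ...) {
  cat(sprintf(
    "<mood_model> a = %g, b = %g, c = %g  (theta = %s)\n",
    x$a, x$b, x$c, paste(format(pack_parameters(x)), collapse = ", ")
  ))
  invisible(x)
}

#' Mood state vector
#'
#' Bundles the two state variables: `x1`, the emotional mood, and `x2`, its
#' change rate. Plain length-2 numeric vectors are accepted everywhere a
#' state is expected; this constructor only validates finiteness.
#'
#' @param x1 emotional mood.
#' @param x2 mood change rate.
#' @return A named numeric vector `c(x1 = , x2 = )`.
#' @export
mood_state <- function(x1, x2) {
  s <- check_state(c(x1, x2))
  c(x1 = s[1], x2 = s[2])
}

#' Plant vector field
#'
#' Evaluates the state derivative \eqn{(\dot x_1, \dot x_2)} of the mood
#' oscillator at a state under a treatment input `u`.
#'
#' @param model a [mood_model()].
#' @param state numeric `(x1, x2)`.
#' @param u treatment input (scalar, default 0).
#' @return Named numeric vector `c(x1 = dx1, x2 = dx2)`.
#' @examples
#' m <- mood_model(1, 2, 9)
#' vector_field(m, c(0.5, 0))   # (0, -4.5)
#' @export
vector_field <- function(model, state, u = 0) {
  if (!inherits(model, "mood_model")) stop_invalid("`model` must be a mood_model")
  s <- check_state(state)
  u <- check_scalar(u, "u")
  x1 <- s[1]; x2 <- s[2]
  c(
    x1 = x2,
    x2 = -model$c * x1 + model$b * model$a * x2 - model$b * x1^2 * x2 + u
  )
}

#' Regression vector of the mood dynamics
#'
#' The drift of \eqn{\dot x_2} is linear in the parameters: with
#' \eqn{W(x) = (-x_1,\; x_2,\; -x_1^2 x_2)} and
#' \eqn{\theta = (c,\; b a,\; b)} it equals \eqn{W \theta}. This
#' linear-in-the-parameters form is what makes gradient adaptation possible.
#'
#' @param state numeric `(x1, x2)`.
#' @return Numeric triple `(w1, w2, w3)`.
#' @seealso [pack_parameters()], [update_law()]
#' @export
regressor <- function(state) {
  s <- check_state(state)
  c(-s[1], s[2], -s[1]^2 * s[2])
}

#' Parameter vector of the mood model
#'
#' Packs the patient parameters into the triple
#' \eqn{\theta = (c,\; b a,\; b)} multiplying the regressor of the
#' \eqn{\dot x_2} drift. For the reference patient (a = 1, b = 2, c = 9)
#' this is (9, 2, 2).
#'
#' @param model a [mood_model()].
#' @return Numeric triple `theta`.
#' @export
pack_parameters <- function(model) {
  if (!inherits(model, "mood_model")) stop_invalid("`model` must be a mood_model")
  c(model$c, model$b * model$a, model$b)
}

#' Equilibrium of the unforced mood model
#'
#' The unforced oscillator has a single equilibrium, the neutral mood
#' \eqn{(x_1, x_2) = (0, 0)}: the drift \eqn{-c x_1 + b a x_2 - b x_1^2 x_2}
#' vanishes together with \eqn{x_2} only there (the first equation forces
#' \eqn{x_2 = 0}, the second then forces \eqn{c x_1 = 0} with \eqn{c > 0}).
#' Treatment aims to drive the state to this point.
#'
#' @param model a [mood_model()].
#' @return The state `c(x1 = 0, x2 = 0)`.
#' @export
equilibrium <- function(model) {
  if (!inherits(model, "mood_model")) stop_invalid("`model` must be a mood_model")
  c(x1 = 0, x2 = 0)
}
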