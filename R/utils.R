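# Internal validation helpers. All user-facing argument errors carry the
# condition class "moodswing_invalid" so callers (and the CLI) can
# distinguish bad input from integration failure.

stop_invalid <- function(msg, class = "moodswing_invalid", ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_integration <- function(time, msg) {
  stop(structure(
    class = c("moodswing_integration_failure", "error", "condition"),
    list(
      message = sprintf("integration failed at t = %.6g: %s", time, msg),
      call = sys.call(-1), time = time
    )
  ))
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  as.numeric(x)
}

# Accepts c(x1, x2) (named or not) and returns an unnamed finite length-2
# numeric vector.
check_state <- function(state, name = "state") {
  if (!is.numeric(state) || length(state) != 2L) {
    stop_invalid(sprintf("`%s` must be a numeric vector (x1, x2)", name))
  }
  if (!all(is.finite(state))) {
    stop_invalid(sprintf("`%s` must have finite components", name))
  }
  as.numeric(unname(state))
}

check_theta <- function(theta, name = "theta") {
  if (!is.numeric(theta) || length(theta) != 3L || !all(is.finite(theta))) {
    stop_invalid(sprintf("`%s` must be a finite numeric triple", name))
  }
  as.numeric(unname(theta))
}
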