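# Shared fixtures and independent oracles.

ref_model <- function() mood_model(a = 1, b = 2, c = 9)
ref_state <- function() c(0.5, 0)

# Closed-form solution of the linear closed loop the corrected EMK law
# produces: z = (x1, h), dz/dt = A z with A = [[-k1, 1], [-1, -k2]].
# Solved by eigendecomposition (matrix exponential), independent of any
# time stepper. Returns t, x1, x2 (x2 = h - k1 x1) and V = (x1^2 + h^2)/2.
emk_closed_form <- function(gains, x0, times) {
  k1 <- gains$k1; k2 <- gains$k2
  A <- matrix(c(-k1, -1, 1, -k2), 2, 2)
  z0 <- c(x0[1], x0[2] + k1 * x0[1])
  eg <- eigen(A)
  coef <- solve(eg$vectors, z0)
  Z <- sapply(times, function(t) Re(eg$vectors %*% (coef * exp(eg$values * t))))
  x1 <- Z[1, ]; h <- Z[2, ]
  data.frame(t = times, x1 = x1, x2 = h - k1 * x1,
             V = 0.5 * (x1^2 + h^2))
}

# Numerical Jacobian of f: R^n -> R^n by central differences.
num_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- eps
    J[, j] <- (f(x + e) - f(x - e)) / (2 * eps)
  }
  J
}

random_model <- function() {
  mood_model(a = runif(1, 0.2, 3), b = runif(1, 0.2, 4), c = runif(1, 0.5, 12))
}

random_gains <- function() control_gains(runif(1, 0.3, 3), runif(1, 1, 15))
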