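test_that("Lyapunov functions reproduce hand-computed values", {
  expect_equal(lyapunov_emk(c(0, 0), 1.1), 0)
  expect_equal(lyapunov_emk(c(0.5, 0), 1.1), 0.27625)
  expect_equal(lyapunov_emk(c(0.5, 0), 1.22), 0.31105)
  expect_equal(lyapunov_adaptive(c(0.5, 0), c(0, 0, 0), 0.1, 1.22),
               lyapunov_emk(c(0.5, 0), 1.22))
  expect_equal(lyapunov_adaptive(c(0, 0), c(1, 1, 1), 0.1, 1.0), 15)
  expect_equal(lyapunov_adaptive(c(0.5, 0), c(3, -0.5, -3), 0.1, 1.22),
               91.56105)
  # a general positive-definite Gamma goes through its inverse
  G <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  tt <- c(1, -2, 0.5)
  expect_equal(lyapunov_adaptive(c(0, 0), tt, G, 1),
               0.5 * sum(tt * solve(G, tt)))
})

test_that("V is non-increasing along both controlled loops and its slope
           matches -k1 x1^2 - k2 h^2", {
  m <- ref_model()
  ge <- control_gains(1.1, 10)
  te <- simulate_emk(m, ge, sim_config(10))
  expect_lt(max(diff(te$V)), 1e-9)
  ga <- control_gains(1.22, 10)
  ta <- simulate_adaptive(m, ga, 0.1, sim_config(10,
                                                 initial_estimate = c(6, 2.5, 5)))
  expect_lt(max(diff(ta$V)), 1e-9)
  step <- 1e-3
  for (case in list(list(tr = te, g = ge), list(tr = ta, g = ga))) {
    tr <- case$tr; g <- case$g
    n <- nrow(tr)
    fd <- (tr$V[-(1:2)] - tr$V[1:(n - 2)]) / (2 * step)
    h <- tr$x2 + g$k1 * tr$x1
    analytic <- (-g$k1 * tr$x1^2 - g$k2 * h^2)[-c(1, n)]
    expect_lt(max(abs(fd - analytic)), 5e-4)   # O(step^2) agreement
  }
})

test_that("exponential envelope check passes real runs and rejects
           constructed violations", {
  m <- ref_model()
  g <- control_gains(1.1, 10)
  tr <- simulate_emk(m, g, sim_config(10))
  env <- exponential_envelope_check(tr, g)
  expect_true(env$pass)
  expect_equal(env$beta, 2.2)
  # degenerate all-zero run
  zero <- simulate_emk(m, g, sim_config(2, initial_state = c(0, 0)))
  env0 <- exponential_envelope_check(zero, g)
  expect_true(env0$pass)
  expect_equal(env0$worst_ratio, 0)
  # a series inflated 1% above the envelope must fail at slack 1e-6
  t <- seq(0, 5, by = 0.01)
  fake <- data.frame(t = t, V = 0.27625 * exp(-2.2 * t) * 1.01)
  fake$V[1] <- 0.27625
  bad <- exponential_envelope_check(fake, g, slack = 1e-6)
  expect_false(bad$pass)
  expect_gt(bad$worst_ratio, 1.009)
  # missing Lyapunov series is a usage error
  expect_error(
    exponential_envelope_check(simulate_untreated(m, sim_config(2)), g),
    class = "moodswing_invalid"
  )
})

test_that("EMK decay is at least as fast as the slow-gain bound 2*k1", {
  g <- control_gains(1.1, 10)
  oracle <- emk_closed_form(g, ref_state(), seq(0, 10, by = 0.01))
  expect_true(all(oracle$V <= oracle$V[1] * exp(-2 * g$k1 * oracle$t) *
                    (1 + 1e-9)))
})

test_that("oscillation metrics quantify the untreated swing and the
           quenched treatment", {
  m <- ref_model()
  un <- simulate_untreated(m, sim_config(12))
  mu <- oscillation_metrics(un, window = 3)
  expect_gt(mu$zero_crossings, 5)
  expect_false(mu$settled)
  # steady-state amplitude agrees with a half-step reference within 0.5%
  fine <- simulate_untreated(m, sim_config(12, step = 5e-4))
  mf <- oscillation_metrics(fine, window = 3)
  expect_lt(abs(mu$peak_amplitude - mf$peak_amplitude) / mf$peak_amplitude,
            0.005)
  em <- simulate_emk(m, control_gains(1.1, 10), sim_config(10))
  me <- oscillation_metrics(em)
  expect_identical(me$zero_crossings, 0L)
  expect_true(me$settled)
  expect_lte(me$settling_time, 10)
  # zero trajectory: amplitude 0, crossings 0
  z <- simulate_untreated(m, sim_config(2, initial_state = c(0, 0)))
  mz <- oscillation_metrics(z)
  expect_equal(mz$peak_amplitude, 0)
  expect_identical(mz$zero_crossings, 0L)
  expect_equal(mz$settling_time, 0)
})

test_that("touching zero without crossing is not counted as a mood change", {
  tr <- data.frame(t = seq(0, 1, by = 0.25),
                   x1 = c(0.5, 0, 0.5, 0, 0.3), x2 = 0, u = 0)
  expect_identical(oscillation_metrics(tr, window = 0.5)$zero_crossings, 0L)
  tr2 <- data.frame(t = seq(0, 1, by = 0.25),
                    x1 = c(0.5, -0.1, 0.5, 0, 0.3), x2 = 0, u = 0)
  expect_identical(oscillation_metrics(tr2, window = 0.5)$zero_crossings, 2L)
})

test_that("peak sequence extracts per-period amplitudes on a settled cycle", {
  un <- simulate_untreated(ref_model(), sim_config(40))
  pk <- peak_sequence(un, window = 10)
  expect_gte(length(pk), 3)
  expect_lt((max(pk) - min(pk)) / mean(pk), 0.01)
})

test_that("estimate convergence is judged by final-window total variation", {
  t <- seq(0, 10, by = 0.01)
  const <- data.frame(t = t, theta1_hat = 6, theta2_hat = 2.5, theta3_hat = 5)
  rc <- estimate_convergence(const)
  expect_true(rc$settled)
  expect_equal(rc$estimate_drift, 0)
  expect_equal(rc$final_estimate, c(6, 2.5, 5))
  # estimates decaying onto the truth: settled, final error ~ 0
  theta <- c(9, 2, 2)
  dec <- data.frame(t = t,
                    theta1_hat = theta[1] + exp(-t),
                    theta2_hat = theta[2] + exp(-t),
                    theta3_hat = theta[3] + exp(-t))
  rd <- estimate_convergence(dec, true_theta = theta, drift_tol = 1e-3)
  expect_true(rd$settled)
  expect_equal(rd$final_error, rep(-exp(-10), 3), tolerance = 1e-6)
  expect_lt(max(abs(rd$final_error)), 1e-4)
  # a wandering estimate is not settled
  wander <- data.frame(t = t, theta1_hat = sin(t), theta2_hat = 2,
                       theta3_hat = 2)
  expect_false(estimate_convergence(wander)$settled)
  # trajectories without estimates are rejected
  expect_error(
    estimate_convergence(simulate_untreated(ref_model(), sim_config(2))),
    class = "moodswing_invalid"
  )
})
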