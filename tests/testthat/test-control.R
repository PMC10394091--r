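ps <- load_preset("lung-ref")

test_that("objective value integrates the weighted burden correctly", {
  t <- seq(0, 1, by = 0.01)
  zero <- list(times = t, states = matrix(0, length(t), 4))
  expect_equal(objective_value(zero, control_weights(1, 1, 1, 1)), 0)
  ones <- list(times = t, states = matrix(1, length(t), 4))
  expect_equal(objective_value(ones, control_weights(1, 1, 1, 1)), 2)
  ramp <- list(times = t, states = cbind(t, 0 * t, 0 * t, 0 * t))
  expect_equal(objective_value(ramp, control_weights(2, 0, 0, 0)), 1,
               tolerance = 1e-12)
})

test_that("objective value is linear in the weights", {
  t <- seq(0, 3, by = 0.05)
  traj <- list(times = t, states = cbind(sin(t) + 2, cos(t) + 2, t, t^2))
  w <- control_weights(0.3, 1.2, 0.7, 0.4)
  wc <- control_weights(3 * 0.3, 3 * 1.2, 3 * 0.7, 3 * 0.4)
  expect_equal(objective_value(traj, wc), 3 * objective_value(traj, w))
})

test_that("PID law reproduces its pure-term examples", {
  g <- function(Kp, Ki, Kd) pid_gains(Kp, Ki, Kd, N_target = 0,
                                      tolerance = 1)
  expect_equal(pid_update(5, g(1, 0, 0), dt = 1), 5)
  e <- rep(2, 5)                                   # t in [0, 4]
  expect_equal(pid_update(e, g(0, 0.5, 0), dt = 1), 4)
  e <- 3 * (0:4) * 0.5                             # e(t) = 3 t, dt = 0.5
  expect_equal(pid_update(e, g(0, 0, 2), dt = 0.5), 6, tolerance = 1e-9)
  expect_error(pid_update(numeric(0), g(1, 0, 0), 1), "at least one")
  expect_error(pid_update(1, g(1, 0, 0), 0), "positive")
})

test_that("PID with default gains drives the scalar plant x' = -x + u to setpoint", {
  g <- pid_gains()            # default Kp, Ki, Kd
  dt <- 0.01
  for (r in c(0.5, 2, -1)) {
    x <- 0; ehist <- numeric(0)
    for (k in 1:8000) {
      ehist <- c(ehist, r - x)
      u <- pid_update(ehist, g, dt)
      x <- x + dt * (-x + u)            # forward Euler on the plant
    }
    expect_lt(abs(x - r), 1e-3)
  }
})

test_that("sweep with all-zero weights returns the trivial fixed point at once", {
  cs <- forward_backward_sweep(demo_therapy_params(), demo_init,
                               control_weights(0, 0, 0, 0), horizon = 5,
                               h = 2^-6, max_iter = 5)
  expect_true(all(cs$costates == 0))
  expect_true(all(cs$control == 0))
  expect_equal(cs$J, 0)
  expect_equal(cs$transversality_residual, 0)
  expect_true(cs$converged)
  expect_lte(nrow(cs$iterations), 1)
})

test_that("sweep improves on the uncontrolled objective for the demo therapy", {
  # In the plain therapy model the dose acts on the disseminated pool, so
  # weight that pool: the optimal dose must strictly beat no treatment.
  tp <- demo_therapy_params()
  w <- control_weights(0, 0, 1, 0)
  cs <- forward_backward_sweep(tp, demo_init, w, horizon = 10, h = 2^-6,
                               u_max = 0.05, max_iter = 25)
  rhs <- make_rhs(tp, "therapy", use_input = TRUE)
  n <- round(10 / 2^-6)
  sol0 <- solve_classical(rhs, demo_init, 0, 10, 2^-6,
                          input = rep(0, n + 1))
  J0 <- objective_value(sol0, w)
  expect_lt(cs$J, J0)                   # strictly better: dose clears P
  expect_equal(unname(cs$costates[nrow(cs$costates), ]), rep(0, 4))
  expect_true(all(diff(cs$iterations$J[cs$iterations$accepted]) <= 1e-9))
  expect_true(all(cs$control >= 0 & cs$control <= 0.05))
})

test_that("dosing loop terminates immediately when the target is already met", {
  tp <- demo_therapy_params()
  rhs <- make_rhs(tp, "feedback", use_input = TRUE)
  n <- round(30 / 2^-6)
  N30 <- solve_classical(rhs, demo_init, 0, 30, 2^-6,
                         input = rep(0, n + 1))$states[n + 1, 1]
  g <- pid_gains(Kp = 1, Ki = 0.5, Kd = 0.1, N_target = N30, tolerance = 1,
                 u_init = 0)
  hist <- feedback_dosing_loop(tp, demo_init, g, horizon = 30, h = 2^-6)
  expect_equal(hist$termination, "converged")
  expect_equal(nrow(hist$cycles), 1)
  expect_lt(abs(hist$cycles$error[1]), 1e-6)
})

test_that("all-zero gains hold the dosage constant until the cycle budget runs out", {
  tp <- demo_therapy_params()
  g <- pid_gains(Kp = 0, Ki = 0, Kd = 0, N_target = 40, tolerance = 0.5,
                 max_cycles = 4, u_init = 0.005)
  hist <- feedback_dosing_loop(tp, demo_init, g, horizon = 30, h = 2^-6)
  expect_equal(hist$termination, "max_cycles")
  expect_equal(nrow(hist$cycles), 4)
  expect_true(all(hist$cycles$dose == 0.005))
})

test_that("closed-loop dosing converges to a mid-range tumor target", {
  tp <- demo_therapy_params()
  g <- pid_gains(Kp = 2e-4, Ki = 1e-4, Kd = 0, N_target = 40,
                 tolerance = 0.5, max_cycles = 50, u_max = 0.05)
  hist <- feedback_dosing_loop(tp, demo_init, g, horizon = 30, h = 2^-6)
  expect_equal(hist$termination, "converged")
  expect_lte(abs(hist$cycles$error[nrow(hist$cycles)]), 0.5)
  # loop is deterministic: repeat run is identical
  hist2 <- feedback_dosing_loop(tp, demo_init, g, horizon = 30, h = 2^-6)
  expect_identical(hist$cycles, hist2$cycles)
})

test_that("auxiliary quadratures reproduce constants, ramps and exact polynomials", {
  t <- seq(0, 4, by = 0.05)
  psi <- matrix(0, length(t), 10)
  phis <- load_preset("lung-ref")$phi_control
  wv <- auxiliary_WV(psi, t, phis, eps1 = 0.5, eps3 = 0.5)
  expect_true(all(wv$W == 100) && all(wv$V == 50))

  psi10 <- psi; psi10[, 10] <- 1
  wv <- auxiliary_WV(psi10, t, phis, eps1 = 0.5, eps3 = 0)
  expect_equal(wv$W, 100 + t, tolerance = 1e-12)

  # linear adjoints: trapezoid is exact; compare against the closed form
  psi_lin <- psi
  psi_lin[, 2] <- 2 * t; psi_lin[, 5] <- 1 - t; psi_lin[, 7] <- 0.5 * t
  psi_lin[, 9] <- t; psi_lin[, 6] <- 3 * t; psi_lin[, 10] <- 2 - t
  wv <- auxiliary_WV(psi_lin, t, phis, eps1 = 0.5, eps3 = 0.5)
  W_exact <- 100 + (2 * t - t^2 / 2) - 0.5 * 3 * t^2 / 2
  V_exact <- 50 + (phis[["phi1"]] + phis[["phi3"]]) * t^2 +
    phis[["phi2"]] * (t - t^2 / 2) + phis[["phi4"]] * 0.5 * t^2 / 2 -
    0.5 * t^2 / 2
  expect_equal(wv$W, W_exact, tolerance = 1e-10)
  expect_equal(wv$V, V_exact, tolerance = 1e-10)
})

test_that("sweep costates embed into the ten-adjoint layout in the right slots", {
  cs <- forward_backward_sweep(demo_therapy_params(), demo_init,
                               control_weights(1, 0, 0, 0), horizon = 2,
                               h = 2^-6, max_iter = 3)
  psi <- costates_to_psi(cs)
  expect_equal(dim(psi), c(nrow(cs$costates), 10))
  expect_equal(psi[, 1], cs$costates[, 1])
  expect_equal(psi[, 2], cs$costates[, 2])
  expect_equal(psi[, 4], cs$costates[, 3])
  expect_equal(psi[, 10], cs$costates[, 4])
  expect_true(all(psi[, c(3, 5:9)] == 0))
})
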