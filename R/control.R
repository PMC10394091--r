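#' Objective weights for the combined-therapy optimization
#'
#' Weighting factors of the running cost
#' `J = integral( w1 N + w2 I + w3 P - w4 T ) dt`: penalise primary tumor
#' burden, tumor-promoting immune load and disseminated cells, and reward
#' the surgically removed pool.
#'
#' @param w1,w2,w3,w4 nonnegative weights, not all zero for a meaningful
#'   problem (all-zero is allowed and gives the trivial solution).
#' @return object of class `control_weights`.
#' @export
control_weights <- function(w1 = 1, w2 = 1, w3 = 1, w4 = 1) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and nonnegative", call. = FALSE)
  structure(as.list(w), class = "control_weights")
}

#' PID controller configuration for dosage scheduling
#'
#' @param Kp,Ki,Kd nonnegative proportional, integral and derivative gains.
#' @param N_target target primary-tumor count at the end of the treatment
#'   horizon (cells).
#' @param tolerance absolute stopping band on the end-of-horizon error
#'   (cells), `> 0`.
#' @param max_cycles upper bound on dosing cycles, `>= 1`.
#' @param u_max dosage clamp (dimensionless scaling of the nominal
#'   efficacies).
#' @param u_init initial dosage.
#' @return object of class `pid_gains`.
#' @export
pid_gains <- function(Kp = 1, Ki = 0.5, Kd = 0, N_target = 0,
                      tolerance = 1, max_cycles = 50L, u_max = 5,
                      u_init = 0) {
  if (any(c(Kp, Ki, Kd) < 0)) stop("gains must be nonnegative", call. = FALSE)
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)
  if (max_cycles < 1) stop("`max_cycles` must be at least 1", call. = FALSE)
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd, N_target = N_target,
                 tolerance = tolerance, max_cycles = as.integer(max_cycles),
                 u_max = u_max, u_init = u_init),
            class = "pid_gains")
}

#' Running-cost objective of a therapy trajectory
#'
#' Composite-trapezoid value of
#' `J = integral over [0, t_f] of (w1 N + w2 I + w3 P - w4 T) dt`
#' on the trajectory's own grid. Linear in the weights.
#'
#' @param traj an `fde_solution` with at least the four state columns
#'   `(N, I, P, T)`.
#' @param weights a [control_weights()] object.
#' @return scalar objective value `J`.
#' @export
objective_value <- function(traj, weights) {
  st <- traj$states
  if (ncol(st) < 4L)
    stop("trajectory must carry the four therapy states (N, I, P, T)",
         call. = FALSE)
  w <- weights
  integrand <- w$w1 * st[, 1] + w$w2 * st[, 2] + w$w3 * st[, 3] -
    w$w4 * st[, 4]
  pracma::trapz(traj$times, integrand)
}

#' PID control law on a sampled error history
#'
#' `u = Kp e(t) + Ki * integral of e + Kd * de/dt`, with the integral
#' taken by composite trapezoid over the supplied history and the
#' derivative as the backward difference `(e_n - e_{n-1})/dt` (zero when
#' only one sample exists).
#'
#' @param error_history numeric vector of error samples on a uniform grid.
#' @param gains a [pid_gains()] object.
#' @param dt sampling step, `> 0`.
#' @return scalar control value `u`.
#' @export
pid_update <- function(error_history, gains, dt) {
  e <- as.numeric(error_history)
  n <- length(e)
  if (n < 1L) stop("need at least one error sample", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  integral <- if (n > 1L) pracma::trapz(dt * (seq_len(n) - 1), e) else 0
  deriv <- if (n > 1L) (e[n] - e[n - 1L]) / dt else 0
  gains$Kp * e[n] + gains$Ki * integral + gains$Kd * deriv
}

# analytic Jacobian of the therapy dynamics wrt the four states, at a
# given time and dosage (needed by the backward costate sweep)
therapy_jacobian <- function(state, t, params, dose = 1) {
  p <- params
  N <- state[1]; I <- state[2]; P <- state[3]
  th <- heaviside_delay(t, p$tau)
  e1 <- dose * p$eps1; e2 <- dose * p$eps2; e3 <- dose * p$eps3
  matrix(c(
    p$lam * (1 - 2 * N / p$K) - p$mu * P - p$beta1 * I, -p$beta1 * N,
      -p$mu * N, 0,
    2 * p$phi2 * N, -p$phi3 - p$beta2 * P, -p$beta2 * I, 0,
    p$gamma * P - th * e1 * P, -p$beta3 * P - th * e2 * P,
      p$gamma * N - p$delta - p$beta3 * I - th * (e1 * N + e2 * I), 0,
    0, 0, th * e3, -p$eps4),
    nrow = 4, byrow = TRUE)
}

#' Pontryagin forward-backward sweep for the combined-therapy problem
#'
#' Minimises the running cost of [objective_value()] over a bounded dosage
#' signal `u(t)` in `[0, u_max]` that scales the therapy efficacies
#' `(eps1, eps2, eps3)` multiplicatively in the therapy dynamics. The
#' textbook first-order conditions are used: Hamiltonian
#' `H = w1 N + w2 I + w3 P - w4 T + lambda' f(x, u)`, costate equations
#' `lambda' = -dH/dx` integrated backward from the transversality condition
#' `lambda(t_f) = 0`, and a control update from the Hamiltonian's
#' `u`-gradient. Because `H` is affine in `u`, the minimising control is
#' bang-bang in the switching function
#' `dH/du = theta(t - tau) * (lambda_P (-eps1 N P - eps2 I P) +
#' lambda_T eps3 P)`; the update relaxes toward that target and is accepted
#' only if the objective does not increase (backtracking halves the
#' relaxation otherwise), so the iteration log of `J` is non-increasing by
#' construction.
#'
#' The sweep operates on the integer-order (`alpha = 1`) dynamics: the
#' costate system of a Caputo problem involves right-sided fractional
#' derivatives that the package deliberately does not implement (see the
#' vignette), and the dosing layer of the model is specified at integer
#' order. Forward and backward integrations use the fixed-step classical
#' solver on a shared grid.
#'
#' @param params a [therapy_params()] object.
#' @param init initial state `c(N, I, P, T)`.
#' @param weights a [control_weights()] object.
#' @param horizon final time `t_f` (days).
#' @param h grid step (default `2^-8`; the reference dynamics need
#'   `h <~ 2^-8` for explicit stability).
#' @param u_max dosage bound.
#' @param relaxation initial relaxation factor of the control update in
#'   (0, 1].
#' @param tol sup-norm convergence tolerance on the control iterates.
#' @param max_iter sweep iteration bound.
#' @param max_backtracks backtracking halvings per iteration before the
#'   sweep stops with the last accepted control.
#' @return object of class `control_solution`: `state` (an
#'   `fde_solution`), `costates` (matrix, terminal row zero), `control`
#'   (dosage on the grid), `J`, `iterations` (data.frame of `iter`, `J`,
#'   `relaxation`, `accepted`), `converged`, `transversality_residual`.
#' @export
forward_backward_sweep <- function(params, init, weights, horizon = 30,
                                   h = 2^-8, u_max = 1, relaxation = 0.5,
                                   tol = 1e-4, max_iter = 50L,
                                   max_backtracks = 10L) {
  stopifnot(inherits(params, "therapy_params"),
            inherits(weights, "control_weights"))
  rhs_u <- make_rhs(params, "therapy", use_input = TRUE)
  n <- round(horizon / h)
  times <- h * (0:n)
  u <- rep(0, n + 1L)

  forward <- function(u) solve_classical(rhs_u, init, 0, horizon, h,
                                         input = u, name = "therapy")
  sol <- forward(u)
  J <- objective_value(sol, weights)

  backward <- function(sol, u) {
    states <- sol$states
    interp <- lapply(seq_len(ncol(states)), function(j)
      stats::approxfun(times, states[, j], rule = 2))
    uf <- stats::approxfun(times, u, method = "constant", rule = 2)
    g <- c(weights$w1, weights$w2, weights$w3, -weights$w4)
    co_rhs <- function(t, lam, uu) {
      x <- vapply(interp, function(f) f(t), numeric(1))
      -(g + drop(crossprod(therapy_jacobian(x, t, params, dose = uf(t)),
                           lam)))
    }
    solve_classical(co_rhs, rep(0, 4), 0, horizon, h, backward = TRUE,
                    name = "costate")$states
  }

  log <- data.frame(iter = integer(), J = numeric(),
                    relaxation = numeric(), accepted = logical())
  converged <- FALSE
  lam <- backward(sol, u)
  for (it in seq_len(max_iter)) {
    st <- sol$states
    th <- heaviside_delay(times, params$tau)
    sw <- th * (lam[, 3] * (-params$eps1 * st[, 1] * st[, 3] -
                              params$eps2 * st[, 2] * st[, 3]) +
                  lam[, 4] * params$eps3 * st[, 3])
    u_star <- ifelse(sw < 0, u_max, 0)
    r <- relaxation
    accepted <- FALSE
    for (bt in seq_len(max_backtracks)) {
      u_try <- (1 - r) * u + r * u_star
      sol_try <- forward(u_try)
      J_try <- objective_value(sol_try, weights)
      if (J_try <= J + 1e-12 * max(1, abs(J))) {
        accepted <- TRUE
        break
      }
      r <- r / 2
    }
    log <- rbind(log, data.frame(iter = it, J = if (accepted) J_try else J,
                                 relaxation = r, accepted = accepted))
    if (!accepted) break                    # no descent direction left
    du <- max(abs(u_try - u))
    u <- u_try; sol <- sol_try; J <- J_try
    lam <- backward(sol, u)
    if (du <= tol) { converged <- TRUE; break }
  }

  structure(list(state = sol, costates = lam, control = u, J = J,
                 iterations = log, converged = converged,
                 transversality_residual = max(abs(lam[nrow(lam), ]))),
            class = "control_solution")
}

#' @export
print.control_solution <- function(x, ...) {
  cat(sprintf(
    "control solution: J = %.6g after %d sweep iteration(s) (%s)\n",
    x$J, nrow(x$iterations),
    if (x$converged) "converged" else "stopped"))
  cat(sprintf("  control range [%.3g, %.3g], transversality residual %.2e\n",
              min(x$control), max(x$control), x$transversality_residual))
  invisible(x)
}

#' Closed-loop PID dosage scheduling
#'
#' Implements the cyclic dosing procedure: simulate the feedback-controlled
#' therapy model over the treatment horizon at the current constant dosage,
#' read off the end-of-horizon tumor burden `N(t_f)`, form the error, and
#' let a PID law choose the next cycle's dosage, until the error is within
#' the tolerance band or the cycle budget is spent.
#'
#' Sign convention: the error driving the controller is the tumor excess
#' `e = N(t_f) - N_target`, so that positive gains map a burden above
#' target to a *larger* dosage (dose kills tumor cells; with the
#' target-minus-actual convention, positive gains would push the dosage the
#' wrong way). The dosage is the initial dosage plus the PID adjustment,
#' clamped to `[0, u_max]` - with all gains zero the dosage therefore stays
#' at its initial value. While clamped, the integral term is frozen
#' (anti-windup), otherwise sustained error would wind the integral far
#' beyond the saturation.
#'
#' The per-cycle simulation uses the integer-order (`alpha = 1`) feedback
#' dynamics, solved with the fixed-step classical solver.
#'
#' @param params a [therapy_params()] object.
#' @param init initial state `c(N, I, P, T)`.
#' @param gains a [pid_gains()] object (carries target, tolerance, cycle
#'   budget, dosage clamp and initial dosage).
#' @param horizon treatment period per cycle (days).
#' @param h simulation step (default `2^-8`).
#' @return object of class `dosing_history`: data.frame `cycles` with one
#'   row per cycle (`cycle`, `dose`, `N_end`, `error`, `P_term`, `I_term`,
#'   `D_term`, `clamped`), plus `termination` (`"converged"`,
#'   `"max_cycles"` or `"simulation_failure"`) and `final_dose`.
#' @export
feedback_dosing_loop <- function(params, init, gains, horizon = 30,
                                 h = 2^-8) {
  stopifnot(inherits(params, "therapy_params"), inherits(gains, "pid_gains"))
  rhs_u <- make_rhs(params, "feedback", use_input = TRUE)
  simulate <- function(dose) {
    sol <- solve_classical(rhs_u, init, 0, horizon, h,
                           input = rep(dose, round(horizon / h) + 1L),
                           name = "feedback")
    sol$states[nrow(sol$states), 1]
  }
  u <- gains$u_init
  int_acc <- 0           # trapezoid accumulator over accepted cycle errors
  e_prev <- NA_real_
  rows <- list()
  termination <- "max_cycles"
  for (cyc in seq_len(gains$max_cycles)) {
    N_end <- tryCatch(simulate(u), error = function(e) NA_real_)
    if (!is.finite(N_end)) { termination <- "simulation_failure"; break }
    e <- N_end - gains$N_target
    P_term <- gains$Kp * e
    int_try <- if (is.na(e_prev)) int_acc else int_acc + (e_prev + e) / 2
    D_term <- if (is.na(e_prev)) 0 else gains$Kd * (e - e_prev)
    u_raw <- gains$u_init + P_term + gains$Ki * int_try + D_term
    clamped <- u_raw < 0 || u_raw > gains$u_max
    if (!clamped) int_acc <- int_try        # anti-windup: freeze if clamped
    u_next <- min(max(u_raw, 0), gains$u_max)
    rows[[cyc]] <- data.frame(cycle = cyc, dose = u, N_end = N_end,
                              error = e, P_term = P_term,
                              I_term = gains$Ki * int_try, D_term = D_term,
                              clamped = clamped)
    if (abs(e) <= gains$tolerance) { termination <- "converged"; break }
    e_prev <- e
    u <- u_next
  }
  structure(list(cycles = do.call(rbind, rows), termination = termination,
                 final_dose = u),
            class = "dosing_history")
}

#' @export
print.dosing_history <- function(x, ...) {
  n <- nrow(x$cycles)
  cat(sprintf("dosing history: %d cycle(s), termination = %s\n",
              n, x$termination))
  if (n > 0)
    cat(sprintf("  last cycle: dose = %.4g, N_end = %.6g, error = %.4g\n",
                x$cycles$dose[n], x$cycles$N_end[n], x$cycles$error[n]))
  invisible(x)
}

#' Expand sweep costates to the ten-adjoint layout
#'
#' The therapy sweep produces four costates (one per state). The auxiliary
#' wound-healing and growth-factor integrals are written against a
#' ten-adjoint layout in which the state adjoints occupy positions 1 (N),
#' 2 (I), 4 (P) and 10 (T) and the remaining positions belong to auxiliary
#' adjoints that are identically zero under the textbook conditions (their
#' equations are homogeneous with zero terminal data). This helper places
#' the four computed costates accordingly and zero-fills the rest.
#'
#' @param solution a `control_solution` from [forward_backward_sweep()].
#' @return matrix with 10 columns `psi1...psi10`, one row per grid node.
#' @export
costates_to_psi <- function(solution) {
  lam <- solution$costates
  psi <- matrix(0, nrow(lam), 10,
                dimnames = list(NULL, paste0("psi", 1:10)))
  psi[, 1] <- lam[, 1]; psi[, 2] <- lam[, 2]
  psi[, 4] <- lam[, 3]; psi[, 10] <- lam[, 4]
  psi
}

#' Auxiliary wound-healing and angiogenesis trajectories
#'
#' Quadrature of the auxiliary adjoint integrals on the sweep grid:
#' `W(t) = W0 + integral of (psi10 - eps3 psi6)` (wound-healing cells) and
#' `V(t) = V0 + integral of (phi1 psi2 + phi2 psi5 + phi3 psi2 +
#' phi4 psi7 - eps1 psi9)` (vascular endothelial growth factor), with the
#' control-auxiliary growth-factor set `phi1'...phi4'` and composite
#' trapezoid on the grid. (The `phi1 psi2` and `phi3 psi2` terms both
#' multiply `psi2`, as printed in the source formulation; see the
#' vignette's notes on formulation quirks.)
#'
#' @param psi ten-column adjoint matrix (see [costates_to_psi()]).
#' @param times grid times matching `psi` rows.
#' @param phis named vector with at least `phi1...phi4` (the
#'   control-auxiliary set, e.g. `load_preset("lung-ref")$phi_control`).
#' @param eps1,eps3 therapy efficacies entering the integrands.
#' @param W0,V0 initial values (reference preset: 100 and 50).
#' @return data.frame with columns `t`, `W`, `V`.
#' @export
auxiliary_WV <- function(psi, times, phis, eps1, eps3, W0 = 100, V0 = 50) {
  stopifnot(ncol(psi) == 10L, nrow(psi) == length(times))
  dW <- psi[, 10] - eps3 * psi[, 6]
  dV <- phis[["phi1"]] * psi[, 2] + phis[["phi2"]] * psi[, 5] +
    phis[["phi3"]] * psi[, 2] + phis[["phi4"]] * psi[, 7] -
    eps1 * psi[, 9]
  data.frame(t = times,
             W = W0 + c(0, pracma::cumtrapz(times, dW)[-1]),
             V = V0 + c(0, pracma::cumtrapz(times, dV)[-1]))
}
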