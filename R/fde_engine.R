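#' Define a Caputo fractional initial-value problem
#'
#' Bundles everything the Adams-Bashforth-Moulton solver needs: the order
#' `alpha` of the Caputo derivative, a right-hand side, an initial state and
#' a uniform time grid. The right-hand side must be a pure function
#' `f(t, y, u)` returning a derivative vector of the same length as `y`;
#' `u` is an optional exogenous scalar input (e.g. a dosage signal) and may
#' be ignored by autonomous models.
#'
#' If `t_final - t0` is not an integer multiple of `h`, `t_final` is snapped
#' to the nearest multiple with a warning, so the grid stays uniform.
#'
#' @param rhs function `f(t, y, u)` returning `numeric(length(y))`.
#' @param y0 numeric initial state at `t0`.
#' @param t0,t_final start and end time (same unit as the model rates, days
#'   for the tumor models).
#' @param h uniform step size, `h > 0`.
#' @param alpha Caputo order, `0 < alpha <= 1`. All components share one
#'   order.
#' @param name optional identifier stored in solution metadata.
#' @return an object of class `fde_problem`.
#' @seealso [solve_fde()]
#' @export
fde_problem <- function(rhs, y0, t0 = 0, t_final = 1, h = 2^-6,
                        alpha = 1, name = "rhs") {
  stopifnot(is.function(rhs), is.numeric(y0), length(y0) >= 1L,
            is.numeric(h), length(h) == 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  if (t_final <= t0) stop("`t_final` must exceed `t0`", call. = FALSE)
  n <- round((t_final - t0) / h)
  if (n < 1L) stop("grid has no steps: increase `t_final` or reduce `h`",
                   call. = FALSE)
  snapped <- t0 + n * h
  if (abs(snapped - t_final) > 1e-12 * max(1, abs(t_final))) {
    warning(sprintf("t_final = %g is not a multiple of h; snapped to %g",
                    t_final, snapped), call. = FALSE)
  }
  f0 <- rhs(t0, y0, 0)
  if (length(f0) != length(y0))
    stop("rhs output dimension differs from length(y0)", call. = FALSE)
  if (!all(is.finite(f0)))
    stop("rhs is not finite at the initial state", call. = FALSE)
  structure(list(rhs = rhs,
                 y0 = stats::setNames(as.numeric(y0), names(y0)), t0 = t0,
                 t_final = snapped, h = h, alpha = alpha,
                 n_steps = as.integer(n), name = name),
            class = "fde_problem")
}

#' @export
print.fde_problem <- function(x, ...) {
  cat(sprintf(
    "Caputo initial-value problem '%s': alpha = %g, dim = %d,\n  grid [%g, %g] with h = %g (%d steps)\n",
    x$name, x$alpha, length(x$y0), x$t0, x$t_final, x$h, x$n_steps))
  invisible(x)
}

#' Fractional Adams quadrature weights
#'
#' Product-integration weights of the fractional Adams-Bashforth (predictor)
#' and Adams-Moulton (corrector) rules for the step from `t_n` to `t_{n+1}`
#' on a uniform grid. The predictor weights are
#' `b_j = (h^alpha / alpha) * ((n+1-j)^alpha - (n-j)^alpha)` for
#' `j = 0, ..., n` (rectangle-type rule on the power-law kernel); the
#' corrector weights come from piecewise-linear product integration and
#' carry the factor `h^alpha / (alpha * (alpha + 1))`. Both sets are
#' returned *without* the `1/Gamma(alpha)` normalisation, which the solver
#' applies once per step; with it, the scales become `h^alpha/Gamma(alpha+1)`
#' and `h^alpha/Gamma(alpha+2)`.
#'
#' At `alpha = 1` the predictor weights all equal `h` (rectangle rule) and
#' the corrector reduces to the trapezoidal rule (`h/2` at the endpoints).
#'
#' @param alpha Caputo order in (0, 1].
#' @param n step index, `n >= 0`: weights for computing the state at
#'   `t_{n+1}` from history at `t_0, ..., t_n`.
#' @param h step size, `h > 0`.
#' @return list with `predictor` (length `n + 1`) and `corrector`
#'   (length `n + 2`; the last entry multiplies the predicted slope at
#'   `t_{n+1}`). All weights are nonnegative.
#' @export
abm_weights <- function(alpha, n, h) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  if (n < 0) stop("`n` must be nonnegative", call. = FALSE)
  n <- as.integer(n)
  j <- 0:n
  b <- (h^alpha / alpha) * ((n + 1 - j)^alpha - (n - j)^alpha)
  c0 <- n^(alpha + 1) - (n - alpha) * (n + 1)^alpha
  ci <- if (n >= 1L) {
    jj <- 1:n
    (n - jj + 2)^(alpha + 1) + (n - jj)^(alpha + 1) -
      2 * (n - jj + 1)^(alpha + 1)
  } else numeric(0)
  a <- (h^alpha / (alpha * (alpha + 1))) * c(c0, ci, 1)
  list(predictor = b, corrector = a)
}

#' Solve a Caputo fractional initial-value problem
#'
#' Full-memory Adams-Bashforth-Moulton predictor-corrector (the scheme
#' behind MATLAB's FDE12): each step predicts with the fractional
#' Adams-Bashforth rule over the entire history, then applies the fractional
#' Adams-Moulton corrector. One corrector evaluation per step is the
#' default; additional corrector iterations re-evaluate the slope at the
#' corrected state. The scheme is explicit, so stiff right-hand sides
#' require `h` small enough that `h * L <~ 2` for the fastest local decay
#' rate `L`; outside that region the iteration diverges and the solver
#' aborts at the first non-finite state, reporting the step index and state.
#'
#' The memory term is the exact discrete convolution over all past slopes
#' (cost quadratic in the number of steps). A short-memory window is
#' available through `memory` for experimentation but is *off* by default,
#' because truncation changes the solution for `alpha < 1`.
#'
#' @param problem an [fde_problem()].
#' @param input optional exogenous input: a function `u(t)` or a numeric
#'   vector on the grid (length `n_steps + 1`). Sampled at grid nodes and
#'   held constant within each step. `NULL` feeds `u = 0`.
#' @param corrector_iters number of corrector iterations per step
#'   (default 1, the FDE12 convention).
#' @param memory number of most recent steps retained in the convolution;
#'   `Inf` (default) keeps the full history.
#' @return object of class `fde_solution`: list with `times` (uniform grid),
#'   `states` (matrix, one row per node, first row is the initial state),
#'   `input` (sampled input or NULL), and `metadata` (`alpha`, `h`, rhs
#'   identifier, corrector iterations, memory window). If any state
#'   component goes negative the first crossing is recorded in
#'   `metadata$first_negative` and signalled as a warning; states are never
#'   clipped.
#' @examples
#' pr <- fde_problem(function(t, y, u) -y, 1, 0, 1, h = 2^-6, alpha = 0.7)
#' sol <- solve_fde(pr)
#' tail(sol$states, 1)  # close to mittag_leffler(0.7, -1)
#' @export
solve_fde <- function(problem, input = NULL, corrector_iters = 1L,
                      memory = Inf) {
  stopifnot(inherits(problem, "fde_problem"))
  alpha <- problem$alpha
  h <- problem$h
  n_steps <- problem$n_steps
  rhs <- problem$rhs
  d <- length(problem$y0)
  times <- problem$t0 + h * (0:n_steps)
  u <- if (is.null(input)) {
    NULL
  } else if (is.function(input)) {
    vapply(times, input, numeric(1))
  } else {
    if (length(input) != n_steps + 1L)
      stop("numeric `input` must have one value per grid node", call. = FALSE)
    as.numeric(input)
  }
  uval <- function(i) if (is.null(u)) 0 else u[i]

  ga1 <- gamma(alpha + 1)
  ga2 <- gamma(alpha + 2)
  m <- 0:(n_steps + 1)
  pow_a <- m^alpha
  pow_a1 <- m^(alpha + 1)
  dpa <- diff(pow_a)                        # k^a - (k-1)^a, k = 1, ...
  # interior corrector kernel indexed by (n - j): (m+1)^(a+1)+(m-1)^(a+1)-2m^(a+1)
  dker <- if (n_steps >= 1L)
    pow_a1[3:(n_steps + 2)] + pow_a1[1:n_steps] - 2 * pow_a1[2:(n_steps + 1)]
  else numeric(0)

  y <- matrix(NA_real_, n_steps + 1L, d)
  fhist <- matrix(0, n_steps + 1L, d)
  y[1, ] <- problem$y0
  fhist[1, ] <- rhs(times[1], problem$y0, uval(1L))
  first_neg <- NULL
  watch_neg <- problem$y0 >= 0   # only flag components that start nonnegative
  hp_a1 <- h^alpha / ga1
  hp_a2 <- h^alpha / ga2

  for (k in seq_len(n_steps)) {
    n <- k - 1L                              # history 0..n known
    j0 <- if (is.finite(memory)) max(0L, n - as.integer(memory)) else 0L
    idx <- (j0 + 1L):(n + 1L)                # rows of history used
    bw <- dpa[(n + 1L - j0):1]               # predictor weights / (h^a/a)
    yp <- problem$y0 + hp_a1 * drop(crossprod(fhist[idx, , drop = FALSE], bw))
    cw <- c(pow_a1[n + 1L] - (n - alpha) * pow_a[n + 2L],
            if (n >= 1L) dker[n:1])
    if (j0 > 0L) cw <- cw[-seq_len(j0)] # window drops oldest corrector terms
    conv <- drop(crossprod(fhist[idx, , drop = FALSE], cw))
    fp <- rhs(times[k + 1L], yp, uval(k + 1L))
    yn <- problem$y0 + hp_a2 * (conv + fp)
    if (corrector_iters > 1L) {
      for (it in seq_len(corrector_iters - 1L)) {
        fp <- rhs(times[k + 1L], yn, uval(k + 1L))
        yn <- problem$y0 + hp_a2 * (conv + fp)
      }
    }
    if (!all(is.finite(yn))) {
      stop(structure(class = c("fde_nonfinite", "error", "condition"),
                     list(message = sprintf(
                       "non-finite state at step %d (t = %g); last finite state: %s",
                       k, times[k + 1L],
                       paste(signif(y[k, ], 6), collapse = ", ")),
                       call = NULL, step = k, time = times[k + 1L],
                       state = y[k, ])))
    }
    y[k + 1L, ] <- yn
    fhist[k + 1L, ] <- rhs(times[k + 1L], yn, uval(k + 1L))
    if (is.null(first_neg) && any(yn < 0 & watch_neg)) {
      first_neg <- list(step = k, time = times[k + 1L],
                        component = which(yn < 0 & watch_neg)[1])
    }
  }

  if (!is.null(first_neg))
    warning(sprintf(
      "state component %d first crossed zero at t = %g (step %d); not clipped",
      first_neg$component, first_neg$time, first_neg$step), call. = FALSE)
  nm <- names(problem$y0)
  colnames(y) <- if (!is.null(nm)) nm else paste0("y", seq_len(d))
  structure(list(times = times, states = y, input = u,
                 metadata = list(alpha = alpha, h = h, rhs = problem$name,
                                 corrector_iters = as.integer(corrector_iters),
                                 memory = memory,
                                 first_negative = first_neg)),
            class = "fde_solution")
}

#' @export
print.fde_solution <- function(x, ...) {
  cat(sprintf("fde_solution '%s': alpha = %g, h = %g, %d nodes on [%g, %g]\n",
              x$metadata$rhs, x$metadata$alpha, x$metadata$h,
              length(x$times), x$times[1], x$times[length(x$times)]))
  cat("final state:", paste(signif(x$states[nrow(x$states), ], 6),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.fde_solution <- function(x, ...) {
  df <- data.frame(t = x$times, x$states, check.names = FALSE)
  if (!is.null(x$input)) df$u <- x$input
  df
}

#' Classical fourth-order Runge-Kutta companion solver
#'
#' Fixed-step RK4 for the ordinary (`alpha = 1`) limit of the same
#' right-hand-side contract `f(t, y, u)`. The control layer uses it for the
#' forward and backward sweeps and for the dosing loop, where the dynamics
#' are integer-order; it agrees with `solve_fde(alpha = 1)` to the schemes'
#' discretisation error. The exogenous input is sampled at grid nodes and
#' held constant across each step, matching the fractional solver.
#'
#' @inheritParams solve_fde
#' @param rhs function `f(t, y, u)`.
#' @param y0 initial state.
#' @param t0,t_final,h uniform grid specification; `t_final` snapped as in
#'   [fde_problem()].
#' @param backward logical; if `TRUE`, integrates from `t_final` down to
#'   `t0` (initial condition given at `t_final`), as needed for costate
#'   equations. The returned grid is always increasing.
#' @return an `fde_solution` with `metadata$alpha = 1` and
#'   `metadata$scheme = "rk4"`.
#' @export
solve_classical <- function(rhs, y0, t0, t_final, h, input = NULL,
                            backward = FALSE, name = "rhs") {
  n_steps <- round((t_final - t0) / h)
  if (n_steps < 1L) stop("empty grid", call. = FALSE)
  times <- t0 + h * (0:n_steps)
  u <- if (is.null(input)) NULL
       else if (is.function(input)) vapply(times, input, numeric(1))
       else { stopifnot(length(input) == n_steps + 1L); as.numeric(input) }
  uval <- function(i) if (is.null(u)) 0 else u[i]
  d <- length(y0)
  y <- matrix(NA_real_, n_steps + 1L, d)
  ord <- if (backward) rev(seq_len(n_steps + 1L)) else seq_len(n_steps + 1L)
  hh <- if (backward) -h else h
  y[ord[1], ] <- as.numeric(y0)
  for (k in seq_len(n_steps)) {
    i0 <- ord[k]; i1 <- ord[k + 1L]
    tt <- times[i0]; yy <- y[i0, ]; uu <- uval(i0)
    k1 <- rhs(tt, yy, uu)
    k2 <- rhs(tt + hh / 2, yy + hh / 2 * k1, uu)
    k3 <- rhs(tt + hh / 2, yy + hh / 2 * k2, uu)
    k4 <- rhs(tt + hh, yy + hh * k3, uu)
    yn <- yy + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(yn)))
      stop(sprintf("non-finite state at t = %g in RK4", times[i1]),
           call. = FALSE)
    y[i1, ] <- yn
  }
  nm <- names(y0)
  colnames(y) <- if (!is.null(nm)) nm else paste0("y", seq_len(d))
  structure(list(times = times, states = y, input = u,
                 metadata = list(alpha = 1, h = h, rhs = name,
                                 scheme = "rk4", backward = backward)),
            class = "fde_solution")
}

#' Mittag-Leffler function of one parameter
#'
#' Evaluates `E_alpha(z) = sum_k z^k / Gamma(alpha k + 1)`, the solution
#' kernel of linear Caputo equations (`D^alpha y = lambda y` has solution
#' `y0 * E_alpha(lambda t^alpha)`), used as the verification oracle for the
#' fractional solver. The power series is summed with term-ratio stopping;
#' for strongly negative arguments (`z < -10`, where the series cancels
#' catastrophically in double precision) the algebraic asymptotic expansion
#' `-sum_{k>=1} z^-k / Gamma(1 - alpha k)` is used instead (valid for
#' `0 < alpha < 1`).
#'
#' For alternating (negative) arguments the series cancels: the largest
#' term has magnitude about `exp(|z|^(1/alpha))`, so in double precision
#' the summed value carries an absolute error of roughly that magnitude
#' times machine epsilon. The implementation therefore uses the series only
#' while `|z|^(1/alpha) <= 18` (where the error stays below ~1e-8, and
#' below 1e-10 for `|z|^(1/alpha) <= 13`, which covers the solver-oracle
#' range `z` in `[-1, 0]` with lots of room) and switches to the
#' asymptotic branch beyond, whose optimally truncated error is of order
#' `exp(-|z|^(1/alpha))`; near the crossover either branch is accurate to
#' about 1e-7 absolute, far better elsewhere. The classical special cases `alpha = 1`
#' (`exp(z)`) and `alpha = 2` (`cosh(sqrt(z))` / `cos(sqrt(-z))`) are
#' evaluated exactly.
#'
#' @param alpha order, `alpha > 0`.
#' @param z real argument (vectorised).
#' @param tol absolute series tolerance (default 1e-12; see the accuracy
#'   discussion above).
#' @param max_terms safeguard on the number of series terms.
#' @return numeric vector of `E_alpha(z)` values.
#' @examples
#' mittag_leffler(1, -1)    # exp(-1)
#' mittag_leffler(2, -1)    # cos(1)
#' @export
mittag_leffler <- function(alpha, z, tol = 1e-12, max_terms = 1000L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be positive", call. = FALSE)
  vapply(z, function(zz) {
    if (zz == 0) return(1)
    if (alpha == 1) return(exp(zz))
    if (alpha == 2) return(if (zz >= 0) cosh(sqrt(zz)) else cos(sqrt(-zz)))
    series_ok <- zz > 0 || abs(zz)^(1 / alpha) <= 18
    if (series_ok) {
      term <- 1; s <- 1
      for (k in seq_len(max_terms)) {
        lg <- k * log(abs(zz)) - lgamma(alpha * k + 1)
        if (lg > 700) stop("Mittag-Leffler overflow for this argument",
                           call. = FALSE)
        term <- sign(zz)^k * exp(lg)
        s <- s + term
        # stop once the tail is provably below tol: terms eventually decay
        # faster than geometrically
        if (abs(term) < tol && lg < log(tol)) return(s)
      }
      stop("Mittag-Leffler series did not converge within max_terms",
           call. = FALSE)
    }
    if (alpha >= 1)
      stop("argument out of the supported range for alpha >= 1", call. = FALSE)
    # asymptotic expansion for z -> -Inf, truncated where the smooth term
    # envelope |z|^-k Gamma(alpha k)/pi is smallest (the reflection sine
    # modulates individual magnitudes, so the envelope - not the raw
    # |term| sequence - identifies the optimal truncation); terms at poles
    # of Gamma(1 - alpha k) vanish.
    ks <- 1:150
    env <- -ks * log(abs(zz)) + lgamma(alpha * ks)
    k_star <- which.min(env)
    s <- 0
    for (k in seq_len(k_star)) {
      x <- alpha * k                      # 1/Gamma(1-x) = Gamma(x) sin(pi x)/pi
      sine <- sin(pi * x)
      if (abs(sine) < 1e-14) next
      lt <- -k * log(abs(zz)) + lgamma(x) + log(abs(sine) / pi)
      s <- s + -(-1)^k * sign(sine) * exp(lt)   # -z^(-k)/Gamma(1-x), z < 0
    }
    s
  }, numeric(1))
}
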