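# --- parameter access helpers shared by the sensitivity operations -------

param_get <- function(params, name) {
  if (inherits(params, "kmodel_params")) {
    if (name == "alpha") return(params$alpha)
    if (name %in% names(params$k)) return(unname(params$k[name]))
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  }
  if (is.list(params) && name %in% names(params)) return(params[[name]])
  stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
}

param_set <- function(params, name, value) {
  if (inherits(params, "kmodel_params")) {
    if (name == "alpha") params$alpha <- value
    else params$k[name] <- value
    return(params)
  }
  params[[name]] <- value
  params
}

# finite-difference Jacobian of a vector function (used by the Newton polish)
fd_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, length(f(x)), n)
  for (i in seq_len(n)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Steady state of the six-compartment stem-cell model
#'
#' Solves `kmodel_rhs = 0`. Two branches are meaningful:
#'
#' * `"interior"` (default): supporting cells persist, which pins the stem
#'   cells at `C = k7/k8`; the stem-cell balance then gives
#'   `S = (k1 - k2)/k3` with `E = 0`, and the linear compartments follow as
#'   `Pk = k5 C / k6`, `Nk = k11/k12` (exact by construction) and
#'   `Ik = k13 Pk / k14`.
#' * `"extinct"`: the stem-cell-free branch `C = Pk = S = E = Ik = 0`,
#'   `Nk = k11/k12`.
#'
#' The closed-form candidate is polished by Newton iteration with a
#' finite-difference Jacobian and returned only if the residual max-norm is
#' at most `1e-8`; otherwise an error names the offending balance.
#'
#' @param params a [kmodel_params()] object (needs `k12 > 0`, `k14 > 0`,
#'   and for the interior branch `k3, k6, k8 > 0`).
#' @param branch `"interior"` or `"extinct"`.
#' @return named numeric steady state `c(C, Pk, S, E, Nk, Ik)` with
#'   attribute `residual`.
#' @export
kmodel_steady_state <- function(params, branch = c("interior", "extinct")) {
  branch <- match.arg(branch)
  k <- params$k
  if (k["k12"] <= 0 || k["k14"] <= 0)
    stop("steady state needs k12 > 0 and k14 > 0", call. = FALSE)
  x0 <- if (branch == "interior") {
    if (k["k8"] <= 0 || k["k3"] <= 0 || k["k6"] <= 0)
      stop("interior branch needs k3, k6, k8 > 0", call. = FALSE)
    C <- k[["k7"]] / k[["k8"]]
    S <- (k[["k1"]] - k[["k2"]]) / k[["k3"]]
    Pk <- k[["k5"]] * C / k[["k6"]]
    c(C, Pk, S, 0, k[["k11"]] / k[["k12"]], k[["k13"]] * Pk / k[["k14"]])
  } else {
    c(0, 0, 0, 0, k[["k11"]] / k[["k12"]], 0)
  }
  f <- function(x) kmodel_rhs(x, params)
  x <- x0
  for (i in 1:30) {
    r <- f(x)
    if (max(abs(r)) < 1e-12) break
    J <- fd_jacobian(f, x)
    step <- tryCatch(solve(J, r), error = function(e) rep(0, length(x)))
    if (!all(is.finite(step)) || max(abs(step)) < 1e-14) break
    x <- x - step
  }
  res <- abs(f(x))
  if (max(res) > 1e-8) {
    nm <- c("stem-cell balance", "progenitor balance", "support balance",
            "effector balance", "normal-cell balance", "immune balance")
    stop(sprintf("steady state did not converge: %s residual %.3g",
                 nm[which.max(res)], max(res)), call. = FALSE)
  }
  structure(stats::setNames(x, c("C", "Pk", "S", "E", "Nk", "Ik")),
            residual = max(res))
}

#' Normalized sensitivity coefficient of a scalar functional
#'
#' Computes the elasticity `S = d ln f / d ln theta` - the percent change
#' of the output per percent change of the parameter - by finite
#' differences with perturbation `epsilon = rel_step * theta`
#' (`rel_step = 0.01` by default). The default `"central"` mode differences
#' in log space, `(ln f(theta+e) - ln f(theta-e)) / (ln(theta+e) -
#' ln(theta-e))`, which is the elasticity's native quotient and is *exact*
#' for power-law dependences such as `Nk = k11/k12` (a plain quotient of
#' `f` would carry an `O(rel_step^2)` curvature bias even there); when the
#' two perturbed values differ in sign the raw quotient
#' `(df/dtheta) (theta/f)` is used instead. `mode = "forward"` is the
#' literal one-sided quotient `(f(theta+e) - f(theta)) / e * theta / f`.
#' When the central estimate is requested, the forward estimate is also
#' computed and attached whenever the two differ by more than `1e-3`, as a
#' convergence diagnostic.
#'
#' @param functional function of the parameter container returning a finite
#'   scalar (e.g. `function(p) kmodel_steady_state(p)[["Nk"]]`).
#' @param param_name parameter name (e.g. `"k11"`, `"lam"`).
#' @param params a parameter container ([base_params()],
#'   [kmodel_params()], or a plain named list).
#' @param mode `"central"` (default) or `"forward"`.
#' @param rel_step relative perturbation (default 0.01).
#' @return object of class `sensitivity_record`: list with `parameter`,
#'   `coefficient`, `method`, `epsilon`, `functional`, `value` (the
#'   unperturbed output) and optionally `alternative` (the other
#'   difference-quotient estimate).
#' @export
normalized_sensitivity <- function(functional, param_name, params,
                                   mode = c("central", "forward"),
                                   rel_step = 0.01) {
  mode <- match.arg(mode)
  theta <- param_get(params, param_name)
  if (!is.finite(theta) || theta == 0)
    stop("parameter value must be nonzero for a relative perturbation",
         call. = FALSE)
  eps <- rel_step * theta
  f0 <- functional(params)
  if (!is.finite(f0)) stop("functional not finite at the nominal parameters",
                           call. = FALSE)
  if (f0 == 0) stop("functional is zero: normalized sensitivity undefined",
                    call. = FALSE)
  fp <- functional(param_set(params, param_name, theta + eps))
  fm <- functional(param_set(params, param_name, theta - eps))
  central <- if (is.finite(fp) && is.finite(fm) && fp * fm > 0) {
    (log(abs(fp)) - log(abs(fm))) / (log(abs(theta + eps)) -
                                       log(abs(theta - eps)))
  } else if (fp == fm) 0 else (fp - fm) / (2 * eps) * theta / f0
  forward <- (fp - f0) / eps * theta / f0
  coef <- if (mode == "central") central else forward
  rec <- list(parameter = param_name, coefficient = coef, method = mode,
              epsilon = eps, value = f0,
              functional = deparse1(substitute(functional)))
  if (mode == "central" && is.finite(forward) &&
      abs(central - forward) > 1e-3)
    rec$alternative <- c(forward = forward)
  structure(rec, class = "sensitivity_record")
}

#' @export
print.sensitivity_record <- function(x, ...) {
  cat(sprintf("S(%s) = %.6g  [%s, epsilon = %.3g]\n",
              x$parameter, x$coefficient, x$method, x$epsilon))
  if (!is.null(x$alternative))
    cat(sprintf("  forward-difference estimate: %.6g\n", x$alternative))
  invisible(x)
}

#' Trajectory sensitivity by finite differences
#'
#' Derivative of one state component at time `t_eval` with respect to a
#' model parameter, obtained from two (or three, for central differences)
#' [solve_fde()] runs on identical grids at the perturbed parameter values.
#' Normalized (elasticity) or raw derivative per `normalized`.
#'
#' @param params parameter container ([base_params()], [therapy_params()]
#'   or [kmodel_params()]).
#' @param variant model variant passed to [make_rhs()].
#' @param param_name parameter to perturb (may also be `"alpha"` or an
#'   initial-condition name present in `init`).
#' @param component index or name of the state component to read out.
#' @param t_eval evaluation time (snapped to the grid node at or below).
#' @param init initial state vector.
#' @param t0,h grid specification; the grid covers `[t0, t_eval]`.
#' @param rel_step relative perturbation (default 0.01).
#' @param normalized if `TRUE` (default) return the elasticity, else the
#'   raw derivative.
#' @return a `sensitivity_record`.
#' @export
trajectory_sensitivity <- function(params, variant, param_name, component,
                                   t_eval, init, t0 = 0, h = 2^-6,
                                   rel_step = 0.01, normalized = TRUE) {
  run <- function(p, ic) {
    alpha <- if (inherits(p, "kmodel_params")) p$alpha else p$alpha
    pr <- fde_problem(make_rhs(p, variant), ic, t0 = t0, t_final = t_eval,
                      h = h, alpha = alpha, name = variant)
    sol <- solve_fde(pr)
    unname(sol$states[nrow(sol$states), component])
  }
  is_ic <- param_name %in% names(init)
  theta <- if (is_ic) init[[param_name]] else param_get(params, param_name)
  if (theta == 0)
    stop("parameter value must be nonzero for a relative perturbation",
         call. = FALSE)
  eps <- rel_step * theta
  perturb <- function(v) {
    if (is_ic) { ic <- init; ic[[param_name]] <- v; run(params, ic) }
    else run(param_set(params, param_name, v), init)
  }
  f0 <- perturb(theta)
  fp <- perturb(theta + eps)
  fm <- perturb(theta - eps)
  deriv <- (fp - fm) / (2 * eps)
  coef <- if (normalized) {
    if (f0 == 0) stop("state is zero at t_eval: elasticity undefined",
                      call. = FALSE)
    deriv * theta / f0
  } else deriv
  structure(list(parameter = param_name, coefficient = coef,
                 method = "central", epsilon = eps, value = f0,
                 functional = sprintf("%s[%s] at t = %g", variant,
                                      as.character(component), t_eval),
                 normalized = normalized),
            class = "sensitivity_record")
}

#' Steady-state sensitivity table for the stem-cell model
#'
#' Elasticities of a steady-state component with respect to every rate
#' `k1...k14`, mirroring the layout of the published coefficient table.
#' For the normal-cell compartment the closed form `Nk = k11/k12` makes the
#' exact pattern `+1` (k11), `-1` (k12), `0` (all others); the
#' finite-difference path reproduces it and serves as a self-check.
#'
#' @param params a [kmodel_params()] object.
#' @param component steady-state component (default `"Nk"`).
#' @param mode difference mode, see [normalized_sensitivity()].
#' @return data.frame with columns `parameter`, `coefficient`.
#' @export
sensitivity_table <- function(params, component = "Nk",
                              mode = c("central", "forward")) {
  mode <- match.arg(mode)
  f <- function(p) kmodel_steady_state(p)[[component]]
  rows <- lapply(paste0("k", 1:14), function(nm) {
    s <- tryCatch(
      normalized_sensitivity(f, nm, params, mode = mode)$coefficient,
      error = function(e) NA_real_)
    data.frame(parameter = nm, coefficient = s)
  })
  do.call(rbind, rows)
}

#' Published sensitivity coefficients (display fixture)
#'
#' The coefficient table reported alongside the stem-cell model, shipped
#' verbatim for side-by-side display. It is *not* used as a test oracle:
#' the reported values are internally inconsistent with the model's own
#' closed-form steady state (`Nk = k11/k12` forces `S(k11) = +1`,
#' `S(k12) = -1` and zero for parameters that do not enter, whereas the
#' reported table lists 0 for `k11`/`k12` and nonzero values for `k5` and
#' `k13`).
#'
#' @return data.frame with columns `parameter`, `reported_coefficient`.
#' @export
reference_sensitivities <- function() {
  path <- system.file("extdata", "reported-sensitivities.csv",
                      package = "fractumor", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
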