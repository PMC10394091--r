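#' Analytic Jacobian of the base model
#'
#' Partial derivatives of [base_rhs()] with respect to `(N, I, P)`, e.g.
#' `d(dN)/dN = lam (1 - 2N/K) - mu P - beta1 I`.
#'
#' @param params a [base_params()] object.
#' @param state numeric `c(N, I, P)`.
#' @return 3 x 3 numeric matrix.
#' @export
jacobian_base <- function(params, state) {
  p <- params
  N <- state[1]; I <- state[2]; P <- state[3]
  matrix(c(
    p$lam * (1 - 2 * N / p$K) - p$mu * P - p$beta1 * I, -p$beta1 * N, -p$mu * N,
    2 * p$phi2 * N, -p$phi3 - p$beta2 * P, -p$beta2 * I,
    p$gamma * P, -p$beta3 * P, p$gamma * N - p$delta - p$beta3 * I),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("dN", "dI", "dP"), c("N", "I", "P")))
}

# Newton iteration on base_rhs with the analytic Jacobian; returns the root
# or NULL on failure.
newton_base <- function(params, start, tol = 1e-11, max_iter = 60L) {
  x <- as.numeric(start)
  for (i in seq_len(max_iter)) {
    f <- base_rhs(x, params)
    if (max(abs(f)) < tol) return(x)
    J <- jacobian_base(params, x)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    x <- x - step
    if (!all(is.finite(x))) return(NULL)
  }
  if (max(abs(base_rhs(x, params))) < tol) x else NULL
}

# Fit the quadratic a*N^2 + b*N + c that a polynomial function of degree <= 2
# takes, by exact interpolation at N = 0, 1, 2.
quad_coeffs <- function(g) {
  g0 <- g(0); g1 <- g(1); g2 <- g(2)
  a <- (g2 - 2 * g1 + g0) / 2
  b <- g1 - g0 - a
  c(a = a, b = b, c = g0)
}

real_quad_roots <- function(co) {
  if (abs(co["a"]) < 1e-300) {
    if (abs(co["b"]) < 1e-300) return(numeric(0))
    return(-co[["c"]] / co[["b"]])
  }
  disc <- co[["b"]]^2 - 4 * co[["a"]] * co[["c"]]
  if (disc < 0) return(numeric(0))
  (-co[["b"]] + c(1, -1) * sqrt(disc)) / (2 * co[["a"]])
}

classify_equilibrium <- function(state, params) {
  N <- state[1]; I <- state[2]; P <- state[3]
  tol <- 1e-6 * max(1, params$K)
  if (abs(N) < tol && abs(P) < tol) return("tumor-free-with-immunity")
  if (abs(N - params$K) < tol && abs(I) < 1e-6 && abs(P) < 1e-6)
    return("disease-free")
  if (N > tol && I > 0 && P > 0) return("positive")
  "other"
}

#' Steady states of the base model
#'
#' Finds equilibria by combining closed-form candidates with seeded
#' multistart Newton iteration:
#'
#' 1. the tumor-free state `(0, phi1 I_baseline / phi3, 0)` (always a root);
#' 2. the metastasis-free branch `P = 0`, `N > 0`, from the quadratic in `N`
#'    obtained by eliminating `I`;
#' 3. the interior branch using the self-consistent reductions
#'    `I = (gamma N - delta) / beta3` and
#'    `P = (lam (1 - N/K) - beta1 I) / mu`, whose substitution into the
#'    immune balance gives a quadratic in `N`;
#' 4. `n_starts` Newton runs from log-uniform random starts on
#'    `[1e-2, K]^3`.
#'
#' Every candidate is polished by Newton iteration and accepted only when
#' the max-norm residual of the right-hand side is at most `1e-8`;
#' duplicates are merged. Whether an interior (all-positive) equilibrium
#' exists depends on the parameters; for the reference preset none exists
#' and the tumor-free state is the only steady state.
#'
#' @param params a [base_params()] object.
#' @param n_starts number of random multistarts (default 24).
#' @param seed RNG seed for the multistart (default 20230801). The global
#'   RNG state is restored on exit.
#' @return list of `equilibrium` objects: each has `state` (named numeric),
#'   `residual` and `kind` (one of `"tumor-free-with-immunity"`,
#'   `"disease-free"`, `"positive"`, `"other"`). Empty list (with a
#'   warning) if nothing converges.
#' @export
find_equilibria <- function(params, n_starts = 24L, seed = 20230801L) {
  p <- params
  cand <- list()
  if (p$phi3 > 0) cand <- c(cand, list(c(0, p$phi1 * p$I_baseline / p$phi3, 0)))
  # P = 0, N != 0: lam(1 - N/K) = beta1 I, I = (phi1 I0 + phi2 N^2)/phi3
  if (p$phi3 > 0 && p$beta1 > 0) {
    g <- function(N) p$lam * (1 - N / p$K) -
      p$beta1 * (p$phi1 * p$I_baseline + p$phi2 * N^2) / p$phi3
    for (N in real_quad_roots(quad_coeffs(g)))
      cand <- c(cand, list(c(N, (p$phi1 * p$I_baseline + p$phi2 * N^2) / p$phi3, 0)))
  }
  # interior branch
  if (p$beta3 > 0 && p$mu > 0) {
    Ifun <- function(N) (p$gamma * N - p$delta) / p$beta3
    Pfun <- function(N) (p$lam * (1 - N / p$K) - p$beta1 * Ifun(N)) / p$mu
    g <- function(N) p$phi1 * p$I_baseline + p$phi2 * N^2 -
      p$phi3 * Ifun(N) - p$beta2 * Ifun(N) * Pfun(N)
    for (N in real_quad_roots(quad_coeffs(g)))
      cand <- c(cand, list(c(N, Ifun(N), Pfun(N))))
  }
  # seeded multistart
  if (n_starts >= 1L) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    starts <- matrix(exp(runif(3 * n_starts, log(1e-2), log(p$K))),
                     ncol = 3)
    for (i in seq_len(n_starts)) cand <- c(cand, list(starts[i, ]))
  }

  roots <- list()
  for (x0 in cand) {
    x <- newton_base(p, x0)
    if (is.null(x)) next
    res <- max(abs(base_rhs(x, p)))
    if (res > 1e-8) next
    dup <- any(vapply(roots, function(r)
      max(abs(r$state - x)) < 1e-6 * max(1, max(abs(x))), logical(1)))
    if (dup) next
    st <- stats::setNames(x, c("N", "I", "P"))
    roots[[length(roots) + 1L]] <-
      structure(list(state = st, residual = res,
                     kind = classify_equilibrium(x, p)),
                class = "equilibrium")
  }
  if (length(roots) == 0L)
    warning("no equilibrium converged to residual <= 1e-8", call. = FALSE)
  roots
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium (%s): %s  [residual %.2e]\n", x$kind,
              paste(sprintf("%s = %.6g", names(x$state), x$state),
                    collapse = ", "), x$residual))
  invisible(x)
}

#' Routh-Hurwitz analysis of a cubic characteristic polynomial
#'
#' Accepts the characteristic coefficients either in the determinant
#' convention `-lambda^3 + T1 lambda^2 + T2 lambda + T3` (`convention =
#' "T"`) or directly as the monic `lambda^3 + a1 lambda^2 + a2 lambda + a3`
#' (`convention = "monic"`, with `a_i = -T_i`). Stability (all roots in the
#' open left half-plane) holds iff `a1 > 0`, `a3 > 0` and
#' `a1 a2 - a3 > 0`. The verdict is `"stable"` when all three quantities
#' are strictly positive and `"unstable"` when any is strictly negative;
#' when a quantity sits exactly on its boundary the algebraic test is
#' inconclusive (a boundary case may hide a genuinely unstable root, as in
#' `lambda^3 - lambda`), so the verdict falls back on the companion-matrix
#' eigenvalues, returning `"marginal"` only when the largest real part is
#' within `1e-9` of zero. The function also reports the minors
#' `M1 = 1`, `M2 = T3 - T1 T2`, `M3 = (T2 T3 - T1^2 T3)/T1` in the
#' determinant convention, and the companion-matrix eigenvalues for
#' cross-checking.
#'
#' @param char_coeffs numeric length-3 coefficient vector in the chosen
#'   convention.
#' @param convention `"T"` (default) or `"monic"`.
#' @return list with `monic` (`a1, a2, a3`), `T` (`T1, T2, T3`), `hurwitz`
#'   (the three test quantities), `minors`, `eigenvalues` and `verdict`.
#' @export
routh_hurwitz_cubic <- function(char_coeffs, convention = c("T", "monic")) {
  convention <- match.arg(convention)
  if (length(char_coeffs) != 3L || any(!is.finite(char_coeffs)))
    stop("`char_coeffs` must be three finite coefficients of a cubic",
         call. = FALSE)
  a <- if (convention == "T") -as.numeric(char_coeffs)
       else as.numeric(char_coeffs)
  Tc <- -a
  hw <- c(a1 = a[1], a3 = a[3], a1a2_minus_a3 = a[1] * a[2] - a[3])
  minors <- c(M1 = 1,
              M2 = Tc[3] - Tc[1] * Tc[2],
              M3 = (Tc[2] * Tc[3] - Tc[1]^2 * Tc[3]) / Tc[1])
  comp <- rbind(c(-a[1], -a[2], -a[3]), c(1, 0, 0), c(0, 1, 0))
  ev <- eigen(comp, only.values = TRUE)$values
  verdict <- if (all(hw > 0)) "stable"
             else if (any(hw < 0)) "unstable"
             else {
    # a test quantity sits exactly on its boundary: the algebraic test is
    # inconclusive there (roots may be imaginary-axis or mixed), so
    # classify by the companion eigenvalues
    mx <- max(Re(ev))
    if (mx > 1e-9) "unstable" else if (mx < -1e-9) "stable" else "marginal"
  }
  list(monic = stats::setNames(a, c("a1", "a2", "a3")),
       T = stats::setNames(Tc, c("T1", "T2", "T3")),
       hurwitz = hw, minors = minors, eigenvalues = ev, verdict = verdict)
}

#' Local stability report at a state
#'
#' Assembles the analytic Jacobian at `state`, its characteristic
#' coefficients in both sign conventions, the Routh-Hurwitz test, minors
#' and eigenvalues, and a verdict consistent with the eigenvalue real parts
#' (marginal band `|max Re| < 1e-9`).
#'
#' @param params a [base_params()] object.
#' @param state numeric `c(N, I, P)` (typically an equilibrium state).
#' @return object of class `stability_report`.
#' @export
stability_report <- function(params, state) {
  J <- jacobian_base(params, state)
  a1 <- -sum(diag(J))
  m2 <- det(J[1:2, 1:2]) + det(J[c(1, 3), c(1, 3)]) + det(J[2:3, 2:3])
  a3 <- -det(J)
  rh <- routh_hurwitz_cubic(c(a1, m2, a3), convention = "monic")
  ev <- eigen(J, only.values = TRUE)$values
  mx <- max(Re(ev))
  verdict <- if (abs(mx) < 1e-9) "marginal"
             else if (mx < 0) "stable" else "unstable"
  structure(list(state = state, jacobian = J,
                 char_coeffs = rh$T, char_monic = rh$monic,
                 minors = rh$minors, routh = rh$hurwitz,
                 eigenvalues = ev, verdict = verdict),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability report at state:",
      paste(signif(x$state, 6), collapse = ", "), "\n")
  cat("eigenvalues:", paste(format(x$eigenvalues, digits = 6),
                            collapse = ", "), "\n")
  cat("Routh-Hurwitz quantities:",
      paste(sprintf("%s = %.4g", names(x$routh), x$routh), collapse = ", "),
      "\n")
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Numeric Lyapunov trace along a trajectory
#'
#' Evaluates the sum-of-squares Lyapunov candidate
#' `V(t) = sum_i (x_i(t) - x_i^*)^2` along a computed trajectory and
#' reports how monotonically it decreases: the fraction of grid steps with
#' `Delta V <= 0`, the first index after which `Delta V <= 0` holds for all
#' subsequent steps (`NA` if none), and the fraction of non-increasing
#' steps after the global maximum of `V` (the transient peak).
#'
#' @param trajectory an `fde_solution` (or any list with `times` and
#'   `states`).
#' @param equilibrium an `equilibrium` object or a plain numeric state of
#'   matching dimension.
#' @return list with `V`, `frac_nonincreasing`, `settle_index`,
#'   `frac_after_peak`, `peak_index`.
#' @export
lyapunov_trace <- function(trajectory, equilibrium) {
  xs <- if (inherits(equilibrium, "equilibrium")) equilibrium$state
        else as.numeric(equilibrium)
  st <- trajectory$states
  if (ncol(st) != length(xs))
    stop("trajectory and equilibrium dimensions differ", call. = FALSE)
  V <- rowSums((st - matrix(xs, nrow(st), length(xs), byrow = TRUE))^2)
  dV <- diff(V)
  non_inc <- dV <= 0
  frac <- if (length(dV)) mean(non_inc) else 1
  settle <- NA_integer_
  if (length(dV)) {
    ok_from <- rev(cumprod(rev(non_inc)))  # 1 where all later steps decrease
    idx <- which(ok_from == 1)
    if (length(idx)) settle <- idx[1]
  }
  peak <- which.max(V)
  frac_after_peak <- if (peak < length(V)) mean(dV[peak:length(dV)] <= 0) else 1
  list(V = V, frac_nonincreasing = frac, settle_index = settle,
       frac_after_peak = frac_after_peak, peak_index = peak)
}

# Disease-free-equilibrium Jacobian in the two modes: "literal" uses the
# printed structure (treating I and P as absent from the off-diagnal
# couplings they multiply), "derived" evaluates the analytic Jacobian.
dfe_jacobian <- function(params, mode = c("literal", "derived")) {
  mode <- match.arg(mode)
  p <- params
  E0 <- c(N = p$K, I = 0, P = 0)
  J <- if (mode == "literal") {
    matrix(c(-p$lam, 0, -p$mu * p$K,
             0, -p$phi3, 0,
             p$gamma * p$K, 0, -p$delta),
           nrow = 3, byrow = TRUE,
           dimnames = list(c("dN", "dI", "dP"), c("N", "I", "P")))
  } else jacobian_base(p, E0)
  list(E0 = E0, J = J)
}

#' Reproduction number and coefficient at the disease-free equilibrium
#'
#' Builds the disease-free equilibrium `E0 = (K, 0, 0)`, assembles its
#' Jacobian, extracts a dominant eigenvalue `lambda1` and evaluates
#' \deqn{R_0 = \beta_1 \phi_1 / (\lambda_1 \mu), \qquad
#'       R_c = \beta_2 \gamma \phi_2 / (\lambda_1 \mu \phi_3).}
#' `R_0` is read as new cancer cells generated per cancer cell over its
#' lifetime, `R_c` as the division rate of cancer cells relative to normal
#' cells.
#'
#' Two ambiguities are explicit and surfaced rather than hidden: the
#' dominant eigenvalue may be selected by maximum real part or by maximum
#' modulus (for a complex pair, the *real part* of the selected eigenvalue
#' enters the ratio so that both numbers stay real); and the Jacobian can
#' be assembled in `"literal"` mode (the structural form with the baseline
#' immune and disseminated populations set to zero in the couplings) or in
#' `"derived"` mode (the analytic Jacobian of the right-hand side, whose
#' `(2,1)` and `(3,3)` entries differ at `E0`). Defaults: max real part,
#' literal. See [reproduction_table()] for a systematic scan.
#'
#' @param params a [base_params()] object with `mu > 0`, `phi3 > 0`.
#' @param dominance `"max-real-part"` (default) or `"max-modulus"`.
#' @param jacobian_mode `"literal"` (default) or `"derived"`.
#' @return object of class `reproduction_report`: `dfe`, `jacobian_dfe`,
#'   `char_coeffs_dfe` (the monic cubic coefficients), `eigenvalues`,
#'   `lambda1` (the real part used in the ratios), `R0`, `Rc`,
#'   `interpretation`.
#' @export
reproduction_numbers <- function(params,
                                 dominance = c("max-real-part", "max-modulus"),
                                 jacobian_mode = c("literal", "derived")) {
  dominance <- match.arg(dominance)
  jacobian_mode <- match.arg(jacobian_mode)
  p <- params
  if (p$mu <= 0 || p$phi3 <= 0)
    stop("reproduction ratios need mu > 0 and phi3 > 0", call. = FALSE)
  dfe <- dfe_jacobian(p, jacobian_mode)
  J <- dfe$J
  ev <- eigen(J, only.values = TRUE)$values
  pick <- switch(dominance,
                 "max-real-part" = which.max(Re(ev)),
                 "max-modulus" = which.max(Mod(ev)))
  lambda1 <- Re(ev[pick])
  if (abs(lambda1) < 1e-12)
    stop("dominant eigenvalue real part is zero; reproduction ratios undefined",
         call. = FALSE)
  a1 <- -sum(diag(J))
  m2 <- det(J[1:2, 1:2]) + det(J[c(1, 3), c(1, 3)]) + det(J[2:3, 2:3])
  a3 <- -det(J)
  structure(list(
    dfe = dfe$E0, jacobian_dfe = J,
    char_coeffs_dfe = c(a1 = a1, a2 = m2, a3 = a3),
    eigenvalues = ev, lambda1 = lambda1,
    R0 = p$beta1 * p$phi1 / (lambda1 * p$mu),
    Rc = p$beta2 * p$gamma * p$phi2 / (lambda1 * p$mu * p$phi3),
    interpretation = list(dominance = dominance,
                          jacobian_mode = jacobian_mode,
                          phi = c(phi1 = p$phi1, phi2 = p$phi2,
                                  phi3 = p$phi3))),
    class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(sprintf(
    "reproduction report (%s, %s Jacobian): lambda1 = %.6g\n  R0 = %.6g, Rc = %.6g\n",
    x$interpretation$dominance, x$interpretation$jacobian_mode,
    x$lambda1, x$R0, x$Rc))
  invisible(x)
}

#' Interpretation table for the reproduction ratios
#'
#' The reference parameter list prints two growth-factor sets (the dynamics
#' set `phi = (0.03, 0.04, 0.01)` and the control-auxiliary set
#' `phi' = (0.9, 0.458, 0.8)`), and the dominant-eigenvalue rule behind the
#' published ratios is not pinned down. This helper evaluates
#' [reproduction_numbers()] under all four combinations (two phi sets x two
#' dominance rules) on the literal disease-free Jacobian and returns them
#' as one table, so the reader can see the full spread of defensible
#' values.
#'
#' @param preset a `sim_preset` from [load_preset()] (needs `base` and
#'   `phi_control`).
#' @return data.frame with columns `phi_set`, `dominance`, `lambda1`, `R0`,
#'   `Rc`, `R0_magnitude`, `Rc_magnitude`.
#' @export
reproduction_table <- function(preset) {
  stopifnot(inherits(preset, "sim_preset"), !is.null(preset$base))
  pc <- preset$phi_control
  alt <- preset$base
  alt$phi1 <- unname(pc["phi1"]); alt$phi2 <- unname(pc["phi2"])
  alt$phi3 <- unname(pc["phi3"])
  rows <- list()
  for (set in c("dynamics", "control")) {
    par <- if (set == "dynamics") preset$base else alt
    for (rule in c("max-real-part", "max-modulus")) {
      rep <- reproduction_numbers(par, dominance = rule)
      rows[[length(rows) + 1L]] <- data.frame(
        phi_set = set, dominance = rule, lambda1 = rep$lambda1,
        R0 = rep$R0, Rc = rep$Rc,
        R0_magnitude = abs(rep$R0), Rc_magnitude = abs(rep$Rc))
    }
  }
  do.call(rbind, rows)
}
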