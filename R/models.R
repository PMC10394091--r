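#' Parameters of the three-compartment tumor-immune-metastasis model
#'
#' Container for the rate constants of the base dynamics in
#' `N` (primary tumor cells), `I` (immune cells) and `P` (disseminated
#' tumor cells):
#' \deqn{D^\alpha N = \lambda N (1 - N/K) - \mu N P - \beta_1 N I}
#' \deqn{D^\alpha I = \phi_1 I_0 + \phi_2 N^2 - \phi_3 I - \beta_2 I P}
#' \deqn{D^\alpha P = \gamma N P - \delta P - \beta_3 I P}
#' The immune source `phi1 * I_baseline` is a constant influx set by the
#' baseline immune count `I_baseline` (it is *not* state dependent).
#'
#' @param lam intrinsic tumor growth rate (1/day).
#' @param K carrying capacity of the lung tissue (cells).
#' @param mu dissemination pressure of circulating tumor cells on the
#'   primary site (1/(cell day)).
#' @param gamma proliferation rate of disseminated cells fed by the primary
#'   tumor (1/(cell day)).
#' @param delta death rate of disseminated cells (1/day).
#' @param beta1 tumor kill rate by immune cells (1/(cell day)).
#' @param beta2 immune exhaustion by disseminated cells (1/(cell day)).
#' @param beta3 clearance of disseminated cells by immune cells
#'   (1/(cell day)).
#' @param phi1,phi2,phi3 growth-factor effects: constant immune recruitment
#'   coefficient, tumor-driven immune stimulation (quadratic in `N`), and
#'   immune decay rate.
#' @param I_baseline baseline immune count `I0` multiplying `phi1` (cells).
#' @param alpha Caputo order in (0, 1].
#' @return object of class `base_params`.
#' @export
base_params <- function(lam, K, mu, gamma, delta, beta1, beta2, beta3,
                        phi1, phi2, phi3, I_baseline, alpha = 1) {
  p <- list(lam = lam, K = K, mu = mu, gamma = gamma, delta = delta,
            beta1 = beta1, beta2 = beta2, beta3 = beta3,
            phi1 = phi1, phi2 = phi2, phi3 = phi3,
            I_baseline = I_baseline, alpha = alpha)
  rates <- unlist(p[setdiff(names(p), "alpha")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and nonnegative", call. = FALSE)
  if (K <= 0) stop("`K` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]",
                                    call. = FALSE)
  structure(p, class = "base_params")
}

#' Parameters of the combined-therapy model
#'
#' Extends [base_params()] with the efficacies of PD-L1 immunotherapy and
#' surgery and the onset delay. Treatment terms are gated by the delayed
#' Heaviside step `theta(t - tau)`: nothing acts before `tau`.
#'
#' @param base a `base_params` object.
#' @param eps1 treatment kill of disseminated cells via the primary tumor
#'   burden (1/(cell day)).
#' @param eps2 treatment kill of disseminated cells via immune engagement
#'   (1/(cell day)).
#' @param eps3 surgical removal rate of disseminated cells (1/day).
#' @param eps4 clearance rate of the surgically removed pool `T` (1/day).
#' @param tau onset delay of the therapy (days).
#' @return object of class `therapy_params` (also carries the embedded
#'   base parameters).
#' @export
therapy_params <- function(base, eps1, eps2, eps3, eps4, tau = 0) {
  stopifnot(inherits(base, "base_params"))
  eps <- c(eps1, eps2, eps3, eps4)
  if (any(!is.finite(eps)) || any(eps < 0))
    stop("efficacies must be finite and nonnegative", call. = FALSE)
  if (tau < 0) stop("`tau` must be nonnegative", call. = FALSE)
  structure(c(unclass(base),
              list(eps1 = eps1, eps2 = eps2, eps3 = eps3, eps4 = eps4,
                   tau = tau)),
            class = c("therapy_params", "base_params"))
}

#' Parameters of the six-compartment stem-cell model
#'
#' Rate constants `k1...k14` of the cancer stem-cell hierarchy used for
#' sensitivity analysis: `C` cancer stem cells, `Pk` progenitor cells, `S`
#' supporting cells, `E` effector/environment compartment, `Nk` normal
#' cells, `Ik` immune compartment. Only the steady-state relations of this
#' model are given in closed form; the dynamics are reconstructed by reading
#' each steady-state expression as the Caputo derivative of its compartment
#' (see [kmodel_rhs()]).
#'
#' @param k numeric vector of length 14 (named or positional, `k1...k14`),
#'   all nonnegative.
#' @param alpha Caputo order in (0, 1].
#' @return object of class `kmodel_params`.
#' @export
kmodel_params <- function(k, alpha = 1) {
  if (length(k) != 14L) stop("`k` must have length 14", call. = FALSE)
  k <- as.numeric(k)
  if (any(!is.finite(k)) || any(k < 0))
    stop("all k must be finite and nonnegative", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]",
                                    call. = FALSE)
  names(k) <- paste0("k", 1:14)
  structure(list(k = k, alpha = alpha), class = "kmodel_params")
}

#' Delayed Heaviside step
#'
#' `theta(t - tau)`: 0 before the therapy onset `tau`, 1 from `tau` on.
#' The boundary is inclusive: `heaviside_delay(tau, tau) == 1`, i.e. the
#' treatment is active at exactly `t = tau`.
#'
#' @param t time.
#' @param tau delay.
#' @return 0 or 1 (vectorised over `t`).
#' @export
heaviside_delay <- function(t, tau) as.numeric(t >= tau)

#' Right-hand side of the base model
#'
#' @param state numeric vector `c(N, I, P)`.
#' @param params a [base_params()] object.
#' @return derivative vector `c(dN, dI, dP)` (the Caputo derivative of each
#'   compartment).
#' @export
base_rhs <- function(state, params) {
  N <- state[1]; I <- state[2]; P <- state[3]
  p <- params
  c(p$lam * N * (1 - N / p$K) - p$mu * N * P - p$beta1 * N * I,
    p$phi1 * p$I_baseline + p$phi2 * N^2 - p$phi3 * I - p$beta2 * I * P,
    p$gamma * N * P - p$delta * P - p$beta3 * I * P)
}

#' Right-hand side of the combined-therapy model
#'
#' Base dynamics for `N` and `I`; the disseminated pool `P` additionally
#' loses `theta(t - tau) * (eps1 N P + eps2 I P)` to the therapy, and the
#' surgically removed pool obeys
#' `dT = theta(t - tau) * eps3 * P - eps4 * T`.
#'
#' @param state numeric vector `c(N, I, P, T)`.
#' @param t time (needed for the delayed treatment gate).
#' @param params a [therapy_params()] object.
#' @param dose multiplicative dosage scaling applied to `eps1`, `eps2`,
#'   `eps3` (default 1 = nominal efficacy). This is the hook through which
#'   the control layer steers the therapy.
#' @return derivative vector `c(dN, dI, dP, dT)`.
#' @export
therapy_rhs <- function(state, t, params, dose = 1) {
  N <- state[1]; I <- state[2]; P <- state[3]; TT <- state[4]
  p <- params
  th <- heaviside_delay(t, p$tau)
  e1 <- dose * p$eps1; e2 <- dose * p$eps2; e3 <- dose * p$eps3
  c(p$lam * N * (1 - N / p$K) - p$mu * N * P - p$beta1 * N * I,
    p$phi1 * p$I_baseline + p$phi2 * N^2 - p$phi3 * I - p$beta2 * I * P,
    p$gamma * N * P - p$delta * P - p$beta3 * I * P -
      th * (e1 * N * P + e2 * I * P),
    th * e3 * P - p$eps4 * TT)
}

#' Right-hand side of the feedback-controlled therapy model
#'
#' Identical to [therapy_rhs()] except that the therapy also acts directly
#' on the primary tumor (`- theta eps1 N P` in the `N` equation) and on the
#' immune pool (`- theta eps2 I P` in the `I` equation); the difference
#' from the plain therapy model is exactly `(-eps1 N P, -eps2 I P, 0, 0)`
#' once the treatment is on.
#'
#' @inheritParams therapy_rhs
#' @return derivative vector `c(dN, dI, dP, dT)`.
#' @export
feedback_rhs <- function(state, t, params, dose = 1) {
  N <- state[1]; I <- state[2]; P <- state[3]
  p <- params
  th <- heaviside_delay(t, p$tau)
  e1 <- dose * p$eps1; e2 <- dose * p$eps2
  out <- therapy_rhs(state, t, params, dose = dose)
  out[1] <- out[1] - th * e1 * N * P
  out[2] <- out[2] - th * e2 * I * P
  out
}

#' Right-hand side of the six-compartment stem-cell model
#'
#' The dynamics whose steady state the sensitivity analysis studies. Each
#' compartment's derivative is the bracketed expression whose zero set
#' defines the steady state:
#' `dC = k1 C - k2 C - k3 C S - k4 C E`, `dPk = k5 C - k6 Pk`,
#' `dS = k7 S - k8 C S`, `dE = k9 E - k10 C E`, `dNk = k11 - k12 Nk`,
#' `dIk = k13 Pk - k14 Ik`.
#'
#' @param state numeric vector `c(C, Pk, S, E, Nk, Ik)`.
#' @param params a [kmodel_params()] object.
#' @return derivative vector of length 6.
#' @export
kmodel_rhs <- function(state, params) {
  k <- params$k
  C <- state[1]; Pk <- state[2]; S <- state[3]
  E <- state[4]; Nk <- state[5]; Ik <- state[6]
  unname(c(k[1] * C - k[2] * C - k[3] * C * S - k[4] * C * E,
           k[5] * C - k[6] * Pk,
           k[7] * S - k[8] * C * S,
           k[9] * E - k[10] * C * E,
           k[11] - k[12] * Nk,
           k[13] * Pk - k[14] * Ik))
}

#' Build an engine-ready right-hand side closure
#'
#' Adapts a parameterised model to the `f(t, y, u)` contract of
#' [fde_problem()] / [solve_fde()]. For the therapy and feedback variants
#' the exogenous input `u` (when `use_input = TRUE`) is interpreted as the
#' dosage scaling of the treatment efficacies; otherwise the nominal
#' `dose = 1` is used and `u` is ignored.
#'
#' @param params `base_params`, `therapy_params` or `kmodel_params`.
#' @param variant one of `"base"`, `"therapy"`, `"feedback"`, `"kmodel"`.
#' @param use_input logical: couple the exogenous input to the dosage.
#' @return function `f(t, y, u)`.
#' @export
make_rhs <- function(params,
                     variant = c("base", "therapy", "feedback", "kmodel"),
                     use_input = FALSE) {
  variant <- match.arg(variant)
  switch(variant,
    base = {
      stopifnot(inherits(params, "base_params"))
      function(t, y, u) base_rhs(y, params)
    },
    therapy = {
      stopifnot(inherits(params, "therapy_params"))
      if (use_input) function(t, y, u) therapy_rhs(y, t, params, dose = u)
      else function(t, y, u) therapy_rhs(y, t, params)
    },
    feedback = {
      stopifnot(inherits(params, "therapy_params"))
      if (use_input) function(t, y, u) feedback_rhs(y, t, params, dose = u)
      else function(t, y, u) feedback_rhs(y, t, params)
    },
    kmodel = {
      stopifnot(inherits(params, "kmodel_params"))
      function(t, y, u) kmodel_rhs(y, params)
    })
}
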