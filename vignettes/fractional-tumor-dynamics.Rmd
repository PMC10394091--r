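---
title: "Fractional-order tumor-immune-metastasis dynamics: models, numerics and control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-order tumor-immune-metastasis dynamics: models, numerics and control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractumor)
```

## The model family

The package centres on a Caputo fractional-order compartmental model of
lung cancer with three state variables: primary tumor cells $N(t)$,
immune cells $I(t)$ and disseminated (metastatic) tumor cells $P(t)$:

$$
\begin{aligned}
D^\alpha N &= \lambda N\Big(1 - \frac{N}{K}\Big) - \mu N P - \beta_1 N I,\\
D^\alpha I &= \phi_1 I_0 + \phi_2 N^2 - \phi_3 I - \beta_2 I P,\\
D^\alpha P &= \gamma N P - \delta P - \beta_3 I P,
\end{aligned}
$$

with $D^\alpha$ the Caputo derivative of order $\alpha \in (0, 1]$. The
fractional order is the memory dial: at $\alpha = 1$ the system is an
ordinary ODE; for $\alpha < 1$ the rate of change at time $t$ is a
power-law-weighted functional of the entire past, a standing model of
delayed, history-dependent cellular response. All compartments share one
order -- the preset's several $\alpha$ values are alternative scenarios,
not per-compartment orders.

Interpretation of the terms: logistic growth of the primary tumor with
carrying capacity $K$; immune kill pressure $\beta_1 N I$; metastatic
pressure $\mu N P$ on the primary site; a *constant* immune source
$\phi_1 I_0$, where $I_0$ is the baseline immune count (a stored
parameter, `I_baseline` -- deliberately not a state-dependent term);
tumor-driven immune stimulation $\phi_2 N^2$; and a disseminated pool fed
by the primary tumor ($\gamma N P$) and cleared by death ($\delta$) and
immune action ($\beta_3 I P$).

Three extensions share this core:

* **Therapy model** (`therapy_rhs`): PD-L1 immunotherapy and surgery act
  on the disseminated pool through
  $-\theta(t-\tau)\,(\epsilon_1 N P + \epsilon_2 I P)$, and a fourth
  compartment $T$ (surgically removed cells) obeys
  $D^\alpha T = \theta(t-\tau)\epsilon_3 P - \epsilon_4 T$. The delayed
  Heaviside gate $\theta(t-\tau)$ switches the treatment on at $t = \tau$;
  the boundary is **inclusive** ($\theta(0) = 1$), a convention the
  package fixes since either choice is defensible.
* **Feedback model** (`feedback_rhs`): additionally applies the direct
  kill terms $-\theta\epsilon_1 N P$ and $-\theta\epsilon_2 I P$ to the
  $N$ and $I$ equations. The difference from the therapy model is exactly
  $(-\epsilon_1 N P, -\epsilon_2 I P, 0, 0)$ once treatment is on, and a
  test pins that down term by term.
* **Stem-cell model** (`kmodel_rhs`): a six-compartment cancer stem-cell
  hierarchy ($C$, $Pk$, $S$, $E$, $Nk$, $Ik$) with rates $k_1 \dots
  k_{14}$, used for sensitivity analysis. Only its *steady-state
  relations* are given in closed form in the source formulation; the
  package reconstructs the dynamics by reading each zero-set expression
  as the Caputo derivative of its compartment. This reconstruction is a
  modelling decision, stated here prominently.

### Reference parameterisation

`load_preset("lung-ref")` freezes the reference constants: $\lambda =
0.3$, $K = 10^4$, $\mu = 0.01$, $\beta_1 = \beta_2 = 0.01$, $\beta_3 =
0.04$, $\phi = (0.03, 0.04, 0.01)$, $\gamma = 0.07$, $\delta = 0.001$,
initial state $(N, I, P, T) = (3000, 90, 20, 0)$, orders $\{0.5, 0.7,
0.9\}$, grid $[0, 400]$ at $h = 2^{-6}$, onset delay $\tau = 5$ days.
Units: days for time, cells for the states, per-day (or per cell-day)
rates.

Quirks the preset carries explicitly instead of hiding:

* Two growth-factor sets are printed in the reference list. The first,
  $\phi = (0.03, 0.04, 0.01)$, drives the dynamics; the second,
  $\phi' = (0.9, 0.458, 0.8, \phi'_4 \dots \phi'_{10})$, is reserved for
  the control auxiliaries (`phi_control`). Both are stored.
* The scalars $\theta = 0.5$, $\eta = 0.7$ and a spare order $0.3$ enter
  no equation; they are stored under `unused` and flagged.
* The therapy efficacies $\epsilon_1 \dots \epsilon_4 = 0.5$ are package
  defaults (the reference list prints none), and the stem-cell rates
  $k_{13} = k_{14} = 0.1$ are likewise package defaults labelled
  `k_defaults` in `load_preset("stemcell-ref")`.

## The numerical core

`solve_fde()` implements the fractional Adams-Bashforth-Moulton
predictor-corrector (the scheme behind MATLAB's FDE12): at each step the
state is predicted with the fractional rectangle (product-integration)
rule over the *entire* history, then corrected once with the fractional
trapezoidal rule. `abm_weights()` exposes the quadrature weights; at
$\alpha = 1$ they collapse to the classical rectangle and trapezoid
weights, which the tests verify symbolically. One corrector pass per step
is the default (the FDE12 convention; the count is configurable, and the
scheme's fixed-point iteration diverges anyway in exactly the stiff
regimes where more passes would be tempting).

Design choices, each with its reason:

* **Full memory, $O(n^2)$ cost.** The Caputo convolution is evaluated
  exactly over all past slopes. A short-memory window exists
  (`memory =`) for experimentation but is off by default: truncation
  changes the solution for $\alpha < 1$, and a test asserts that it does.
* **Uniform grid only**; `t_final` is snapped to the nearest step
  multiple with a warning.
* **Exogenous input** $u(t)$ (the dosage channel) is sampled at grid
  nodes and held constant within each step -- the simplest contract that
  makes the PID coupling well defined.
* **Negative states are never clipped.** Populations crossing zero are a
  diagnostic, not something to silently repair (clipping would alter the
  dynamics being studied); the first crossing of any component that
  started nonnegative is recorded in the metadata and raised as a
  warning.
* **Non-finite states abort** with the step index and last finite state
  in the condition object (class `fde_nonfinite`).

### Stability of the explicit scheme, and the reference grid

The scheme is explicit. For the reference parameters the immune
stimulation $\phi_2 N^2 \approx 3.6\times10^5$ cells/day drives the
immune pool to $\approx 5900$ within a fraction of a day, after which the
linearised decay rates reach $\beta_3 I \approx 236$/day. An explicit
one-step corrector is stable only while $h \cdot \text{rate} \lesssim 2$,
i.e. $h \lesssim 2^{-8}$ here. At the reference grid step $h = 2^{-6}$
the iteration diverges for *every* order $\{0.5, 0.7, 0.9, 1\}$ -- the
reference grid and the reference rates are mutually inconsistent for
this class of solver. The package documents this rather than papering
over it: the acceptance-style test that compares the $\alpha = 1$ run at
the reference grid against an adaptive classical integrator (deSolve's
LSODA) is expected to fail and says why, while a companion test shows the
classical limit holds to $10^{-3}$ relative error on a
stability-compatible grid ($h = 2^{-12}$ over $[0, 2]$, which covers the
violent transient; the horizon is kept short because full-memory cost is
quadratic in the step count).

### Verification oracle

`mittag_leffler()` evaluates $E_\alpha(z) = \sum_k z^k/\Gamma(\alpha k +
1)$, the solution kernel of linear Caputo equations: $D^\alpha y = -y$,
$y(0) = 1$ has $y(t) = E_\alpha(-t^\alpha)$. The series alternates for
$z < 0$ and its largest term is $\sim e^{|z|^{1/\alpha}}$, so in double
precision the sum is trusted only while $|z|^{1/\alpha} \le 18$; beyond,
the algebraic asymptotic expansion is used, truncated at the minimum of
its smooth term envelope (the reflection sine makes raw term magnitudes
oscillate, so the envelope -- not the first growing term -- locates the
optimal truncation). $\alpha = 1$ and $\alpha = 2$ use the exact
exponential and cosine identities. Solver tests compare trajectories at
$t = 1$ against series values frozen from 30-digit arithmetic; measured
convergence order on linear decay is $\approx 1 + \alpha$.

## Equilibria, stability, reproduction ratios

`find_equilibria()` combines closed-form candidates with seeded
multistart Newton iteration (analytic Jacobian), accepting only roots
whose residual max-norm is $\le 10^{-8}$. The closed forms use the
self-consistent reductions $I = (\gamma N - \delta)/\beta_3$ and
$P = (\lambda(1 - N/K) - \beta_1 I)/\mu$ (the source formulation's
$I = \gamma N \delta / \beta_3$ does not solve its own defining
equation; residual verification is the arbiter). For the reference
parameters the interior reduction leads to
$0.0707 N^2 - 0.543 N + 2.708 = 0$ with negative discriminant: **no
positive equilibrium exists**, and the only steady state is the
tumor-free state $(0,\ \phi_1 I_0/\phi_3,\ 0) = (0, 270, 0)$, which is
locally stable (eigenvalues $\approx -2.4, -0.01, -10.8$). Simulated
trajectories do converge there, which is what the Lyapunov test checks.

`routh_hurwitz_cubic()` applies the classical cubic criteria ($a_1 > 0$,
$a_3 > 0$, $a_1 a_2 - a_3 > 0$, after normalising the determinant
convention $-\lambda^3 + T_1\lambda^2 + T_2\lambda + T_3$ to monic with
$a_i = -T_i$) and reports the literal minors $M_1, M_2, M_3$ of the
source formulation alongside. On the boundary the algebraic test is
inconclusive (e.g. $\lambda^3 - \lambda$ has a frankly unstable root
while all test quantities vanish), so the verdict falls back on
companion-matrix eigenvalues with a marginal band of $10^{-9}$. A
property test checks 1000 random cubics against eigenvalues with 100%
agreement.

`lyapunov_trace()` evaluates the sum-of-squares candidate
$V(t) = \sum_i (x_i(t) - x_i^*)^2$ along a computed trajectory and
reports how monotonically it decreases. Because the immune pool relaxes
at rate $\phi_3 = 0.01$/day, coming within 1% of $I^* = 270$ takes about
800 days; the test integrates the $\alpha = 1$ dynamics in restarted
5-day chunks (exact in the memoryless classical limit only) at
$h = 2^{-8}$ and finds $V$ non-increasing at every step after the
transient peak.

### Reproduction number and coefficient

At the disease-free equilibrium $E_0 = (K, 0, 0)$ the package computes
$$
R_0 = \frac{\beta_1\phi_1}{\lambda_1\mu}, \qquad
R_c = \frac{\beta_2\gamma\phi_2}{\lambda_1\mu\phi_3},
$$
with $\lambda_1$ a dominant eigenvalue of the Jacobian at $E_0$. Two
genuine ambiguities are surfaced instead of resolved silently:

1. **Which Jacobian.** The structural (`"literal"`) form sets the
   baseline immune and disseminated populations to zero inside the
   couplings; the analytic (`"derived"`) Jacobian of the right-hand side
   differs at $E_0$ (notably its $(3,3)$ entry carries
   $\gamma K - \delta$). Both modes are available; neither is asserted
   "correct".
2. **Which eigenvalue, which $\phi$ set.** `reproduction_table()`
   evaluates all four combinations of growth-factor set (dynamics vs
   control) and dominance rule (max real part vs max modulus), using the
   real part of the selected eigenvalue so the ratios stay real.

```{r}
reproduction_table(load_preset("lung-ref"))
```

For the reference constants the spread of magnitudes is
$R_0 \in \{3.0,\ 0.20,\ 5.98\}$ and $R_c \in \{28,\ 1.86,\ 0.27\}$; no
interpretation reproduces the published headline pair (2.6, 0.22) to two
significant figures, and no pair $(\lambda_1, \phi\text{-set})$ can
satisfy both ratios simultaneously. The package reports the default
interpretation (dynamics $\phi$ set, max real part) and ships the full
table; choosing whichever row lands closest would be curve fitting, not
analysis.

## Sensitivity analysis

`normalized_sensitivity()` computes elasticities
$S_i = \partial\ln f/\partial\ln\theta_i$ with perturbation
$\varepsilon = 0.01\,\theta$. The default central mode differences **in
log space**, which is the elasticity's native quotient and exact for
power laws -- for the stem-cell steady state $N_k^* = k_{11}/k_{12}$ it
returns $+1$, $-1$ and structural $0$s to machine precision, where a
plain central quotient of $f$ would carry a $10^{-4}$ curvature bias at
the same $\varepsilon$. The one-sided (`"forward"`) quotient is kept as
the literal variant, and central and forward estimates are shown to
converge toward each other as $\varepsilon$ shrinks.

`kmodel_steady_state()` uses the closed-form interior branch
($C = k_7/k_8$, $S = (k_1-k_2)/k_3$, $E = 0$, linear compartments exact)
polished by Newton iteration, with the stem-cell-free branch available;
`trajectory_sensitivity()` differences two full `solve_fde` runs on
identical grids for time-resolved sensitivities. At the reference
stem-cell constants the elasticity of $C(t)$ to the division rate $k_1$
is positive for $t \lesssim 20$ days and flips sign later as the support
compartment collapses; the package's examples therefore evaluate at
$t = 20$. The published coefficient table ships verbatim
(`reference_sensitivities()`) for side-by-side display only: it lists
zeros for $k_{11}, k_{12}$ and nonzero values for $k_5, k_{13}$ on a
steady state that closed-form analysis shows has the opposite sparsity
pattern, so it is displayed, never asserted.

## Therapy optimization and dosing

`forward_backward_sweep()` minimises
$J = \int_0^{t_f} (w_1 N + w_2 I + w_3 P - w_4 T)\,dt$ over a bounded
dosage $u(t) \in [0, u_{\max}]$ scaling $(\epsilon_1, \epsilon_2,
\epsilon_3)$ multiplicatively. The first-order conditions are the
textbook ones -- Hamiltonian $H = \text{integrand} + \lambda^\top f$,
costates $\dot\lambda = -\partial H/\partial x$ with $\lambda(t_f) = 0$,
control from the $u$-gradient of $H$. Decisions worth stating:

* The source formulation's expanded adjoint system mixes state and
  costate symbols in ways that do not form a consistent stationarity
  system (its "state equations" read $dN/dt = \mu\psi_1$ and its
  Hamiltonian carries adjoint-bearing terms with no matching dynamics);
  the package implements the textbook conditions for the stated dynamics
  and cost, and treats the expanded system as documentation only. The
  ten-adjoint layout survives in `costates_to_psi()`, which embeds the
  four computed costates at positions 1, 2, 4, 10 (the remaining
  auxiliary adjoints are identically zero under zero terminal data).
* $H$ is affine in $u$, so the minimiser is bang-bang in the switching
  function $\partial H/\partial u$; the update relaxes toward it and is
  accepted only if $J$ does not increase (backtracking halves the
  relaxation), making the iteration log non-increasing by construction.
* The sweep runs on the $\alpha = 1$ dynamics. The adjoint of a Caputo
  system involves *right-sided* fractional derivatives; the package
  deliberately does not implement that machinery, and the dosing layer
  of the model family is specified at integer order anyway. Forward and
  backward integrations use the fixed-step classical Runge-Kutta
  companion (`solve_classical`), which is cross-checked against
  `solve_fde(alpha = 1)`.
* How a scalar dosage maps onto three efficacies is a modelling choice,
  not a derived fact; multiplicative scaling is the package's explicit,
  replaceable policy.
* A second control formulation in the source embeds the PID signal
  directly in the immune equation with $u_2 \equiv 0$; the package
  honours $u_2 \equiv 0$ and realises the PID pathway through the dosing
  loop below. Closed-form integrating-factor solutions offered for the
  controlled compartments are not implemented: they are not consistent
  with the stated dynamics, and the controlled system is integrated
  numerically instead.

For the reference preset the treatment delay $\tau = 5$ days is longer
than the uncontrolled collapse of the tumor (the immune surge extinguishes
$N$ and $P$ within a day), so the optimal dose cannot improve on
$u \equiv 0$ and the sweep correctly returns $J(u^*) = J(0)$; the strict
improvement property is exercised on a synthetic test-bed (below).

`feedback_dosing_loop()` implements the cyclic dosing procedure:
simulate the feedback model over the horizon at a constant dose, read
off $N(t_f)$, update the dose with `pid_update()` (trapezoidal integral
term, backward-difference derivative term), repeat until the
end-of-horizon error is inside the tolerance band. Two sign/semantics
decisions: the driving error is the tumor *excess* $N(t_f) -
N_{\text{target}}$, so nonnegative gains push the dose the
pharmacologically right way; and the dose is the initial dose plus the
PID adjustment, clamped to $[0, u_{\max}]$ with the integral frozen while
clamped (anti-windup) -- so all-zero gains hold the dose constant. Each
cycle is deterministic; so is the whole loop.

### The synthetic controller test-bed

Controller properties need a plant whose dose response is smooth and
monotone, which the reference preset is not (its tumor self-extinguishes
before therapy onset). The tests therefore build a *synthetic*
harvested-logistic configuration: a small logistic tumor ($K = 100$,
$\lambda = 0.15$/day) under a large, nearly frozen disseminated pool
($P_0 = 5000$, $\epsilon_1 = 10^{-3}$, all other couplings zero), so the
dose acts like a proportional harvesting rate and $N(30)$ falls smoothly
from $\approx 99$ to extinction over $u \in [0, 0.03]$. On this plant the
PID loop converges to a mid-range target within the cycle budget, and
the sweep strictly beats no treatment. What this does and does not show:
it validates the controller and optimizer logic under clean, monotone
conditions; it says nothing about dosing real tumors, where
non-monotone dose responses (as the reference parameters themselves
produce) are possible.

## Problem sizes used by the test suite

The suite runs in about a minute on one core. Deliberate choices: the
Mittag-Leffler solver checks use $h = 2^{-8}$ on $[0, 1]$; the classical
limit uses $h = 2^{-12}$ on $[0, 2]$ (quadratic memory cost caps the
horizon); the Lyapunov run covers $[0, 800]$ days in restarted 5-day
chunks at $h = 2^{-8}$; sweeps and dosing loops use $h \in \{2^{-6},
2^{-8}\}$ over horizons of 10-30 days. These are accuracy/stability
choices documented above, not tuning knobs.

## Known limitations

* No right-sided Caputo adjoints, hence no fractional-order optimality
  system; the sweep is integer-order by design.
* Local stability is argued through classical Routh-Hurwitz eigenvalue
  conditions; the fractional Matignon sector condition
  $|\arg\lambda| > \alpha\pi/2$ (which is *less* restrictive for
  $\alpha < 1$) is noted here but not implemented, matching the analysis
  layer this package reproduces.
* The explicit solver has a bounded stability region; stiff
  parameterisations need small steps, and the full-memory cost grows
  quadratically with the step count. No implicit fractional solver is
  provided.
* No parameter fitting to patient data, no stochastic or spatial
  extensions; simulated dynamics inherit every idealisation of the model
  (deterministic rates, well-mixed compartments, exact full-state
  feedback for the controller).
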