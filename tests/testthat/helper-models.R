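# High-precision values of E_alpha(-1), summed from the defining series in
# 30-digit arithmetic; independent oracle for the solver tests.
ML_NEG1 <- c("0.5" = 0.427583576155807,
             "0.7" = 0.399611978115599,
             "0.9" = 0.376066021424642,
             "1"   = exp(-1))

# Harvested-logistic therapy test-bed (synthetic, built for controller
# tests): a small logistic tumor (K = 100) under a large, nearly frozen
# disseminated pool that acts as the drug's effector, so the end-of-horizon
# burden N(30) responds smoothly and monotonically to the dosage.
demo_therapy_params <- function() {
  bp <- base_params(lam = 0.15, K = 100, mu = 0, gamma = 0, delta = 0,
                    beta1 = 0, beta2 = 0, beta3 = 0, phi1 = 0, phi2 = 0,
                    phi3 = 0.01, I_baseline = 0, alpha = 1)
  therapy_params(bp, eps1 = 1e-3, eps2 = 0, eps3 = 0, eps4 = 0, tau = 0)
}
demo_init <- c(N = 50, I = 0, P = 5000, T = 0)

# Piecewise (restarted) integration of an alpha = 1 problem: valid only in
# the memoryless classical limit, where the solution is a semigroup.
chunked_classical_fde <- function(rhs, y0, t0, t_final, h, chunk = 5) {
  y <- y0; states <- NULL; times <- NULL
  starts <- seq(t0, t_final - chunk, by = chunk)
  for (c0 in starts) {
    s <- suppressWarnings(
      solve_fde(fde_problem(rhs, y, c0, c0 + chunk, h = h, alpha = 1)))
    keep <- if (is.null(states)) seq_len(nrow(s$states)) else -1L
    states <- rbind(states, s$states[keep, , drop = FALSE])
    times <- c(times, s$times[keep])
    y <- s$states[nrow(s$states), ]
  }
  list(times = times, states = states)
}
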