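#' Available simulation presets
#'
#' @return character vector of registered preset names.
#' @export
preset_names <- function() c("lung-ref", "stemcell-ref")

#' Load a named simulation preset
#'
#' Presets freeze every constant a reproducible run needs. Two are shipped:
#'
#' * `"lung-ref"` - the reference parameterisation of the three-compartment
#'   tumor-immune-metastasis model and its therapy extension: base rates
#'   (`lam = 0.3`, `K = 1e4`, `mu = 0.01`, `beta1 = beta2 = 0.01`,
#'   `beta3 = 0.04`, `phi1 = 0.03`, `phi2 = 0.04`, `phi3 = 0.01`,
#'   `gamma = 0.07`, `delta = 0.001`), initial state
#'   `(N, I, P, T) = (3000, 90, 20, 0)`, fractional orders
#'   `{0.5, 0.7, 0.9}`, grid `[0, 400]` with `h = 2^-6`, onset delay
#'   `tau = 5`, the second growth-factor set (`phi1' = 0.9`,
#'   `phi2' = 0.458`, `phi3' = 0.8`, `phi4...phi10`) reserved for the
#'   control auxiliaries, auxiliary initial values `W0 = 100`, `V0 = 50`,
#'   and the spare scalars `theta = 0.5`, `eta = 0.7`, `alpha' = 0.3`
#'   (stored for completeness; they enter no equation and are flagged
#'   `unused`). The therapy efficacies `eps1..eps4 = 0.5` are package
#'   defaults, not part of the frozen reference list.
#' * `"stemcell-ref"` - the six-compartment stem-cell model for sensitivity
#'   analysis: `k1 = 0.35 ... k12 = 0.1`, `alpha = 0.8`, initial state
#'   `(C, Pk, S, E, Nk, Ik) = (100, 0, 100, 0, 10, 0)`. `k13 = k14 = 0.1`
#'   are package defaults, absent from the reference list, and are labelled
#'   as such in the preset.
#'
#' The presets are stored as JSON under `inst/extdata/presets/`; a test
#' asserts the shipped files match the loader's frozen expectations.
#'
#' @param name preset name, see [preset_names()].
#' @return a list of class `sim_preset` with elements `base`
#'   ([base_params()]), `therapy` ([therapy_params()]) and/or `kmodel`
#'   ([kmodel_params()]), `init` (named initial state), `alphas`, `grid`,
#'   `control_grid`, `phi_control`, `unused` and `raw` (the parsed JSON).
#' @export
load_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% preset_names()))
    stop(sprintf("unknown preset '%s'; available: %s",
                 as.character(name)[1],
                 paste(preset_names(), collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "fractumor", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (name == "lung-ref") {
    b <- raw$base
    base <- base_params(lam = b$lam, K = b$K, mu = b$mu, gamma = b$gamma,
                        delta = b$delta, beta1 = b$beta1, beta2 = b$beta2,
                        beta3 = b$beta3, phi1 = b$phi1, phi2 = b$phi2,
                        phi3 = b$phi3, I_baseline = b$I_baseline,
                        alpha = raw$alphas[2])
    th <- raw$therapy
    therapy <- therapy_params(base, eps1 = th$eps1, eps2 = th$eps2,
                              eps3 = th$eps3, eps4 = th$eps4, tau = th$tau)
    structure(list(
      name = name,
      base = base, therapy = therapy,
      init = c(N = raw$init$N0, I = raw$init$I0, P = raw$init$P0,
               T = raw$init$T0),
      aux_init = c(W0 = raw$init$W0, V0 = raw$init$V0),
      alphas = raw$alphas,
      grid = raw$grid, control_grid = raw$control_grid,
      phi_control = unlist(raw$phi_control),
      unused = list(theta_scalar = raw$theta_scalar, eta = raw$eta,
                    alpha_control = raw$alpha_control),
      raw = raw), class = "sim_preset")
  } else {
    k <- unlist(raw$k)
    structure(list(
      name = name,
      kmodel = kmodel_params(k, alpha = raw$alpha),
      init = c(C = raw$init$C0, Pk = raw$init$Pk0, S = raw$init$S0,
               E = raw$init$E0, Nk = raw$init$Nk0, Ik = raw$init$Ik0),
      alphas = raw$alpha,
      grid = raw$grid,
      k_defaults = c("k13", "k14"),
      raw = raw), class = "sim_preset")
  }
}

#' @export
print.sim_preset <- function(x, ...) {
  cat(sprintf("simulation preset '%s'\n", x$name))
  cat("  initial state:", paste(sprintf("%s = %g", names(x$init), x$init),
                                collapse = ", "), "\n")
  cat(sprintf("  grid: [%g, %g], h = %g; alpha: %s\n",
              x$grid$t0, x$grid$t_final, x$grid$h,
              paste(x$alphas, collapse = ", ")))
  invisible(x)
}
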