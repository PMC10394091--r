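ps <- load_preset("lung-ref")

test_that("analytic Jacobian matches structure and finite differences", {
  p <- ps$base
  J <- jacobian_base(p, c(p$K, 0, 0))
  expect_equal(J[1, 1], -p$lam)
  expect_equal(unname(diag(jacobian_base(p, c(0, 0, 0)))),
               c(p$lam, -p$phi3, -p$delta))
  set.seed(7)
  for (rep in 1:5) {
    st <- runif(3, 0, 5000)
    J <- jacobian_base(p, st)
    Jfd <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- rep(0, 3); e[j] <- 1e-6 * max(1, abs(st[j]))
      Jfd[, j] <- (base_rhs(st + e, p) - base_rhs(st - e, p)) / (2 * e[j])
    }
    expect_lt(max(abs(J - Jfd)) / max(1, max(abs(J))), 1e-5)
  }
})

test_that("equilibrium search finds the tumor-free state of the reference set", {
  eq <- find_equilibria(ps$base)
  expect_gt(length(eq), 0)
  kinds <- vapply(eq, function(e) e$kind, character(1))
  expect_true("tumor-free-with-immunity" %in% kinds)
  tf <- eq[[which(kinds == "tumor-free-with-immunity")[1]]]
  # I* = phi1 * I_baseline / phi3 = 0.03 * 90 / 0.01 = 270
  expect_equal(unname(tf$state), c(0, 270, 0), tolerance = 1e-9)
  for (e in eq) expect_lte(max(abs(base_rhs(e$state, ps$base))), 1e-8)
})

test_that("the constructed tumor-free root has zero residual for random parameters", {
  set.seed(11)
  for (rep in 1:5) {
    p <- base_params(lam = runif(1, 0.05, 0.5), K = 10^runif(1, 2, 4),
                     mu = runif(1, 0, 0.05), gamma = runif(1, 0, 0.1),
                     delta = runif(1, 0, 0.01), beta1 = runif(1, 0, 0.05),
                     beta2 = runif(1, 0, 0.05), beta3 = runif(1, 0, 0.05),
                     phi1 = runif(1, 0.01, 0.1), phi2 = runif(1, 0, 0.1),
                     phi3 = runif(1, 0.005, 0.05),
                     I_baseline = runif(1, 10, 200))
    st <- c(0, p$phi1 * p$I_baseline / p$phi3, 0)
    expect_equal(max(abs(base_rhs(st, p))), 0)
  }
})

test_that("equilibrium search is deterministic for a fixed seed", {
  e1 <- find_equilibria(ps$base, n_starts = 10, seed = 42)
  e2 <- find_equilibria(ps$base, n_starts = 10, seed = 42)
  expect_identical(lapply(e1, `[[`, "state"), lapply(e2, `[[`, "state"))
})

test_that("Routh-Hurwitz verdicts match the worked examples in both conventions", {
  expect_equal(routh_hurwitz_cubic(c(3, 3, 1), "monic")$verdict, "stable")
  expect_equal(routh_hurwitz_cubic(c(0, -1, 0), "monic")$verdict, "unstable")
  expect_false(routh_hurwitz_cubic(c(0, -1, 0), "monic")$verdict == "stable")
  expect_equal(routh_hurwitz_cubic(c(1, 1, 1), "monic")$verdict, "marginal")
  # determinant convention: -l^3 + T1 l^2 + T2 l + T3 with T = -a
  rT <- routh_hurwitz_cubic(c(-3, -3, -1), "T")
  expect_equal(unname(rT$monic), c(3, 3, 1))
  expect_equal(rT$verdict, "stable")
  expect_error(routh_hurwitz_cubic(c(1, 2), "monic"), "cubic")
})

test_that("companion eigenvalues satisfy the monic characteristic polynomial", {
  set.seed(3)
  for (rep in 1:20) {
    a <- runif(3, -5, 5)
    r <- routh_hurwitz_cubic(a, "monic")
    ev <- r$eigenvalues
    resid <- ev^3 + a[1] * ev^2 + a[2] * ev + a[3]
    expect_lt(max(Mod(resid)), 1e-8)
  }
})

test_that("stability report is internally consistent at the tumor-free state", {
  eq <- find_equilibria(ps$base)
  tf <- eq[[which(vapply(eq, `[[`, "", "kind") ==
                    "tumor-free-with-immunity")[1]]]
  sr <- stability_report(ps$base, tf$state)
  expect_equal(sr$verdict, "stable")
  ev <- sr$eigenvalues
  a <- sr$char_monic
  expect_lt(max(Mod(ev^3 + a[1] * ev^2 + a[2] * ev + a[3])) /
              max(1, max(Mod(ev))^3), 1e-8)
  expect_true(all(Re(ev) < 0))
})

test_that("Lyapunov trace behaves on constant, decaying and arbitrary trajectories", {
  eq <- structure(list(state = c(1, 2), residual = 0, kind = "other"),
                  class = "equilibrium")
  const <- list(times = 0:10, states = matrix(rep(c(1, 2), each = 11), 11))
  lt <- lyapunov_trace(const, eq)
  expect_true(all(lt$V == 0))
  expect_equal(lt$frac_nonincreasing, 1)

  t <- seq(0, 5, by = 0.1)
  decay <- list(times = t, states = cbind(3 * exp(-t), -2 * exp(-t)))
  lt <- lyapunov_trace(decay, c(0, 0))
  expect_equal(lt$frac_nonincreasing, 1)
  expect_equal(lt$settle_index, 1)

  set.seed(5)
  wander <- list(times = 1:50, states = matrix(rnorm(100), 50))
  lt <- lyapunov_trace(wander, c(0.3, -0.1))
  expect_true(all(lt$V >= 0))
  expect_error(lyapunov_trace(decay, c(0, 0, 0)), "dimension")
})

test_that("reproduction ratios follow their defining formulas and scale law", {
  p <- ps$base
  for (rule in c("max-real-part", "max-modulus")) {
    rep <- reproduction_numbers(p, dominance = rule)
    expect_equal(rep$R0, p$beta1 * p$phi1 / (rep$lambda1 * p$mu))
    expect_equal(rep$Rc,
                 p$beta2 * p$gamma * p$phi2 / (rep$lambda1 * p$mu * p$phi3))
  }
  # scaling beta1 and phi1 by c multiplies R0 by c^2 exactly (lambda1 and
  # mu are untouched: neither enters the disease-free Jacobian)
  r1 <- reproduction_numbers(p)
  p2 <- p; p2$beta1 <- 3 * p$beta1; p2$phi1 <- 3 * p$phi1
  r2 <- reproduction_numbers(p2)
  expect_equal(r2$R0, 9 * r1$R0)
  expect_equal(r2$Rc, r1$Rc)
})

test_that("dominant eigenvalue of the reference literal Jacobian is -phi3", {
  rep <- reproduction_numbers(ps$base, dominance = "max-real-part")
  expect_equal(rep$lambda1, -ps$base$phi3)
  expect_equal(rep$dfe, c(N = ps$base$K, I = 0, P = 0))
})

test_that("zero dominant eigenvalue raises an undefined-ratio error", {
  p <- base_params(lam = 0.3, K = 100, mu = 0.01, gamma = 0, delta = 0,
                   beta1 = 0.01, beta2 = 0.01, beta3 = 0.04, phi1 = 0.03,
                   phi2 = 0.04, phi3 = 0.01, I_baseline = 90)
  expect_error(reproduction_numbers(p), "undefined")
})

test_that("the interpretation table spans both phi sets and both dominance rules", {
  tab <- reproduction_table(ps)
  expect_equal(nrow(tab), 4)
  expect_true(all(is.finite(tab$R0)) && all(is.finite(tab$Rc)))
  expect_setequal(unique(tab$phi_set), c("dynamics", "control"))
  expect_setequal(unique(tab$dominance), c("max-real-part", "max-modulus"))
})
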