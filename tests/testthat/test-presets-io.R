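test_that("the frozen presets carry the reference constants", {
  ps <- load_preset("lung-ref")
  expect_equal(ps$base$lam, 0.3)
  expect_equal(ps$base$K, 10000)
  expect_equal(ps$base$mu, 0.01)
  expect_equal(ps$base$gamma, 0.07)
  expect_equal(ps$base$delta, 0.001)
  expect_equal(unname(ps$init[c("N", "I", "P", "T")]), c(3000, 90, 20, 0))
  expect_equal(ps$grid$h, 2^-6)
  expect_equal(ps$grid$t_final, 400)
  expect_equal(ps$alphas, c(0.5, 0.7, 0.9))
  expect_equal(ps$therapy$tau, 5)
  expect_equal(unname(ps$phi_control[c("phi1", "phi2", "phi3")]),
               c(0.9, 0.458, 0.8))
  expect_equal(unname(ps$aux_init), c(100, 50))
  expect_equal(ps$unused$theta_scalar, 0.5)
  expect_equal(ps$unused$eta, 0.7)

  kp <- load_preset("stemcell-ref")
  expect_equal(unname(kp$kmodel$k[c("k1", "k2", "k8", "k11", "k12")]),
               c(0.35, 0.2, 0.05, 1.0, 0.1))
  expect_equal(kp$kmodel$alpha, 0.8)
  expect_equal(unname(kp$init[c("C", "S", "Nk")]), c(100, 100, 10))
  expect_equal(kp$k_defaults, c("k13", "k14"))
})

test_that("preset fixtures on disk are byte-identical to the frozen checksums", {
  md5 <- function(nm) unname(tools::md5sum(
    system.file("extdata", "presets", paste0(nm, ".json"),
                package = "fractumor")))
  expect_equal(md5("lung-ref"), "12e719ad24331494a67e1d4509605686")
  expect_equal(md5("stemcell-ref"), "123203b39816d4c06d6870686afbc9fe")
})

test_that("unknown presets fail with the list of available names", {
  expect_error(load_preset("nosuch"), "lung-ref")
  expect_error(load_preset("nosuch"), "stemcell-ref")
})

test_that("configured runs are bit-reproducible across repeats", {
  cfg <- run_config(preset = "stemcell-ref", variant = "kmodel",
                    alphas = c(0.5, 0.7, 0.9),
                    grid = list(t0 = 0, t_final = 10, h = 2^-6))
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_equal(names(s1), c("alpha_0.5", "alpha_0.7", "alpha_0.9"))
  for (nm in names(s1)) expect_identical(s1[[nm]]$states, s2[[nm]]$states)
})

test_that("therapy run with zero efficacies reproduces the base run", {
  ps <- load_preset("lung-ref")
  tp0 <- therapy_params(ps$base, eps1 = 0, eps2 = 0, eps3 = 0, eps4 = 0,
                        tau = 5)
  pr_b <- fde_problem(make_rhs(ps$base, "base"), ps$init[1:3], 0, 2,
                      h = 2^-8, alpha = 0.9)
  pr_t <- fde_problem(make_rhs(tp0, "therapy"), ps$init, 0, 2, h = 2^-8,
                      alpha = 0.9)
  sb <- suppressWarnings(solve_fde(pr_b))
  st <- suppressWarnings(solve_fde(pr_t))
  # equal to rounding error (state dimension changes the BLAS summation
  # path, so bit identity is not guaranteed)
  expect_lt(max(abs(st$states[, 1:3] - sb$states)) / max(abs(sb$states)),
            1e-12)
  expect_true(all(st$states[, 4] == 0))
})

test_that("config hashing is stable and writing artifacts is deterministic", {
  cfg1 <- run_config(preset = "stemcell-ref", variant = "kmodel",
                     grid = list(t0 = 0, t_final = 5, h = 2^-6))
  cfg2 <- run_config(preset = "stemcell-ref", variant = "kmodel",
                     grid = list(t0 = 0, t_final = 5, h = 2^-6))
  expect_equal(cfg1$hash, cfg2$hash)
  cfg3 <- run_config(preset = "stemcell-ref", variant = "kmodel",
                     grid = list(t0 = 0, t_final = 6, h = 2^-6))
  expect_false(cfg1$hash == cfg3$hash)

  out1 <- file.path(tempdir(), "runA"); out2 <- file.path(tempdir(), "runB")
  for (o in c(out1, out2)) {
    cfg <- run_config(preset = "stemcell-ref", variant = "kmodel",
                      alphas = 0.8, grid = list(t0 = 0, t_final = 5, h = 2^-6),
                      outdir = o)
    run_simulation(cfg)
  }
  f1 <- file.path(out1, "kmodel_alpha_0.8.csv")
  f2 <- file.path(out2, "kmodel_alpha_0.8.csv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("exactly one of preset and inline parameters must be given", {
  expect_error(run_config(), "exactly one")
  expect_error(run_config(preset = "lung-ref",
                          params = load_preset("lung-ref")$base),
               "exactly one")
  expect_error(run_config(params = load_preset("lung-ref")$base,
                          variant = "base"), "init")
})

test_that("trajectory CSV round-trips beyond 15 significant digits, long and wide", {
  sol <- solve_fde(fde_problem(function(t, y, u) -y, c(x = pi), 0, 1,
                               h = 2^-5, alpha = 0.7))
  for (long in c(TRUE, FALSE)) {
    f <- tempfile(fileext = ".csv")
    write_trajectory_csv(sol, f, long = long)
    back <- read_trajectory_csv(f)
    expect_equal(back$t, sol$times, tolerance = 1e-15)
    expect_equal(back$x, unname(sol$states[, 1]), tolerance = 1e-15)
  }
})

test_that("solution JSON round-trips states, input and metadata", {
  sol <- solve_fde(fde_problem(function(t, y, u) -y + u, c(x = 1), 0, 1,
                               h = 2^-5, alpha = 0.8),
                   input = function(t) cos(t))
  f <- tempfile(fileext = ".json")
  write_solution_json(sol, f)
  back <- read_solution_json(f)
  expect_equal(back$states, sol$states, tolerance = 1e-15)
  expect_equal(back$times, sol$times, tolerance = 1e-15)
  expect_equal(back$input, sol$input, tolerance = 1e-15)
  expect_equal(back$metadata$alpha, 0.8)
})

test_that("flat model configs load from JSON and YAML and reject unknown keys", {
  kv <- list(lam = 0.3, K = 1e4, mu = 0.01, gamma = 0.07, delta = 0.001,
             beta1 = 0.01, beta2 = 0.01, beta3 = 0.04, phi1 = 0.03,
             phi2 = 0.04, phi3 = 0.01, I_baseline = 90, eps1 = 0.5,
             eps2 = 0.5, eps3 = 0.5, eps4 = 0.5, tau = 5)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(kv, fj, auto_unbox = TRUE, digits = NA)
  pj <- load_model_config(fj)
  expect_s3_class(pj, "therapy_params")
  expect_equal(pj$eps1, 0.5)
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(kv, fy)
  py <- load_model_config(fy)
  expect_equal(unclass(py)[order(names(py))], unclass(pj)[order(names(pj))])

  bad <- c(kv, list(zeta = 1))
  jsonlite::write_json(bad, fj, auto_unbox = TRUE, digits = NA)
  expect_error(load_model_config(fj), "zeta")

  kk <- as.list(stats::setNames(rep(0.1, 14), paste0("k", 1:14)))
  kk$alpha <- 0.8
  jsonlite::write_json(kk, fj, auto_unbox = TRUE, digits = NA)
  expect_s3_class(load_model_config(fj), "kmodel_params")
})
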