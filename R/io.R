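#' Assemble a reproducible run configuration
#'
#' Exactly one of `preset` / `params` must be given. The configuration is
#' hashed (MD5 of its canonical JSON) so every artifact a run writes can be
#' traced back to it.
#'
#' @param preset preset name (see [preset_names()]) or `NULL`.
#' @param params inline parameter container (with `init` required) or
#'   `NULL`.
#' @param variant model variant: `"base"`, `"therapy"`, `"feedback"` or
#'   `"kmodel"`.
#' @param alphas fractional orders to run (default: the preset's).
#' @param init initial state override.
#' @param grid list with `t0`, `t_final`, `h` overriding the preset grid.
#' @param outdir output directory or `NULL` (no files written).
#' @param seed integer seed recorded with the run (only the multistart
#'   equilibrium search consumes randomness; the dynamics are
#'   deterministic).
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = NULL, params = NULL,
                       variant = c("base", "therapy", "feedback", "kmodel"),
                       alphas = NULL, init = NULL, grid = NULL,
                       outdir = NULL, seed = 20230801L) {
  variant <- match.arg(variant)
  if (is.null(preset) == is.null(params))
    stop("give exactly one of `preset` or `params`", call. = FALSE)
  if (!is.null(preset)) {
    ps <- load_preset(preset)
    params_use <- switch(variant,
                         base = ps$base,
                         therapy = ,
                         feedback = ps$therapy,
                         kmodel = ps$kmodel)
    if (is.null(params_use))
      stop(sprintf("preset '%s' does not parameterise variant '%s'",
                   preset, variant), call. = FALSE)
    if (is.null(init)) {
      init <- ps$init
      if (variant == "base" && length(init) > 3L) init <- init[1:3]
    }
    if (is.null(alphas)) alphas <- ps$alphas
    if (is.null(grid)) grid <- ps$grid
  } else {
    params_use <- params
    if (is.null(init) || is.null(grid))
      stop("inline `params` require `init` and `grid`", call. = FALSE)
    if (is.null(alphas))
      alphas <- if (inherits(params, "kmodel_params")) params$alpha
                else params$alpha
  }
  cfg <- list(preset = preset, variant = variant, params = params_use,
              alphas = alphas, init = init, grid = grid, outdir = outdir,
              seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  cfg$outdir <- NULL   # where outputs land does not change what is computed
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Execute a configured simulation run
#'
#' Solves the configured variant with [solve_fde()] once per requested
#' fractional order. When `outdir` is set, writes one trajectory CSV per
#' order, a JSON report with metadata and final states, and a plain-text
#' log (package version, configuration hash, wall time); outputs are
#' deterministic, so re-running a configuration reproduces them
#' byte-for-byte.
#'
#' @param config a [run_config()].
#' @param long write trajectories in long format (default) or wide.
#' @return named list of `fde_solution` objects (one per alpha), invisibly
#'   when files are written.
#' @export
run_simulation <- function(config, long = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  rhs <- make_rhs(config$params, config$variant)
  sols <- list()
  for (a in config$alphas) {
    pr <- fde_problem(rhs, config$init, t0 = config$grid$t0,
                      t_final = config$grid$t_final, h = config$grid$h,
                      alpha = a, name = config$variant)
    sols[[sprintf("alpha_%g", a)]] <- solve_fde(pr)
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(sols)) {
      write_trajectory_csv(
        sols[[nm]],
        file.path(config$outdir, sprintf("%s_%s.csv", config$variant, nm)),
        run_id = config$hash, long = long)
      write_solution_json(
        sols[[nm]],
        file.path(config$outdir, sprintf("%s_%s.json", config$variant, nm)))
    }
    log <- c(sprintf("fractumor %s", as.character(utils::packageVersion("fractumor"))),
             sprintf("config hash: %s", config$hash),
             sprintf("variant: %s; alphas: %s", config$variant,
                     paste(config$alphas, collapse = ", ")),
             sprintf("wall time: %.2f s",
                     as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
    writeLines(log, file.path(config$outdir, "run.log"))
    return(invisible(sols))
  }
  sols
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a trajectory to CSV
#'
#' Long format (default) has columns `run_id, t, variable, value`; wide
#' format has `t`, one column per state and optionally `u`. Floats are
#' written with 17 significant digits so a read-back reproduces them
#' exactly (round-trip beyond 15 significant digits).
#'
#' @param sol an `fde_solution`.
#' @param path output file.
#' @param run_id identifier recorded in long format (default the rhs name).
#' @param long logical.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sol, path, run_id = sol$metadata$rhs,
                                 long = TRUE) {
  df <- as.data.frame(sol)
  if (long) {
    vars <- setdiff(names(df), "t")
    out <- do.call(rbind, lapply(vars, function(v)
      data.frame(run_id = run_id, t = fmt17(df$t), variable = v,
                 value = fmt17(df[[v]]))))
  } else {
    out <- data.frame(lapply(df, fmt17), check.names = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV file.
#' @return data.frame in wide format (`t` plus one column per variable).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("run_id", "variable", "value") %in% names(df))) {
    wide <- stats::reshape(df[, c("t", "variable", "value")],
                           idvar = "t", timevar = "variable",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide$t <- as.numeric(wide$t)
    wide[-1] <- lapply(wide[-1], as.numeric)
    rownames(wide) <- NULL
    wide[order(wide$t), , drop = FALSE]
  } else {
    df[] <- lapply(df, as.numeric)
    df
  }
}

#' Serialise a solution (with metadata) to JSON
#'
#' Full-precision JSON (`digits = NA`) containing times, states, input and
#' metadata; [read_solution_json()] restores an equivalent `fde_solution`.
#'
#' @param sol an `fde_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(sol, path) {
  payload <- list(times = sol$times, states = sol$states,
                  state_names = colnames(sol$states),
                  input = sol$input,
                  metadata = sol$metadata[c("alpha", "h", "rhs",
                                            "corrector_iters")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_solution_json
#' @export
read_solution_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- matrix(as.numeric(x$states), nrow = length(x$times))
  colnames(states) <- x$state_names
  structure(list(times = as.numeric(x$times), states = states,
                 input = if (is.null(x$input)) NULL else as.numeric(x$input),
                 metadata = x$metadata),
            class = "fde_solution")
}

#' Load model parameters from a flat configuration file
#'
#' Reads a flat key-value JSON or YAML file (by extension) into a parameter
#' container. Recognised layouts: the base/therapy keys of [base_params()]
#' and [therapy_params()], or `k1...k14` (+ `alpha`) for
#' [kmodel_params()]. Unknown keys are rejected.
#'
#' @param path configuration file (`.json`, `.yaml` or `.yml`).
#' @return a parameter container.
#' @export
load_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  kv <- switch(ext,
               json = jsonlite::read_json(path, simplifyVector = TRUE),
               yaml = ,
               yml = yaml::read_yaml(path),
               stop("config must be .json, .yaml or .yml", call. = FALSE))
  if (!is.list(kv) || is.null(names(kv)) || any(names(kv) == ""))
    stop("config must be a flat named key-value mapping", call. = FALSE)
  kv <- lapply(kv, function(v) if (is.character(v)) as.numeric(v) else v)
  knames <- paste0("k", 1:14)
  base_names <- c("lam", "K", "mu", "gamma", "delta", "beta1", "beta2",
                  "beta3", "phi1", "phi2", "phi3", "I_baseline", "alpha")
  ther_names <- c(base_names, "eps1", "eps2", "eps3", "eps4", "tau")
  nm <- names(kv)
  if (all(nm %in% c(knames, "alpha"))) {
    if (!all(knames %in% nm))
      stop("k-model config must provide k1...k14", call. = FALSE)
    return(kmodel_params(unlist(kv[knames]),
                         alpha = if ("alpha" %in% nm) kv$alpha else 1))
  }
  if (!all(nm %in% ther_names))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(setdiff(nm, ther_names), collapse = ", ")),
         call. = FALSE)
  base <- do.call(base_params, kv[intersect(nm, base_names)])
  if (any(c("eps1", "eps2", "eps3", "eps4") %in% nm)) {
    do.call(therapy_params,
            c(list(base = base),
              kv[intersect(nm, c("eps1", "eps2", "eps3", "eps4", "tau"))]))
  } else base
}
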