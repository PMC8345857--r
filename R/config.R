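#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing one experiment and
#' returns a fully validated configuration with all defaults applied.
#' Recognised top-level keys: `experiment` (one of `simulate`, `steady`,
#' `converge`, `sweep`, `manifold`, `calibrate`, `fit`), `preset`,
#' `geometry`, `params`, `mesh`, `initial_condition`, `solver`, `sweep`,
#' `output_dir`, `rng_seed`. Unknown keys anywhere are rejected with the
#' offending path, as are out-of-range parameter values.
#'
#' @param path Path to the configuration file.
#' @return An object of class `"tau_config"`: `experiment`, `model`
#'   (a `"tau_model"`), `ic_spec`, `opts`, `sweep`, `output_dir`,
#'   `rng_seed`, and `raw` (the parsed document).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a key-value document")
  known <- c("experiment", "preset", "geometry", "params", "mesh",
             "initial_condition", "solver", "sweep", "output_dir", "rng_seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  experiments <- c("simulate", "steady", "converge", "sweep", "manifold",
                   "calibrate", "fit")
  experiment <- raw$experiment %||% "simulate"
  if (!experiment %in% experiments)
    stop("experiment must be one of: ", paste(experiments, collapse = ", "))

  geo_known <- c("sd_pre", "ais", "axon", "cleft", "sd_post")
  check_keys(raw$geometry, geo_known, "geometry")
  layout <- do.call(build_layout, raw$geometry %||% list())

  par_known <- c("D_n", "f", "v_a", "v_r", "beta", "gamma", "delta",
                 "epsilon", "lam", "scale_sd_diffusion")
  check_keys(raw$params, par_known, "params")
  par_args <- raw$params %||% list()
  if (!is.null(raw$preset)) {
    params <- do.call(tau_preset, c(list(name = raw$preset), par_args))
  } else {
    params <- do.call(tau_params, par_args)
  }

  mesh_known <- c("coarse_h", "fine_h", "refine_width")
  check_keys(raw$mesh, mesh_known, "mesh")
  model <- do.call(tau_model, c(list(params = params, layout = layout),
                                raw$mesh %||% list()))

  ic_known <- c("kind", "c0", "seed_side", "seed_dose", "rng_seed",
                "target_mass")
  check_keys(raw$initial_condition, ic_known, "initial_condition")
  ic_spec <- raw$initial_condition %||% list(kind = "axonal_uniform")
  if (!(ic_spec$kind %||% "axonal_uniform") %in%
      c("axonal_uniform", "sd_seed", "random"))
    stop("initial_condition$kind must be axonal_uniform, sd_seed or random")

  sol_known <- c("t_end", "output_times", "n_output", "rel_tol", "abs_tol",
                 "steady_tol", "max_steps")
  check_keys(raw$solver, sol_known, "solver")
  opts <- do.call(solver_options, raw$solver %||% list())

  sweep_known <- c("delta", "epsilon", "gamma_scale", "beta_scale", "n_seeds")
  check_keys(raw$sweep, sweep_known, "sweep")

  structure(list(experiment = experiment, model = model, ic_spec = ic_spec,
                 opts = opts, sweep = raw$sweep %||% list(),
                 output_dir = raw$output_dir %||% ".",
                 rng_seed = raw$rng_seed %||% 1L, raw = raw),
            class = "tau_config")
}

check_keys <- function(block, known, where) {
  if (is.null(block)) return(invisible(NULL))
  if (!is.list(block)) stop(sprintf("config block '%s' must be a mapping", where))
  bad <- setdiff(names(block), known)
  if (length(bad))
    stop(sprintf("unknown config key: %s", paste0(where, "$", bad[1])))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialise the initial condition described by a config
#'
#' @param config A `"tau_config"`.
#' @return A `"tau_state"`.
#' @export
config_ic <- function(config) {
  spec <- config$ic_spec
  switch(spec$kind %||% "axonal_uniform",
         axonal_uniform = axonal_uniform_ic(config$model,
                                            c0 = spec$c0 %||% 0.2),
         sd_seed = sd_seed_ic(config$model, side = spec$seed_side %||% "pre",
                              dose = spec$seed_dose),
         random = random_ic(config$model,
                            seed = spec$rng_seed %||% config$rng_seed,
                            target_mass = spec$target_mass))
}

#' Write a trajectory as a long-format CSV table
#'
#' Columns: `time_s`, `x_um`, `compartment`, `n_uM`, `m_uM`.
#'
#' @param traj A `"tau_trajectory"`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write a bias time series as CSV
#'
#' @param series A `"tau_bias_series"` from [bias_timeseries()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bias_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write a manifold result as JSON
#'
#' @param manifold A `"tau_manifold"`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_manifold_json <- function(manifold, path) {
  jsonlite::write_json(list(slope = manifold$slope,
                            intercept = manifold$intercept,
                            residual = manifold$residual,
                            roots = manifold$roots),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Echoes the configuration, package version and seed to a JSON sidecar so
#' a deterministic run can be reproduced bit-identically.
#'
#' @param config A `"tau_config"` (or any serialisable list).
#' @param path Output file.
#' @param extra Optional named list of additional entries (e.g. solver
#'   diagnostics, total-mass trace).
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, path, extra = NULL) {
  manifest <- list(
    package = "tauspread",
    version = as.character(utils::packageVersion("tauspread")),
    rng_seed = if (inherits(config, "tau_config")) config$rng_seed else NULL,
    config = if (inherits(config, "tau_config")) config$raw else config,
    written = format(Sys.time(), tz = "UTC"))
  if (!is.null(extra)) manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
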