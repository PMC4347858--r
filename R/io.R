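# Tabular I/O (comma-separated, UTF-8, header row, '.' decimal), JSON run
# configuration and run manifests.

#' Write / read a prevalence trajectory
#'
#' The CSV has columns `generation`, `prevalence`; model parameters go to a
#' JSON sidecar (`<path>.params.json`) so the run can be reproduced.
#'
#' @param trajectory A `wolb_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "wolb_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  pars <- trajectory$params
  jsonlite::write_json(
    list(mu = pars$mu, F_rel = pars$F_rel, H = pars$H, w = pars$w,
         p0 = trajectory$p[1], generations = trajectory$generations),
    paste0(path, ".params.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".params.json"),
                              simplifyVector = TRUE)
  structure(
    list(params = model_params(mu = meta$mu, F_rel = meta$F_rel,
                               H = meta$H, w = meta$w),
         generations = meta$generations, p = df$prevalence),
    class = "wolb_trajectory")
}

#' Write / read a long-format count table
#'
#' Columns `group`, `replicate`, `infected`, `total`.
#'
#' @param table A count table data frame.
#' @param path CSV path.
#' @return `path` (write) or the validated table (read).
#' @export
write_count_table <- function(table, path) {
  check_count_table(table)
  utils::write.csv(table[, c("group", "replicate", "infected", "total")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  check_count_table(utils::read.csv(path))
}

#' Write / read a long-format fitness dataset
#'
#' Columns `arm`, `replicate`, `trait`, `value`, `trials`.
#'
#' @param data A fitness data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_fitness_data <- function(data, path) {
  if (is.null(data$trials)) data$trials <- NA_real_
  utils::write.csv(data[, c("arm", "replicate", "trait", "value", "trials")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fitness_data
#' @export
read_fitness_data <- function(path) {
  utils::read.csv(path)
}

run_config_schema <- list(
  simulate = c("panel", "generations", "w", "p0", "mu"),
  equilibria = c("mu", "F_rel", "H", "w_grid"),
  abm = c("p0", "n_hosts", "visit_prob", "infect_prob", "survive_prob",
          "infectious_visits", "kill_hosts", "mu", "F_rel", "H",
          "generations", "replicates"),
  synth = c("experiment", "params"),
  analyze = c("analysis", "input")
)

#' Load and validate a JSON run configuration
#'
#' A configuration names a `subcommand` (`simulate`, `equilibria`, `abm`,
#' `synth`, `analyze`) plus that subcommand's parameter block; unknown keys
#' are rejected by name. Stochastic subcommands (`abm`, `synth`) require a
#' `seed`.
#'
#' @param path Path to a JSON file.
#' @return A validated list of class `wolb_run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$subcommand) ||
      !cfg$subcommand %in% names(run_config_schema))
    stop("config must name a subcommand: ",
         paste(names(run_config_schema), collapse = ", "), call. = FALSE)
  common <- c("subcommand", "seed", "out_dir", "log_level")
  allowed <- c(common, run_config_schema[[cfg$subcommand]])
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (cfg$subcommand %in% c("abm", "synth") && is.null(cfg$seed))
    stop("'seed' is required for subcommand '", cfg$subcommand, "'",
         call. = FALSE)
  structure(cfg, class = "wolb_run_config")
}

#' Save a run configuration to JSON
#'
#' Round-trips with [load_run_config()].
#'
#' @param cfg A `wolb_run_config` (or plain list with the same fields).
#' @param path Output path.
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_manifest <- function(out_dir, cfg, files) {
  jsonlite::write_json(
    list(config = unclass(cfg),
         files = files,
         package_version = as.character(utils::packageVersion("wolbdyn")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

#' Execute a run configuration
#'
#' Dispatches the configured subcommand to the corresponding package
#' functions and writes CSV artifacts plus a `manifest.json` (configuration,
#' seed, package and R versions) into `out_dir`. Stochastic subcommands are
#' byte-reproducible from the manifest.
#'
#' @param cfg A `wolb_run_config` (see [load_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a character vector of files written.
#' @export
run_config <- function(cfg, out_dir) {
  cfg <- validate_run_config(unclass(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grab <- function(name, default) if (is.null(cfg[[name]])) default
  else cfg[[name]]
  files <- character(0)
  if (cfg$subcommand == "simulate") {
    trs <- scenario_trajectories(
      panel = grab("panel", "A"),
      generations = grab("generations", 1000),
      w = grab("w", c(0, 0.01, 0.06)),
      p0 = grab("p0", 0.01), mu = grab("mu", 0.03))
    for (nm in names(trs)) {
      f <- file.path(out_dir, paste0("trajectory_", gsub("=", "", nm), ".csv"))
      write_trajectory(trs[[nm]], f)
      files <- c(files, f)
    }
  } else if (cfg$subcommand == "equilibria") {
    sweep <- equilibrium_sweep(
      mu = grab("mu", 0.03), F_rel = grab("F_rel", 1), H = grab("H", 1),
      w_grid = grab("w_grid", seq(0, 0.1, by = 0.005)))
    f <- file.path(out_dir, "equilibria.csv")
    utils::write.csv(sweep, f, row.names = FALSE)
    files <- f
  } else if (cfg$subcommand == "abm") {
    vp <- vector_params(
      n_hosts = grab("n_hosts", 1e4), visit_prob = grab("visit_prob", 0.3),
      infect_prob = grab("infect_prob", 0.938),
      survive_prob = grab("survive_prob", 0.302),
      infectious_visits = grab("infectious_visits", 1),
      kill_hosts = grab("kill_hosts", FALSE))
    mp <- model_params(mu = grab("mu", 0.03), F_rel = grab("F_rel", 1),
                       H = grab("H", 1))
    res <- simulate_abm(grab("p0", 0.1), vp, mp,
                        grab("generations", 20),
                        grab("replicates", 5), seed = cfg$seed)
    f <- file.path(out_dir, "abm.csv")
    utils::write.csv(as.data.frame(res), f, row.names = FALSE)
    files <- f
  } else if (cfg$subcommand == "synth") {
    pars <- as.list(grab("params", list()))
    pars$seed <- cfg$seed
    experiment <- grab("experiment", "persistence")
    gen <- switch(experiment,
                  transmission = gen_transmission,
                  persistence = gen_persistence,
                  decay = gen_decay,
                  fitness = gen_fitness,
                  stop("unknown experiment: ", experiment, call. = FALSE))
    dat <- do.call(gen, pars)
    f <- file.path(out_dir, paste0("synth_", experiment, ".csv"))
    if (experiment == "transmission")
      utils::write.csv(as.data.frame(unclass(dat)), f, row.names = FALSE)
    else if (experiment == "fitness") write_fitness_data(dat, f)
    else write_count_table(dat, f)
    files <- f
  } else if (cfg$subcommand == "analyze") {
    analysis <- grab("analysis", "heterogeneity")
    res <- switch(analysis,
                  heterogeneity = lrt_heterogeneity(
                    read_count_table(cfg$input)),
                  trend = logistic_trend(read_count_table(cfg$input)),
                  fitness = fitness_compare(read_fitness_data(cfg$input)),
                  prevalence = logit_prevalence_fit(
                    read_count_table(cfg$input)),
                  stop("unknown analysis: ", analysis, call. = FALSE))
    f <- file.path(out_dir, paste0("analysis_", analysis, ".csv"))
    utils::write.csv(res, f, row.names = FALSE)
    files <- f
  }
  write_manifest(out_dir, cfg, basename(files))
  invisible(c(files, file.path(out_dir, "manifest.json")))
}
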