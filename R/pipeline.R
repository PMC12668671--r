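#' Build an effective run configuration
#'
#' Reads an optional YAML file (or takes a nested list) and merges it over
#' the package defaults, so every run is fully described by one serialisable
#' object. Unknown keys are kept verbatim. The effective configuration is
#' echoed into each run's log for provenance.
#'
#' @param config Path to a YAML file, a nested list, or `NULL` for pure
#'   defaults.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(config = NULL) {
  defaults <- list(
    seed = 1L,
    constants = list(),  # overrides for env_constants()
    simulate = list(phenotype = "brave", params = NULL, n_turns = 200L,
                    depth = 5L),
    synth = list(groups = c("brave", "intermediate", "timid"),
                 noise_sd = 0, n_minutes = 100L),
    fit = list(target_type = "synthetic_model", phenotype = "timid",
               record = NULL, B = 16L, T_gen = 5L, percentile = 0.3,
               n_turns = 200L, depth = 5L)
  )
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    out <- tryCatch(yaml::read_yaml(config), error = function(e) {
      stop("could not parse YAML config ", config, ": ",
           conditionMessage(e), call. = FALSE)
    })
    if (is.null(out)) list() else out
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a file path, a list, or NULL", call. = FALSE)
  }
  merge_lists <- function(base, override) {
    for (k in names(override)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
        merge_lists(base[[k]], override[[k]])
      } else {
        override[[k]]
      }
    }
    base
  }
  structure(merge_lists(defaults, user), class = "run_config")
}

# Internal: constants with config overrides applied.
config_constants <- function(config) {
  do.call(env_constants, config$constants)
}

# Internal: resolve the agent parameters a config describes.
config_params <- function(block) {
  if (!is.null(block$params)) {
    p <- block$params
    agent_params(mu = unlist(p$mu), v = unlist(p$v), alpha = p$alpha,
                 G0 = p$G0, f = p$f)
  } else {
    phenotype_params(block$phenotype)
  }
}

# Internal: write the effective config (and a few runtime facts) to a log.
write_run_log <- function(config, out_dir, command, extra = list()) {
  log <- c(
    sprintf("riskbout %s run, %s", command,
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "effective config:",
    strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]],
    vapply(names(extra), function(k) paste0(k, ": ", extra[[k]]),
           character(1))
  )
  writeLines(log, file.path(out_dir, paste0(command, "_log.txt")))
}

#' Simulate an agent and write its trajectory and statistics
#'
#' Pipeline command: resolves the agent parameters from the config (either
#' an explicit parameter block or a named phenotype), simulates, parses
#' bouts, summarises, and writes `trajectory.csv` plus `statistics.json`
#' and a run log into `out_dir`.
#'
#' @param config Passed to [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the trajectory and the model statistics.
#' @export
pipeline_simulate <- function(config = NULL, out_dir = ".") {
  config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(config$simulate)
  constants <- config_constants(config)
  traj <- simulate_agent(params, n_turns = config$simulate$n_turns,
                         constants = constants,
                         depth = config$simulate$depth)
  ms <- model_statistics(traj)
  write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
  stats_obj <- list(
    group = attr(ms$stats, "group"),
    degenerate = isTRUE(attr(ms$stats, "degenerate")),
    statistics = as.list(stats::setNames(as.numeric(ms$stats),
                                         names(ms$stats))),
    n_bouts = nrow(ms$phases$bouts)
  )
  jsonlite::write_json(stats_obj, file.path(out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(config, out_dir, "simulate",
                list(n_bouts = nrow(ms$phases$bouts),
                     group = attr(ms$stats, "group")))
  invisible(list(trajectory = traj, statistics = ms))
}

#' Generate synthetic minute records for the configured archetypes
#'
#' Pipeline command: writes one `record_<group>.csv` per requested group,
#' with a JSON side-car describing the generating archetype, plus a run
#' log.
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, a named list of the generated records.
#' @export
pipeline_synth <- function(config = NULL, out_dir = ".") {
  config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- list()
  for (i in seq_along(config$synth$groups)) {
    group <- config$synth$groups[[i]]
    spec <- archetype_spec(group, noise_sd = config$synth$noise_sd,
                           n_minutes = config$synth$n_minutes,
                           seed = config$seed + i - 1L)
    rec <- generate_minute_record(spec)
    utils::write.csv(rec, file.path(out_dir, paste0("record_", group, ".csv")),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unclass(spec),
                         file.path(out_dir, paste0("record_", group, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
    records[[group]] <- rec
  }
  write_run_log(config, out_dir, "synth")
  invisible(records)
}

#' Fit agent parameters to a target by ABC-SMC and write the posterior
#'
#' Pipeline command: builds the observed statistic vector either from a
#' minute-record CSV (`fit$target_type: "record"`) or from a simulated
#' model target under a named phenotype (`"synthetic_model"`), runs
#' [run_abcsmc()], and writes `posterior.csv` (one particle per row),
#' `fit_summary.json`, and a run log.
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, the `abc_fit`.
#' @export
pipeline_fit <- function(config = NULL, out_dir = ".") {
  config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fc <- config$fit
  constants <- config_constants(config)
  observed <- if (identical(fc$target_type, "record")) {
    if (is.null(fc$record) || !file.exists(fc$record)) {
      stop("fit$record must name an existing minute-record CSV; got ",
           if (is.null(fc$record)) "nothing" else fc$record, call. = FALSE)
    }
    extract_statistics(summarize_record(utils::read.csv(fc$record)))
  } else if (identical(fc$target_type, "synthetic_model")) {
    generate_model_target(config_params(fc), n_turns = fc$n_turns,
                          constants = constants, depth = fc$depth)
  } else {
    stop("fit$target_type must be \"record\" or \"synthetic_model\"; got ",
         fc$target_type, call. = FALSE)
  }
  cfg <- abc_config(B = fc$B, T_gen = fc$T_gen, percentile = fc$percentile,
                    seed = config$seed, n_turns = fc$n_turns,
                    depth = fc$depth, constants = constants)
  fit <- run_abcsmc(observed, cfg)
  utils::write.csv(as.data.frame(fit), file.path(out_dir, "posterior.csv"),
                   row.names = FALSE, quote = FALSE)
  final <- fit$populations[[length(fit$populations)]]
  summary_obj <- list(
    group = attr(observed, "group"),
    observed = as.list(stats::setNames(as.numeric(observed),
                                       names(observed))),
    generations = length(fit$populations),
    epsilon_schedule = vapply(fit$populations, `[[`, numeric(1), "epsilon"),
    mean_distance = vapply(fit$populations,
                           function(p) mean(p$distances), numeric(1)),
    posterior_mean = as.list(stats::setNames(
      as.numeric(colSums(final$particles * final$weights)), PARAM_NAMES))
  )
  jsonlite::write_json(summary_obj, file.path(out_dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(config, out_dir, "fit",
                list(generations = length(fit$populations)))
  invisible(fit)
}
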