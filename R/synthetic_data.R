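#' Specify a synthetic behavioural archetype
#'
#' Describes a stylised animal of one of the three phenotypes as the
#' boxcar-shaped phase profile that the statistics pipeline assumes:
#' piecewise-constant per-minute approach-time percentages, bout durations,
#' and bout frequencies, with phase transitions at minutes `t1` (cautious
#' to confident) and `t2` (peak to steady state). The default levels are
#' plausible fixtures for testing the pipeline, not estimates of any real
#' animal. Timid archetypes have no confident channel at all, and
#' intermediate ones have no peak-to-steady split.
#'
#' @param group `"brave"`, `"intermediate"`, or `"timid"`.
#' @param t1,t2 Transition minutes (whichever the group possesses).
#' @param pct Per-phase approach-time levels in percent. Brave:
#'   `c(cautious, confident_peak, confident_steady)`; intermediate:
#'   `c(cautious, confident)`; timid: `c(cautious_peak, cautious_steady)`.
#' @param duration_s Per-phase mean bout durations in seconds (same phase
#'   order as `pct`).
#' @param bouts_per_min Per-phase mean bout frequencies (same order).
#' @param noise_sd Additive Gaussian noise SD per channel (0 = noiseless).
#' @param n_minutes Record length (default 100 minutes).
#' @param seed Seed used by [generate_minute_record()].
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(group = c("brave", "intermediate", "timid"),
                           t1 = NULL, t2 = NULL, pct = NULL,
                           duration_s = NULL, bouts_per_min = NULL,
                           noise_sd = 0, n_minutes = 100L, seed = 1L) {
  group <- match.arg(group)
  defaults <- switch(group,
    brave = list(t1 = 21L, t2 = 41L, pct = c(10, 25, 5),
                 duration_s = c(0.75, 3.75, 3.75),
                 bouts_per_min = c(1, 2, 0.5)),
    intermediate = list(t1 = 31L, t2 = NULL, pct = c(10, 15),
                        duration_s = c(0.75, 2.25),
                        bouts_per_min = c(1, 0.5)),
    timid = list(t1 = NULL, t2 = 31L, pct = c(10, 4),
                 duration_s = c(0.75, 0.75),
                 bouts_per_min = c(1, 0.25))
  )
  spec <- list(group = group,
               t1 = if (is.null(t1)) defaults$t1 else as.integer(t1),
               t2 = if (is.null(t2)) defaults$t2 else as.integer(t2),
               pct = if (is.null(pct)) defaults$pct else pct,
               duration_s = if (is.null(duration_s)) defaults$duration_s else duration_s,
               bouts_per_min = if (is.null(bouts_per_min)) defaults$bouts_per_min else bouts_per_min,
               noise_sd = noise_sd, n_minutes = as.integer(n_minutes),
               seed = seed)
  n_phase <- if (group == "brave") 3L else 2L
  if (length(spec$pct) != n_phase || length(spec$duration_s) != n_phase ||
      length(spec$bouts_per_min) != n_phase) {
    stop(group, " archetypes have ", n_phase, " phases; `pct`, ",
         "`duration_s` and `bouts_per_min` must all have that length",
         call. = FALSE)
  }
  n <- spec$n_minutes
  if (group != "timid") {
    if (!(spec$t1 >= 2 && spec$t1 <= n)) {
      stop("`t1` must lie in [2, n_minutes]", call. = FALSE)
    }
  }
  if (group == "brave") {
    if (!(spec$t2 > spec$t1 && spec$t2 <= n)) {
      stop("`t2` must lie in (t1, n_minutes]", call. = FALSE)
    }
    if (spec$t2 < spec$t1 + 10L || spec$t2 > n - 9L) {
      stop("brave archetypes need a confident-peak phase of at least 10 ",
           "minutes and a steady phase covering the last 10 minutes ",
           "(t1 + 10 <= t2 <= n_minutes - 9) so the group classification ",
           "windows are well defined", call. = FALSE)
    }
    if (!(spec$pct[2] > spec$pct[3])) {
      stop("a brave archetype needs pct[confident_peak] > ",
           "pct[confident_steady]", call. = FALSE)
    }
  }
  if (group == "timid") {
    if (!(spec$t2 >= 2 && spec$t2 <= n)) {
      stop("`t2` must lie in [2, n_minutes]", call. = FALSE)
    }
    if (!(spec$pct[1] != spec$pct[2])) {
      stop("a timid archetype needs distinct cautious peak and steady ",
           "levels", call. = FALSE)
    }
  }
  structure(spec, class = "archetype_spec")
}

#' Ground-truth statistic vector of an archetype
#'
#' The statistics that a noiseless record generated from `spec` abstracts
#' to; [extract_statistics()] applied to such a record recovers these
#' exactly.
#'
#' @param spec An [archetype_spec()].
#' @return A `stat_vector`.
#' @export
archetype_truth <- function(spec) {
  stopifnot(inherits(spec, "archetype_spec"))
  f <- spec$bouts_per_min
  switch(spec$group,
    brave = stat_vector(c(spec$t1, spec$t2, spec$duration_s[1],
                          spec$duration_s[2], f[2] / f[3]), "brave"),
    intermediate = stat_vector(c(spec$t1, spec$duration_s[1],
                                 spec$duration_s[2], max(f[1] / f[2], 1)),
                               "intermediate"),
    timid = stat_vector(c(spec$t2, spec$duration_s[1], spec$duration_s[2],
                          f[1] / f[2]), "timid")
  )
}

#' Generate a synthetic minute-resolution bout record
#'
#' Builds the boxcar profile described by `spec` on the minute grid and
#' adds truncated Gaussian noise. Noise is applied to a percentage channel
#' only where its underlying level is positive (the presence or absence of
#' an approach type is taken to be observed without error; only the
#' measured times fluctuate), and all channels are clamped to their valid
#' ranges. Reproducible from `spec$seed`.
#'
#' @param spec An [archetype_spec()].
#' @return A minute-record data frame with columns `minute`,
#'   `pct_cautious`, `pct_confident`, `duration_s`, `bouts_per_min`, with
#'   the generating `archetype_spec` attached as attribute `"spec"`.
#' @export
generate_minute_record <- function(spec) {
  stopifnot(inherits(spec, "archetype_spec"))
  n <- spec$n_minutes
  phase_of <- function(minute) {
    if (spec$group == "brave") {
      ifelse(minute < spec$t1, 1L, ifelse(minute < spec$t2, 2L, 3L))
    } else if (spec$group == "intermediate") {
      ifelse(minute < spec$t1, 1L, 2L)
    } else {
      ifelse(minute < spec$t2, 1L, 2L)
    }
  }
  ph <- phase_of(seq_len(n))
  cau <- switch(spec$group,
    brave = c(spec$pct[1], 0, 0)[ph],
    intermediate = c(spec$pct[1], 0)[ph],
    timid = spec$pct[ph])
  con <- switch(spec$group,
    brave = c(0, spec$pct[2], spec$pct[3])[ph],
    intermediate = c(0, spec$pct[2])[ph],
    timid = rep(0, n))
  dur <- spec$duration_s[ph]
  freq <- spec$bouts_per_min[ph]
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    jitter <- function(x, lo, hi, where = rep(TRUE, n)) {
      noisy <- x + ifelse(where, stats::rnorm(n, 0, spec$noise_sd), 0)
      pmin(pmax(noisy, lo), hi)
    }
    cau <- jitter(cau, 0, 100, cau > 0)
    con <- jitter(con, 0, 100, con > 0)
    dur <- jitter(dur, 0, Inf)
    freq <- jitter(freq, 0, Inf)
  }
  out <- data.frame(minute = seq_len(n), pct_cautious = cau,
                    pct_confident = con, duration_s = dur,
                    bouts_per_min = freq)
  attr(out, "spec") <- spec
  out
}

#' Simulate a model-generated fitting target
#'
#' Runs the agent forward under known parameters and summarises the
#' trajectory into its statistic vector; used as a self-consistent target
#' for parameter-recovery fits.
#'
#' @param params An [agent_params()].
#' @param n_turns,constants,depth Passed to [simulate_agent()].
#' @return A `stat_vector`.
#' @export
generate_model_target <- function(params, n_turns = 200L,
                                  constants = env_constants(), depth = 5L) {
  traj <- simulate_agent(params, n_turns = n_turns, constants = constants,
                         depth = depth)
  model_statistics(traj)$stats
}

#' Reference parameter sets for the three phenotypes
#'
#' Fixture configurations that produce each behavioural phenotype under the
#' default environment constants: brave agents hold a flexible (high
#' variance) hazard prior with low means and are nearly risk-neutral, so
#' they transition from short cautious bouts to long confident ones; timid
#' agents hold an inflexible high prior and a low risk level and never
#' approach confidently; intermediate agents sit between. Used as worked
#' examples and as ground-truth generators in recovery tests.
#'
#' @param group `"brave"`, `"intermediate"`, or `"timid"`.
#' @return An [agent_params()].
#' @export
phenotype_params <- function(group = c("brave", "intermediate", "timid")) {
  group <- match.arg(group)
  switch(group,
    brave = agent_params(mu = c(0.30, 0.15, 0.10),
                         v = c(0.105, 0.06375, 0.045),
                         alpha = 0.95, G0 = 5, f = 0.3),
    intermediate = agent_params(mu = c(0.25, 0.20, 0.50),
                                v = c(0.075, 0.064, 0.1),
                                alpha = 0.85, G0 = 20, f = 1.5),
    timid = agent_params(mu = c(0.28, 0.50, 0.55),
                         v = c(0.002, 0.003, 0.005),
                         alpha = 0.6, G0 = 5, f = 0.25)
  )
}
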