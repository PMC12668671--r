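#' Map agent turns to experimental minutes
#'
#' Two turns of the agent correspond to one minute of wall-clock time (so
#' the standard 200-turn simulation covers a 100-minute session).
#'
#' @param turns Numeric vector of turn counts.
#' @return Minutes.
#' @export
map_turns_to_minutes <- function(turns) {
  stopifnot(is.numeric(turns))
  turns / 2
}

#' Map agent bout durations to animal bout durations
#'
#' The agent spends a discrete 2, 3, or 4 turns at the object per bout;
#' animal bout durations are continuous seconds. The linear map
#' \deqn{d_{animal} = 0.75 + 1.5\,(d_{agent} - 2)}
#' sends the admissible agent range onto 0.75--3.75 s, covering the bulk of
#' observed phase-averaged durations.
#'
#' @param d_agent Numeric vector of agent bout lengths; every element must
#'   be in \{2, 3, 4\}.
#' @return Durations in seconds.
#' @export
agent_duration_to_seconds <- function(d_agent) {
  if (length(d_agent) == 0) return(numeric(0))
  if (!all(d_agent %in% c(2, 3, 4))) {
    stop("agent bout durations must lie in {2, 3, 4}; got ",
         paste(utils::head(setdiff(d_agent, c(2, 3, 4))), collapse = ", "),
         call. = FALSE)
  }
  0.75 + 1.5 * (d_agent - 2)
}

#' Fit a single-step boxcar to a per-minute series
#'
#' Exhaustively searches all candidate change points and returns the
#' two-level piecewise-constant fit minimising the total squared error;
#' segment levels are the per-segment means. If no split improves on a
#' single constant level (in particular for an exactly constant series), no
#' change point is reported.
#'
#' @param series Numeric vector, length at least 2.
#' @return A list with `changepoint` (index of the first point of the
#'   second segment, or `NA` if none) and `levels` (length 2, or length 1
#'   when there is no change point).
#' @export
fit_boxcar <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  stopifnot(n >= 2L, all(is.finite(x)))
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_ss <- function(lo_cs, lo_cs2, len) max(0, lo_cs2 - lo_cs^2 / len)
  sse_none <- seg_ss(cs[n], cs2[n], n)
  ks <- 2:n
  sse <- vapply(ks, function(k) {
    left <- seg_ss(cs[k - 1L], cs2[k - 1L], k - 1L)
    right <- seg_ss(cs[n] - cs[k - 1L], cs2[n] - cs2[k - 1L], n - k + 1L)
    left + right
  }, numeric(1))
  best <- which.min(sse)  # first minimum: earliest change point on ties
  if (sse[best] >= sse_none - 1e-12 * max(1, sse_none)) {
    return(list(changepoint = NA_integer_, levels = cs[n] / n))
  }
  k <- ks[best]
  list(changepoint = k,
       levels = c(cs[k - 1L] / (k - 1L), (cs[n] - cs[k - 1L]) / (n - k + 1L)))
}

#' Classify a minute record into brave / intermediate / timid
#'
#' An animal with no confident (tail-exposed) approach at all is timid.
#' Otherwise the ratio
#' \eqn{y = } (confident approach time in the first 10 minutes of the
#' confident phase) / (confident approach time in the last 10 minutes of
#' the record) separates brave (\eqn{y > 1}: approach decays from a peak to
#' a steady state) from intermediate (\eqn{y \le 1}; the boundary case is
#' assigned to intermediate).
#'
#' @param record A minute record: data frame with columns `minute`,
#'   `pct_cautious`, `pct_confident`, `duration_s`, `bouts_per_min`.
#' @param window Window length in minutes (default 10).
#' @return `"brave"`, `"intermediate"`, or `"timid"`.
#' @export
classify_group <- function(record, window = 10L) {
  stopifnot(all(c("pct_cautious", "pct_confident") %in% names(record)))
  conf <- record$pct_confident
  n <- length(conf)
  if (sum(conf) == 0) return("timid")
  onset <- which(conf > 0)[1]
  if (n < window || (n - onset + 1L) < window) {
    stop("record too short: need at least ", window,
         " minutes of confident phase and of total recording", call. = FALSE)
  }
  y <- sum(conf[onset:(onset + window - 1L)]) /
       sum(conf[(n - window + 1L):n])
  if (y > 1) "brave" else "intermediate"
}

#' Segment a minute record into behavioural phases
#'
#' Classifies the record, then locates the phase-transition points with
#' boxcar fits and averages the time, duration, and frequency channels
#' within each phase. The cautious-to-confident transition `t1` is read
#' from the collapse of the cautious curve; for brave animals the
#' peak-to-steady transition `t2` is then read from the level drop of the
#' confident curve after `t1`; for timid animals `t2` comes from the level
#' drop of the cautious curve.
#'
#' @param record A minute record (see [classify_group()]).
#' @return A `phase_summary`: list with `group`, transition minutes `t1`,
#'   `t2` (NA where the group lacks one), and a data frame `phases` with
#'   columns `phase`, `start`, `end`, `pct_level`, `duration`, `frequency`.
#' @export
summarize_record <- function(record) {
  stopifnot(all(c("minute", "pct_cautious", "pct_confident", "duration_s",
                  "bouts_per_min") %in% names(record)))
  n <- nrow(record)
  group <- classify_group(record)
  seg <- function(name, lo, hi, level_col) {
    idx <- lo:hi
    data.frame(phase = name, start = lo, end = hi,
               pct_level = mean(record[[level_col]][idx]),
               duration = mean(record$duration_s[idx]),
               frequency = mean(record$bouts_per_min[idx]),
               stringsAsFactors = FALSE)
  }
  if (group == "timid") {
    fit <- fit_boxcar(record$pct_cautious)
    t2 <- fit$changepoint
    if (is.na(t2)) {
      stop("timid record has no detectable peak-to-steady transition in ",
           "the cautious curve", call. = FALSE)
    }
    phases <- rbind(seg("cautious_peak", 1L, t2 - 1L, "pct_cautious"),
                    seg("cautious_steady", t2, n, "pct_cautious"))
    out <- list(group = group, t1 = NA_integer_, t2 = t2, phases = phases)
  } else {
    fit_cau <- fit_boxcar(record$pct_cautious)
    t1 <- fit_cau$changepoint
    if (is.na(t1)) {
      stop("no cautious-to-confident transition found in the cautious curve",
           call. = FALSE)
    }
    if (group == "intermediate") {
      phases <- rbind(seg("cautious", 1L, t1 - 1L, "pct_cautious"),
                      seg("confident", t1, n, "pct_confident"))
      out <- list(group = group, t1 = t1, t2 = NA_integer_, phases = phases)
    } else {
      fit_con <- fit_boxcar(record$pct_confident[t1:n])
      k <- fit_con$changepoint
      if (is.na(k)) {
        stop("brave record has no peak-to-steady transition in the ",
             "confident curve", call. = FALSE)
      }
      t2 <- t1 + k - 1L
      phases <- rbind(seg("cautious", 1L, t1 - 1L, "pct_cautious"),
                      seg("confident_peak", t1, t2 - 1L, "pct_confident"),
                      seg("confident_steady", t2, n, "pct_confident"))
      out <- list(group = group, t1 = t1, t2 = t2, phases = phases)
    }
  }
  structure(out, class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("<phase_summary> group=%s t1=%s t2=%s\n", x$group,
              format(x$t1), format(x$t2)))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

# Internal constructor for the group-specific statistic vector, carrying
# the per-entry normalizer type used by the ABC distance.
stat_vector <- function(values, group, degenerate = FALSE) {
  types <- switch(group,
    brave = c(t_cautious_to_confident = "time", t_peak_to_steady = "time",
              d_cautious = "duration", d_peak_confident = "duration",
              f_ratio = "ratio"),
    intermediate = c(t_cautious_to_confident = "time",
                     d_cautious = "duration", d_confident = "duration",
                     f_ratio = "ratio"),
    timid = c(t_peak_to_steady = "time", d_cautious_peak = "duration",
              d_cautious_steady = "duration", f_ratio = "ratio"),
    stop("unknown group: ", group, call. = FALSE)
  )
  stopifnot(length(values) == length(types))
  structure(stats::setNames(as.numeric(values), names(types)),
            group = group, stat_types = unname(types),
            degenerate = degenerate, class = "stat_vector")
}

#' @export
print.stat_vector <- function(x, ...) {
  cat(sprintf("<stat_vector> group=%s%s\n", attr(x, "group"),
              if (isTRUE(attr(x, "degenerate"))) " (degenerate)" else ""))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Extract the group-specific statistic vector from a phase summary
#'
#' Brave records yield five statistics (two transition times, cautious and
#' peak-confident durations, and the peak/steady confident frequency
#' ratio); intermediate and timid records yield four. The intermediate
#' frequency ratio is clamped below at 1 because the generative model can
#' only decrease bout frequency across the transition.
#'
#' @param phases A `phase_summary` from [summarize_record()].
#' @return A `stat_vector` (named numeric vector with a `group` attribute).
#' @export
extract_statistics <- function(phases) {
  stopifnot(inherits(phases, "phase_summary"))
  ph <- phases$phases
  get <- function(name, col) {
    i <- match(name, ph$phase)
    if (is.na(i)) {
      stop("phase summary is missing required phase `", name, "`",
           call. = FALSE)
    }
    ph[[col]][i]
  }
  switch(phases$group,
    brave = stat_vector(c(
      phases$t1, phases$t2,
      get("cautious", "duration"), get("confident_peak", "duration"),
      get("confident_peak", "frequency") / get("confident_steady", "frequency")
    ), "brave"),
    intermediate = stat_vector(c(
      phases$t1,
      get("cautious", "duration"), get("confident", "duration"),
      max(get("cautious", "frequency") / get("confident", "frequency"), 1)
    ), "intermediate"),
    timid = stat_vector(c(
      phases$t2,
      get("cautious_peak", "duration"), get("cautious_steady", "duration"),
      get("cautious_peak", "frequency") / get("cautious_steady", "frequency")
    ), "timid")
  )
}

# Internal: mean bout-start period of a phase, with graceful fallbacks when
# the phase holds fewer than two bouts (documented in the methods vignette).
phase_period <- function(starts, phase_len) {
  if (length(starts) >= 2L) mean(diff(starts))
  else if (length(starts) == 1L) phase_len
  else 2 * phase_len
}

#' Summarise a simulated trajectory into the statistic space of the animals
#'
#' Parses bouts, locates the model's phase transitions, and maps the
#' resulting statistics into animal units. The cautious-to-confident
#' transition is the turn of the first confident bout; the peak-to-steady
#' transition is the first time the agent spends more than one consecutive
#' turn at the nest (waiting for the exploration pool to regenerate) after
#' the relevant phase has begun. Durations are phase means of bout lengths
#' mapped through [agent_duration_to_seconds()]; a phase's frequency is the
#' inverse of its mean bout-start period, and frequency ratios are unitless.
#' Transitions that never occur are placed at the end of the session, empty
#' phases get zero durations and a unit frequency ratio, and a trajectory
#' with no bouts at all yields a maximally timid summary flagged as
#' degenerate.
#'
#' @param traj A trajectory from [simulate_agent()].
#' @param group Force the statistic schema of a given group (needed when
#'   comparing against an observed animal of a known group); `NULL` infers
#'   it from the trajectory.
#' @return A list with `stats` (a `stat_vector`) and `phases` (a list with
#'   the transition turns and per-phase bout statistics, in agent units).
#' @export
model_statistics <- function(traj, group = NULL) {
  bouts <- parse_bouts(traj)
  n_turns <- max(traj$turn)
  total_min <- map_turns_to_minutes(n_turns)

  if (nrow(bouts) == 0L) {
    grp <- if (is.null(group)) "timid" else group
    vals <- switch(grp,
      timid = c(total_min, 0, 0, 1),
      intermediate = c(total_min, 0, 0, 1),
      brave = c(total_min, total_min, 0, 0, 1))
    return(list(stats = stat_vector(vals, grp, degenerate = TRUE),
                phases = list(bouts = bouts)))
  }

  # first nest run longer than one turn starting at or after `from`
  nest_runs <- rle(traj$state == "nest")
  ends <- cumsum(nest_runs$lengths)
  starts <- ends - nest_runs$lengths + 1L
  long_nest_start <- function(from) {
    k <- which(nest_runs$values & nest_runs$lengths > 1L & starts >= from)
    if (length(k)) traj$turn[starts[k[1]]] else NA_integer_
  }

  conf <- bouts[bouts$type == "confident", , drop = FALSE]
  t1_turn <- if (nrow(conf)) conf$start[1] else NA_integer_

  if (is.null(group)) {
    group <- if (is.na(t1_turn)) {
      "timid"
    } else if (!is.na(long_nest_start(t1_turn))) "brave" else "intermediate"
  }

  phase_stats <- function(lo, hi) {
    sel <- bouts$start >= lo & bouts$start <= hi
    len <- hi - lo + 1L
    list(n = sum(sel),
         duration = if (any(sel)) mean(agent_duration_to_seconds(bouts$length[sel])) else 0,
         frequency = 1 / phase_period(bouts$start[sel], len))
  }
  ratio_or_unit <- function(f_a, f_b, a_has, b_has) {
    if (a_has && b_has) f_a / f_b else 1
  }

  if (group == "timid") {
    t2_turn <- long_nest_start(bouts$start[1])
    t2 <- if (is.na(t2_turn)) total_min else map_turns_to_minutes(t2_turn)
    split <- if (is.na(t2_turn)) n_turns + 1L else t2_turn
    peak <- phase_stats(1L, split - 1L)
    steady <- phase_stats(split, n_turns)
    stats <- stat_vector(c(
      t2, peak$duration, steady$duration,
      ratio_or_unit(peak$frequency, steady$frequency, peak$n > 0, steady$n > 0)
    ), "timid")
    phases <- list(t2_turn = t2_turn, peak = peak, steady = steady)
  } else if (group == "intermediate") {
    t1 <- if (is.na(t1_turn)) total_min else map_turns_to_minutes(t1_turn)
    split <- if (is.na(t1_turn)) n_turns + 1L else t1_turn
    cau <- phase_stats(1L, split - 1L)
    con <- phase_stats(split, n_turns)
    stats <- stat_vector(c(
      t1, cau$duration, con$duration,
      max(ratio_or_unit(cau$frequency, con$frequency, cau$n > 0, con$n > 0), 1)
    ), "intermediate")
    phases <- list(t1_turn = t1_turn, cautious = cau, confident = con)
  } else {
    t1 <- if (is.na(t1_turn)) total_min else map_turns_to_minutes(t1_turn)
    t2_turn <- if (is.na(t1_turn)) NA_integer_ else long_nest_start(t1_turn)
    t2 <- if (is.na(t2_turn)) total_min else map_turns_to_minutes(t2_turn)
    split1 <- if (is.na(t1_turn)) n_turns + 1L else t1_turn
    split2 <- if (is.na(t2_turn)) n_turns + 1L else t2_turn
    cau <- phase_stats(1L, split1 - 1L)
    peak <- phase_stats(split1, split2 - 1L)
    steady <- phase_stats(split2, n_turns)
    stats <- stat_vector(c(
      t1, t2, cau$duration, peak$duration,
      ratio_or_unit(peak$frequency, steady$frequency, peak$n > 0, steady$n > 0)
    ), "brave")
    phases <- list(t1_turn = t1_turn, t2_turn = t2_turn, cautious = cau,
                   peak = peak, steady = steady)
  }
  phases$bouts <- bouts
  list(stats = stats, phases = phases)
}
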