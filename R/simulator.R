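#' Bundle the nine fitted agent parameters
#'
#' Six parameters describe the hazard prior (mean and variance of the Beta
#' prior on the per-turn detection probability for stays of 2, 3, and 4
#' turns), one the nCVaR risk level, and two the exploration-bonus dynamics
#' (initial pool and forgetting rate).
#'
#' @param mu Length-3 vector of hazard prior means for tau = 2, 3, 4.
#' @param v Length-3 vector of hazard prior variances (each in
#'   `(0, mu - mu^2)`).
#' @param alpha nCVaR risk level in (0, 1]; lower is more risk-averse.
#' @param G0 Initial exploration pool, positive.
#' @param f Forgetting (pool regeneration) rate per turn, non-negative.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(mu, v, alpha, G0, f) {
  stopifnot(length(mu) == 3L, length(v) == 3L,
            alpha > 0, alpha <= 1, G0 > 0, f >= 0)
  for (i in 1:3) {
    if (!(mu[i] > 0 && mu[i] < 1 && v[i] > 0 && v[i] < mu[i] - mu[i]^2)) {
      stop("hazard prior for tau = ", i + 1L,
           " violates 0 < v < mu - mu^2", call. = FALSE)
    }
  }
  structure(list(mu = as.numeric(mu), v = as.numeric(v),
                 alpha = alpha, G0 = G0, f = f),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>\n")
  cat(sprintf("  hazard prior mu = (%.3f, %.3f, %.3f), v = (%.4g, %.4g, %.4g)\n",
              x$mu[1], x$mu[2], x$mu[3], x$v[1], x$v[2], x$v[3]))
  cat(sprintf("  alpha = %.3f, G0 = %.3g, f = %.3g\n", x$alpha, x$G0, x$f))
  invisible(x)
}

#' Simulate the agent in the real (predator-free) environment
#'
#' Rolls the nCVaR planner out for `n_turns` turns. At every decision point
#' the agent plans with [plan()]; because no predator actually exists, the
#' realised transition is always the no-detection branch, so trajectories
#' never visit detect or dead states and are fully deterministic given the
#' parameters. After each completed bout of length tau the persistent
#' hazard belief receives the safe-bout update [observe_safe_bout()] and
#' the bout clock (and hence the hazard) resets for the next bout; the pool
#' advances every turn. Two turns of the agent correspond to one minute of
#' experimental time, so the default 200 turns model a 100-minute session.
#'
#' @param params An [agent_params()].
#' @param n_turns Number of turns to simulate (default 200).
#' @param constants An [env_constants()].
#' @param depth Planning horizon (default 5 turns, one full bout cycle).
#' @return A data frame of class `trajectory` with columns `turn`, `state`,
#'   `tau`, `action`, `G` (`state`, `tau`, and `G` are measured at the start
#'   of the turn, before `action` is taken).
#' @export
simulate_agent <- function(params, n_turns = 200L,
                           constants = env_constants(), depth = 5L) {
  stopifnot(inherits(params, "agent_params"), n_turns >= 1)
  belief <- hazard_belief(params$mu, params$v)
  pool <- pool_state(params$G0, params$f)
  state <- "nest"
  tau <- 0L
  rows_state <- character(n_turns)
  rows_tau <- integer(n_turns)
  rows_action <- character(n_turns)
  rows_G <- numeric(n_turns)

  for (t in seq_len(n_turns)) {
    action <- plan(state, tau, belief, pool, params$alpha, constants,
                   depth)$action
    rows_state[t] <- state
    rows_tau[t] <- tau
    rows_action[t] <- action
    rows_G[t] <- pool$G

    if (action == "stay_nest") {
      pool <- step_pool(pool, "elsewhere")
    } else if (action == "approach_cautious") {
      state <- "cautious_object"
      tau <- 1L
      pool <- step_pool(pool, state)
    } else if (action == "approach_confident") {
      state <- "confident_object"
      tau <- 1L
      pool <- step_pool(pool, state)
    } else if (action == "stay_object") {
      tau <- tau + 1L
      pool <- step_pool(pool, state)
    } else if (action == "retreat") {
      belief <- observe_safe_bout(belief, tau)
      state <- "nest"
      tau <- 0L
      pool <- step_pool(pool, "elsewhere")
    } else {
      stop("internal error: unknown action ", action)
    }
  }

  out <- data.frame(turn = seq_len(n_turns), state = rows_state,
                    tau = rows_tau, action = rows_action, G = rows_G,
                    stringsAsFactors = FALSE)
  class(out) <- c("trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "final_belief") <- belief
  out
}

#' Parse object-visit bouts from a trajectory
#'
#' A bout is one maximal run of object states: the agent leaves the nest,
#' stays at the object for 2--4 turns, and returns via retreat. The approach
#' type is read off the approach action that started the run. A bout still
#' in progress when the trajectory ends (not yet closed by a retreat) is
#' dropped, mirroring the fact that its safe-bout belief update also never
#' happened.
#'
#' @param traj A trajectory from [simulate_agent()] (or any data frame with
#'   columns `turn`, `state`, `action`).
#' @return A data frame with one row per completed bout: `start` (turn of
#'   the first object turn), `length` (turns at the object), `type`
#'   (`"cautious"` or `"confident"`).
#' @export
parse_bouts <- function(traj) {
  stopifnot(all(c("turn", "state", "action") %in% names(traj)))
  at_obj <- traj$state %in% c("cautious_object", "confident_object")
  if (!any(at_obj)) {
    return(data.frame(start = integer(0), length = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  r <- rle(at_obj)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  res <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || !startsWith(traj$action[i0 - 1L], "approach_")) {
      stop("malformed trajectory: object run at turn ", traj$turn[i0],
           " is not preceded by an approach action", call. = FALSE)
    }
    if (traj$action[i1] != "retreat") return(NULL)  # truncated final bout
    type <- if (traj$state[i0] == "cautious_object") "cautious" else "confident"
    if (length(unique(traj$state[i0:i1])) != 1L) {
      stop("malformed trajectory: approach type switches mid-bout",
           call. = FALSE)
    }
    data.frame(start = traj$turn[i0], length = i1 - i0 + 1L, type = type,
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(start = integer(0), length = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Write a trajectory to CSV
#'
#' @param traj A trajectory from [simulate_agent()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("turn", "state", "tau", "action", "G")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
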