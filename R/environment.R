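#' Fixed constants of the decision problem
#'
#' The discrete world has three occupiable real states (nest, cautious
#' object, confident object), a retreat transition back to the nest, and
#' three imagined states (cautious detect, confident detect, dead) that
#' exist only inside planning: there is no actual predator. Costs and escape-failure probabilities are free constants of
#' the model, not quantities estimated from data; the defaults were chosen
#' so that a cautious approach strictly dominates a confident one under a
#' high hazard belief while both phenotype extremes (always-approach,
#' never-approach-confidently) remain reachable within the fitted parameter
#' ranges. All are overridable here and through the pipeline config.
#'
#' @param travel_cost Cost (non-positive) per nest-object traversal.
#' @param dying_cost Cost (negative, below `travel_cost`) of the imagined
#'   dead outcome.
#' @param p1 Probability that escape fails from the confident detect state.
#' @param p2 Probability that escape fails from the cautious detect state;
#'   must be below `p1` (a cautious posture is better poised to escape).
#' @param gamma Discount factor in (0, 1].
#' @return An object of class `env_constants`.
#' @export
env_constants <- function(travel_cost = -0.2, dying_cost = -4,
                          p1 = 0.6, p2 = 0.3, gamma = 0.95) {
  stopifnot(travel_cost <= 0, dying_cost < travel_cost,
            p1 > 0, p1 < 1, p2 > 0, p2 < p1,
            gamma > 0, gamma <= 1)
  structure(list(travel_cost = travel_cost, dying_cost = dying_cost,
                 p1 = p1, p2 = p2, gamma = gamma),
            class = "env_constants")
}

# State labels. tau (turns spent at the object this bout) is carried
# alongside the label; tau > 0 only at object/detect states. Retreating is
# a one-turn transition back to the nest rather than a separate state, so
# the five-turn planning horizon covers a complete nest-object-nest cycle.
REAL_STATES <- c("nest", "cautious_object", "confident_object")
IMAGINED_STATES <- c("cautious_detect", "confident_detect", "dead")

# Fixed deterministic tie-break order for the planner.
ACTION_ORDER <- c("stay_nest", "approach_cautious", "approach_confident",
                  "stay_object", "retreat")

#' Actions available in a physical state
#'
#' The nest offers staying or either type of approach. At the object the
#' agent must stay at least until two turns have been spent (bouts of length
#' one do not exist: the approach turn itself counts as the first, hazard
#' free, turn), may stay or retreat at 2-3 turns, and is forced to retreat
#' after four. Retreat occupies one turn and leads back to the nest; dead is
#' absorbing. Imagined detect states are chance nodes, not decision states.
#'
#' @param label State label.
#' @param tau Turns spent at the object this bout (0 away from the object).
#' @return Character vector of action names (possibly empty).
#' @export
available_actions <- function(label, tau = 0L) {
  switch(label,
    nest = c("stay_nest", "approach_cautious", "approach_confident"),
    cautious_object = ,
    confident_object = {
      stopifnot(tau >= 1, tau <= 4)
      if (tau == 1L) "stay_object"
      else if (tau < 4L) c("stay_object", "retreat")
      else "retreat"
    },
    dead = character(0),
    cautious_detect = ,
    confident_detect =
      stop("detect states are chance nodes and have no agent actions",
           call. = FALSE),
    stop("unknown state label: ", label, call. = FALSE)
  )
}

# Internal: branch-local belief update for surviving one more turn at the
# object. Surviving into turn `tau_new` appends the single increment that
# extends the cumulative safe-bout observation from tau_new - 1 to tau_new,
# so that a branch that completes a bout of length tau has received exactly
# observe_safe_bout(belief, tau).
observe_safe_turn <- function(belief, tau_new) {
  stopifnot(tau_new %in% 2:4)
  out <- belief
  out$b[[tau_new - 1L]] <- out$b[[tau_new - 1L]] + 1
  out
}

#' Transition distribution of a state-action pair
#'
#' Returns the outcomes of taking `action` in state (`label`, `tau`) under
#' the current hazard belief, each with its probability, edge reward, and
#' branch-local successor belief and pool. Epistemic uncertainty enters only
#' through the expected transition probability: staying for turn
#' \eqn{\tau + 1} is detected with probability \eqn{h(\tau + 1)}, the
#' cumulative hazard at the new stay length under the branch belief (so the
#' risk of a longer stay falls as the agent learns that the early per-turn
#' detection causes are small -- the generalisation that lets bouts lengthen
#' over a session; on the first stay decision, where \eqn{h(1) = 0}, this
#' coincides with the conditional hazard increment
#' \eqn{[h(2) - h(1)]/[1 - h(1)] = \mu_2}). A detect state resolves as a chance node
#' (pass `action = "resolve"`): escape fails, leading to the absorbing dead
#' state with the dying cost, with probability `p1` (confident) or `p2`
#' (cautious), otherwise the agent ends up back at the nest. Rewards:
#' imagined exploration reward on each turn spent at an object state, travel
#' cost on approach and retreat edges, the dying cost on the dead
#' transition, zero at the nest. The bout clock `tau` (and with it the
#' hazard) resets on any return to the nest.
#'
#' @param label,tau Physical state.
#' @param action An action from [available_actions()], or `"resolve"` for a
#'   detect state.
#' @param belief A [hazard_belief()].
#' @param pool A [pool_state()].
#' @param constants An [env_constants()].
#' @return A list of outcomes; each has elements `label`, `tau`, `prob`,
#'   `reward`, `belief`, `pool`.
#' @export
transition_distribution <- function(label, tau, action, belief, pool,
                                    constants = env_constants()) {
  stopifnot(inherits(belief, "hazard_belief"), inherits(pool, "pool_state"),
            inherits(constants, "env_constants"))
  out <- function(label, tau, prob, reward, belief2 = belief,
                  pool_loc = "elsewhere") {
    list(label = label, tau = tau, prob = prob, reward = reward,
         belief = belief2, pool = step_pool(pool, pool_loc))
  }
  if (label %in% c("cautious_detect", "confident_detect")) {
    if (!identical(action, "resolve")) {
      stop("detect states resolve as chance nodes; use action = \"resolve\"",
           call. = FALSE)
    }
    p_die <- if (label == "confident_detect") constants$p1 else constants$p2
    return(list(
      out("dead", 0L, p_die, constants$dying_cost),
      out("nest", 0L, 1 - p_die, 0)
    ))
  }
  if (!action %in% available_actions(label, tau)) {
    stop("action `", action, "` is not available in state ", label,
         " with tau = ", tau, call. = FALSE)
  }
  approach_of <- c(cautious_object = "cautious", confident_object = "confident")
  switch(action,
    stay_nest = list(out("nest", 0L, 1, 0)),
    approach_cautious = list(
      out("cautious_object", 1L, 1,
          constants$travel_cost + imagined_reward(pool, "cautious"),
          pool_loc = "cautious_object")),
    approach_confident = list(
      out("confident_object", 1L, 1,
          constants$travel_cost + imagined_reward(pool, "confident"),
          pool_loc = "confident_object")),
    stay_object = {
      appr <- approach_of[[label]]
      q <- hazard_predictive(belief, tau + 1L)
      detect_label <- paste0(appr, "_detect")
      list(
        out(detect_label, tau + 1L, q, 0),
        out(label, tau + 1L, 1 - q, imagined_reward(pool, appr),
            belief2 = observe_safe_turn(belief, tau + 1L),
            pool_loc = label)
      )
    },
    retreat = list(out("nest", 0L, 1, constants$travel_cost))
  )
}
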