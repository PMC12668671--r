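#' CVaR distortion of a discrete value distribution
#'
#' Computes the inner minimisation of the nested-CVaR Bellman backup: over
#' the risk envelope \eqn{U(\bar\alpha) = \{\xi : 0 \le \xi_i \le
#' 1/\bar\alpha,\ \sum_i \xi_i p_i = 1\}}, find the reweighting of outcome
#' probabilities that minimises the expected value. The solution has a
#' closed form: sort outcomes ascending by value and greedily assign the
#' maximal weight \eqn{1/\bar\alpha} to the worst outcomes until unit
#' probability mass is allocated, with a fractional weight on the pivot
#' outcome. At \eqn{\bar\alpha = 1} the distortion is the identity and the
#' result is the plain expectation.
#'
#' @param values Numeric vector of outcome values.
#' @param probs Probabilities, same length, summing to one.
#' @param alpha Risk level \eqn{\bar\alpha} in (0, 1].
#' @return A list with `value` (the distorted expectation) and `xi` (the
#'   optimal envelope weights, in the original outcome order).
#' @examples
#' cvar_distort(c(0, 10), c(0.5, 0.5), alpha = 0.5)  # value 0
#' @export
cvar_distort <- function(values, probs, alpha) {
  stopifnot(length(values) == length(probs), all(probs >= 0))
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1)) {
    stop("`alpha` must be a single risk level in (0, 1]; got ", alpha,
         call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-8) {
    stop("`probs` must sum to 1", call. = FALSE)
  }
  ord <- order(values)
  xi <- numeric(length(values))
  mass <- 0
  cap <- 1 / alpha
  for (i in ord) {
    if (probs[i] <= 0) next
    xi[i] <- min(cap, max(0, (1 - mass)) / probs[i])
    mass <- mass + xi[i] * probs[i]
    if (mass >= 1) break
  }
  list(value = sum(xi * probs * values), xi = xi)
}

#' Plan one action by receding-horizon nCVaR tree search
#'
#' Expands the decision tree from the current hyperstate (physical state,
#' hazard belief, exploration pool, risk level) to `depth` turns, backing
#' values up with the nested-CVaR Bellman operator: at each chance stage the
#' outcome distribution is distorted by [cvar_distort()] before the
#' expectation, so risk sensitivity is applied recursively and
#' time-consistently. Along imagined safe-continuation branches the belief
#' receives the incremental safe-turn update and the pool advances exactly
#' as it would in reality (each branch carries its own posterior); leaves
#' are valued at zero, since the default depth of 5 covers one complete
#' nest-object-nest cycle including the longest allowed bout. Ties between
#' actions are broken by the fixed order stay_nest, approach_cautious,
#' approach_confident, stay_object, retreat, making simulations fully
#' reproducible.
#'
#' @param label,tau Physical state (a real, non-imagined state).
#' @param belief A [hazard_belief()].
#' @param pool A [pool_state()].
#' @param alpha Risk level in (0, 1]; 1 is risk-neutral.
#' @param constants An [env_constants()].
#' @param depth Planning horizon in turns (default 5).
#' @return A list with `action` (the argmax action), `actions` (available
#'   actions in tie-break order) and `values` (their nCVaR action values).
#' @export
plan <- function(label, tau, belief, pool, alpha,
                 constants = env_constants(), depth = 5L) {
  stopifnot(inherits(belief, "hazard_belief"), inherits(pool, "pool_state"),
            inherits(constants, "env_constants"),
            depth >= 1, alpha > 0, alpha <= 1)
  if (label == "dead") stop("the dead state has no actions", call. = FALSE)
  if (label %in% IMAGINED_STATES) {
    stop("planning starts from a real state; got ", label, call. = FALSE)
  }
  res <- plan_values_cpp(
    state_code(label), as.integer(tau),
    belief$a, belief$b, pool$G,
    pool$omega_cautious, pool$omega_confident,
    pool$n1 / (pool$n1 + pool$n0), pool$f, pool$G0,
    constants$travel_cost, constants$dying_cost,
    constants$p1, constants$p2, constants$gamma,
    alpha, as.integer(depth))
  actions <- available_actions(label, tau)
  values <- stats::setNames(res, actions)
  list(action = actions[which.max(values)], actions = actions,
       values = values)
}

# Internal: integer state codes shared with the compiled planner.
state_code <- function(label) {
  code <- match(label, c("nest", "cautious_object", "confident_object",
                         "retreat", "cautious_detect", "confident_detect",
                         "dead"))
  if (is.na(code)) stop("unknown state label: ", label, call. = FALSE)
  code - 1L
}
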