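#' Construct an exploration-bonus pool state
#'
#' The drive to approach the object is modelled as a depletable resource
#' \eqn{G(t)}: the agent imagines harvesting reward proportional to the
#' remaining pool on every turn spent at the object, so the bonus decays
#' exponentially with engagement, and the pool regenerates linearly back
#' towards its initial size \eqn{G_0} at the forgetting rate \eqn{f} on every
#' turn (as if the object's affordances might change over time). The
#' reward/no-reward pseudocounts `n1`, `n0` carry the agent's belief about
#' real reward at the object; no real reward is ever delivered in this
#' environment, so they stay at their initial values (1, 1) and contribute a
#' constant base rate `n1/(n1+n0)` to the imagined reward.
#'
#' @param G0 Initial (and maximal) pool size, positive.
#' @param f Forgetting/regeneration rate per turn, non-negative.
#' @param G Current pool level; defaults to `G0`.
#' @param n1,n0 Reward/no-reward pseudocounts; default 1 each.
#' @param R,K Depletion constants: the confident depletion rate is
#'   `R / G0` and the cautious rate is `K` times that. Defaults 1.1 and 0.89.
#' @return An object of class `pool_state`.
#' @export
pool_state <- function(G0, f, G = G0, n1 = 1, n0 = 1, R = 1.1, K = 0.89) {
  if (!(is.numeric(G0) && length(G0) == 1L && G0 > 0)) {
    stop("`G0` must be a single positive number; got ", G0, call. = FALSE)
  }
  stopifnot(f >= 0, G >= 0, G <= G0, n1 >= 0, n0 >= 0, n1 + n0 > 0)
  om <- depletion_rates(G0, R = R, K = K)
  structure(list(G = G, G0 = G0, f = f, n1 = n1, n0 = n0,
                 omega_cautious = om[["cautious"]],
                 omega_confident = om[["confident"]]),
            class = "pool_state")
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("<pool_state> G=%.4g / G0=%.4g, f=%.3g, omega=(cau %.4g, con %.4g)\n",
              x$G, x$G0, x$f, x$omega_cautious, x$omega_confident))
  invisible(x)
}

#' Depletion rates of the exploration pool
#'
#' The confident approach harvests the pool at rate
#' \eqn{\omega_{conf} = R / G_0} and the cautious approach at
#' \eqn{\omega_{caut} = K \omega_{conf}} with constants \eqn{R = 1.1} and
#' \eqn{K = 0.89 < 1}: a confident visit extracts more bonus per turn and so
#' also exhausts the pool faster. For very small `G0` the ratio `R / G0`
#' would reach or exceed 1, outside the meaningful range of a per-turn
#' depletion fraction, so rates are capped at 0.999; this keeps the dynamics
#' well defined for extreme parameter draws during fitting.
#'
#' @param G0 Initial pool size, positive.
#' @param R,K Constants as above.
#' @return Named numeric vector `c(cautious = ..., confident = ...)`.
#' @export
depletion_rates <- function(G0, R = 1.1, K = 0.89) {
  if (!(is.numeric(G0) && length(G0) == 1L && G0 > 0)) {
    stop("`G0` must be a single positive number; got ", G0, call. = FALSE)
  }
  conf <- min(R / G0, 0.999)
  c(cautious = K * conf, confident = conf)
}

#' Imagined per-turn reward at an object state
#'
#' On a turn at the object the agent imagines extracting
#' \eqn{\omega_{appr} G(t) + n^1 / (n^1 + n^0)}: the exploration bonus
#' proportional to the remaining pool plus the expected real reward under its
#' Beta reward belief.
#'
#' @param pool A [pool_state()].
#' @param approach `"cautious"` or `"confident"`.
#' @return A single numeric reward.
#' @export
imagined_reward <- function(pool, approach = c("cautious", "confident")) {
  stopifnot(inherits(pool, "pool_state"))
  approach <- match.arg(approach)
  omega <- if (approach == "cautious") pool$omega_cautious else pool$omega_confident
  omega * pool$G + pool$n1 / (pool$n1 + pool$n0)
}

#' Advance the exploration pool by one turn
#'
#' At an object state the pool is depleted by the approach-specific rate and
#' then regenerates; elsewhere it only regenerates. The update at, e.g., the
#' cautious object state is
#' \deqn{G(t+1) = \min\{(1 - \omega_{caut}) G(t) + f,\; G_0\},}
#' applied in that order (deplete, add `f`, clamp); regeneration acts in all
#' states, including the object states.
#'
#' @param pool A [pool_state()].
#' @param location `"cautious_object"`, `"confident_object"`, or
#'   `"elsewhere"`.
#' @return A new `pool_state` with updated `G`.
#' @export
step_pool <- function(pool,
                      location = c("elsewhere", "cautious_object",
                                   "confident_object")) {
  stopifnot(inherits(pool, "pool_state"))
  location <- match.arg(location)
  g <- switch(location,
    cautious_object  = (1 - pool$omega_cautious) * pool$G,
    confident_object = (1 - pool$omega_confident) * pool$G,
    elsewhere        = pool$G
  )
  out <- pool
  out$G <- min(g + pool$f, pool$G0)
  out
}
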