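# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the CVaR oracle solves the envelope linear program
# by vertex enumeration, the planner oracle re-derives values by exhaustive
# recursion over the module-level transition distributions, and the
# posterior oracle integrates the noisy-or model on a dense grid.

# --- CVaR: linear program over the risk envelope, by vertex enumeration ---
# min sum xi_i p_i v_i  s.t.  sum xi_i p_i = 1,  0 <= xi_i <= 1/alpha.
# At a vertex all but one coordinate sit on a box bound; enumerate them.
cvar_lp_oracle <- function(values, probs, alpha) {
  n <- length(values)
  cap <- 1 / alpha
  live <- which(probs > 0)
  best <- Inf
  for (i in live) {
    others <- setdiff(live, i)
    k <- length(others)
    combos <- as.matrix(expand.grid(rep(list(c(0, cap)), k)))
    if (k == 0) combos <- matrix(0, 1, 0)
    mass_others <- if (k > 0) combos %*% probs[others] else matrix(0, 1, 1)
    obj_others <- if (k > 0) combos %*% (probs[others] * values[others]) else matrix(0, 1, 1)
    xi_i <- (1 - mass_others) / probs[i]
    feas <- xi_i >= -1e-12 & xi_i <= cap + 1e-12
    if (any(feas)) {
      obj <- obj_others[feas] + xi_i[feas] * probs[i] * values[i]
      best <- min(best, obj)
    }
  }
  best
}

# --- Planner: exhaustive enumeration with per-stage distortion -----------
# Mirrors the Bellman semantics through the public module surface only
# (available_actions, transition_distribution, cvar_distort), independent of
# the compiled tree search.
ref_plan_value <- function(label, tau, belief, pool, alpha, constants,
                           depth) {
  if (depth <= 0 || label == "dead") return(0)
  backup <- function(outs) {
    vals <- vapply(outs, function(o) {
      o$reward + constants$gamma *
        ref_plan_value(o$label, o$tau, o$belief, o$pool, alpha, constants,
                       depth - 1)
    }, numeric(1))
    probs <- vapply(outs, `[[`, numeric(1), "prob")
    cvar_distort(vals, probs, alpha)$value
  }
  if (label %in% c("cautious_detect", "confident_detect")) {
    return(backup(transition_distribution(label, tau, "resolve", belief,
                                          pool, constants)))
  }
  acts <- available_actions(label, tau)
  max(vapply(acts, function(a) {
    backup(transition_distribution(label, tau, a, belief, pool, constants))
  }, numeric(1)))
}

ref_plan_values <- function(label, tau, belief, pool, alpha, constants,
                            depth) {
  acts <- available_actions(label, tau)
  vapply(acts, function(a) {
    outs <- transition_distribution(label, tau, a, belief, pool, constants)
    vals <- vapply(outs, function(o) {
      o$reward + constants$gamma *
        ref_plan_value(o$label, o$tau, o$belief, o$pool, alpha, constants,
                       depth - 1)
    }, numeric(1))
    cvar_distort(vals, vapply(outs, `[[`, numeric(1), "prob"), alpha)$value
  }, numeric(1))
}

# Risk-neutral variant: plain expectation instead of the distortion.
ref_expectimax_value <- function(label, tau, belief, pool, constants,
                                 depth) {
  if (depth <= 0 || label == "dead") return(0)
  backup <- function(outs) {
    sum(vapply(outs, function(o) {
      o$prob * (o$reward + constants$gamma *
                  ref_expectimax_value(o$label, o$tau, o$belief, o$pool,
                                       constants, depth - 1))
    }, numeric(1)))
  }
  if (label %in% c("cautious_detect", "confident_detect")) {
    return(backup(transition_distribution(label, tau, "resolve", belief,
                                          pool, constants)))
  }
  acts <- available_actions(label, tau)
  max(vapply(acts, function(a) {
    backup(transition_distribution(label, tau, a, belief, pool, constants))
  }, numeric(1)))
}

# Random hyperstate generator for planner comparisons.
random_hyperstate <- function() {
  mu <- runif(3, 0.05, 0.6)
  v <- runif(3, 0.05, 0.8) * (mu - mu^2)
  belief <- hazard_belief(mu, v)
  G0 <- runif(1, 2, 30)
  pool <- pool_state(G0, f = runif(1, 0, 1.5), G = runif(1, 0, G0))
  states <- list(c("nest", 0L), c("cautious_object", 1L),
                 c("cautious_object", 2L), c("cautious_object", 3L),
                 c("confident_object", 2L), c("confident_object", 4L))
  s <- states[[sample.int(length(states), 1)]]
  list(label = s[1], tau = as.integer(s[2]), belief = belief, pool = pool,
       alpha = runif(1, 0.3, 1))
}

# --- Noisy-or posterior: grid integration --------------------------------
# Discretises each theta_j, applies Bayes' rule for a set of safe bouts,
# and returns the posterior predictive hazard h(tau).
grid_posterior_hazard <- function(mu, v, bout_lengths, tau, m = 4000L) {
  edges <- seq(0, 1, length.out = m + 1L)
  theta <- (edges[-1] + edges[-(m + 1L)]) / 2
  surv <- 1
  for (j in 2:tau) {
    p <- beta_from_mean_var(mu[j - 1], v[j - 1])
    # exact prior mass per cell (robust to the density's edge singularities)
    prior <- diff(stats::pbeta(edges, p$a, p$b))
    c_j <- sum(bout_lengths >= j)  # safe observations covering turn j
    post <- prior * (1 - theta)^c_j
    post <- post / sum(post)
    surv <- surv * sum(post * (1 - theta))
  }
  1 - surv
}

# --- Misc helpers ---------------------------------------------------------
# Hand-build a trajectory data frame from a bout description: each bout is
# (gap_before in nest turns, length, type).
build_trajectory <- function(bouts, tail_nest = 2L) {
  state <- character(0); action <- character(0); tau <- integer(0)
  for (i in seq_len(nrow(bouts))) {
    g <- bouts$gap[i]; len <- bouts$length[i]; type <- bouts$type[i]
    obj <- paste0(type, "_object")
    if (g > 1) {
      state <- c(state, rep("nest", g - 1L))
      action <- c(action, rep("stay_nest", g - 1L))
      tau <- c(tau, rep(0L, g - 1L))
    }
    state <- c(state, "nest", rep(obj, len))
    action <- c(action, paste0("approach_", type),
                rep("stay_object", len - 1L), "retreat")
    tau <- c(tau, 0L, seq_len(len))
  }
  state <- c(state, rep("nest", tail_nest))
  action <- c(action, rep("stay_nest", tail_nest))
  tau <- c(tau, rep(0L, tail_nest))
  data.frame(turn = seq_along(state), state = state, tau = tau,
             action = action, G = NA_real_, stringsAsFactors = FALSE)
}
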