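#' Normalised L1 distance between statistic vectors
#'
#' The ABC distance between simulated statistics `x` and observed
#' statistics `x0` is
#' \deqn{d(x, x_0) = \frac{1}{n} \sum_i \frac{|x^i - x_0^i|}{C^i(x^i)},}
#' where the normaliser depends on the statistic type and is evaluated at
#' the *simulated* value (the distance is intentionally asymmetric):
#' durations use the constant \eqn{C = 4} s; transition times use the
#' piecewise-linear \eqn{C(x) = \min(30, 10 + 0.8 \max(x - 5, 0))};
#' frequency ratios use \eqn{C(x) = \min(20, 2 + \frac{18}{19}
#' \max(x - 1, 0))}. The piecewise caps prevent extreme values from
#' dominating the fit.
#'
#' @param x Simulated `stat_vector`.
#' @param x0 Observed `stat_vector` of the same group/shape.
#' @return A non-negative scalar distance.
#' @export
abc_distance <- function(x, x0) {
  if (length(x) != length(x0)) {
    stop("statistic vectors have different lengths (", length(x), " vs ",
         length(x0), "); were they computed for the same group?",
         call. = FALSE)
  }
  types <- attr(x, "stat_types")
  if (is.null(types)) types <- attr(x0, "stat_types")
  if (is.null(types)) {
    stop("no `stat_types` attribute found on either vector", call. = FALSE)
  }
  cc <- vapply(seq_along(x), function(i) stat_normalizer(x[[i]], types[[i]]),
               numeric(1))
  mean(abs(as.numeric(x) - as.numeric(x0)) / cc)
}

# Internal: per-type normaliser, evaluated at the simulated value.
stat_normalizer <- function(value, type) {
  switch(type,
    duration = 4.0,
    time = min(30, 10 + 0.8 * max(value - 5, 0)),
    ratio = min(20, 2 + (18 / 19) * max(value - 1, 0)),
    stop("unknown statistic type: ", type, call. = FALSE)
  )
}

#' Silverman rule-of-thumb perturbation bandwidth
#'
#' Per-dimension Gaussian kernel scale
#' \eqn{0.9 \min(\mathrm{sd}, \mathrm{IQR}/1.34)\, B^{-1/5}} for a particle
#' population of size B; dimensions with no spread are floored at a small
#' positive value so the kernel stays proper.
#'
#' @param particles Numeric matrix, one particle per row.
#' @param floor Minimum scale (default 1e-8).
#' @return Numeric vector of per-dimension scales.
#' @export
silverman_bandwidth <- function(particles, floor = 1e-8) {
  particles <- as.matrix(particles)
  B <- nrow(particles)
  stopifnot(B >= 2L)
  apply(particles, 2L, function(col) {
    spread <- min(stats::sd(col), stats::IQR(col) / 1.34)
    max(0.9 * spread * B^(-1 / 5), floor)
  })
}

#' Uniform prior ranges for the nine agent parameters
#'
#' Hazard prior means are uniform on (0.01, 0.99); each variance is uniform
#' on its admissible range \eqn{(0, \mu - \mu^2)} conditional on the
#' sampled mean; the risk level is uniform on (0.05, 1); the initial pool
#' on (2, 40); the forgetting rate on (0, 2). The ranges span all three
#' behavioural phenotypes in pilot simulations and are overridable.
#'
#' @param mu_range,alpha_range,G0_range,f_range Length-2 numeric ranges.
#' @return An `abc_priors` object.
#' @export
abc_priors <- function(mu_range = c(0.01, 0.99), alpha_range = c(0.05, 1),
                       G0_range = c(2, 40), f_range = c(0, 2)) {
  structure(list(mu = mu_range, alpha = alpha_range, G0 = G0_range,
                 f = f_range), class = "abc_priors")
}

PARAM_NAMES <- c("mu2", "mu3", "mu4", "v2", "v3", "v4", "alpha", "G0", "f")

# Internal: one draw from the prior, as a named length-9 vector.
sample_prior <- function(priors) {
  mu <- stats::runif(3, priors$mu[1], priors$mu[2])
  v <- stats::runif(3, 0, mu - mu^2)
  stats::setNames(c(mu, v,
                    stats::runif(1, priors$alpha[1], priors$alpha[2]),
                    stats::runif(1, priors$G0[1], priors$G0[2]),
                    stats::runif(1, priors$f[1], priors$f[2])),
                  PARAM_NAMES)
}

# Internal: prior support indicator (includes the Beta variance constraint).
in_prior_support <- function(theta, priors) {
  mu <- theta[1:3]; v <- theta[4:6]
  all(mu > priors$mu[1], mu < priors$mu[2],
      v > 0, v < mu - mu^2,
      theta[7] > priors$alpha[1], theta[7] <= priors$alpha[2],
      theta[8] > priors$G0[1], theta[8] < priors$G0[2],
      theta[9] >= priors$f[1], theta[9] < priors$f[2])
}

# Internal: prior density (only the variance factors depend on theta; the
# uniform constants matter for none of the weight ratios but are included
# for completeness).
prior_density <- function(theta, priors) {
  if (!in_prior_support(theta, priors)) return(0)
  mu <- theta[1:3]
  base <- 1 / diff(priors$mu)^3 / diff(priors$alpha) / diff(priors$G0) /
    diff(priors$f)
  base * prod(1 / (mu - mu^2))
}

#' Convert a parameter vector to an `agent_params` object
#'
#' @param theta Named length-9 vector in the order mu2, mu3, mu4, v2, v3,
#'   v4, alpha, G0, f.
#' @return An [agent_params()].
#' @export
theta_to_params <- function(theta) {
  agent_params(mu = theta[1:3], v = theta[4:6], alpha = theta[[7]],
               G0 = theta[[8]], f = theta[[9]])
}

#' Configuration for an ABC-SMC fit
#'
#' @param B Population size (default 100).
#' @param T_gen Number of populations (default 30).
#' @param percentile Quantile of the previous population's distances used
#'   as the next acceptance threshold (default 0.3).
#' @param seed Integer seed for the fit's random stream.
#' @param n_turns Simulation length per particle (default 200).
#' @param depth Planner horizon (default 5).
#' @param max_attempts_factor Retry budget per generation, as a multiple of
#'   `B` (default 30).
#' @param accept_floor Early-stop floor on the acceptance rate
#'   (default 0.01).
#' @param priors An [abc_priors()].
#' @param constants An [env_constants()].
#' @return An `abc_config` list.
#' @export
abc_config <- function(B = 100L, T_gen = 30L, percentile = 0.3, seed = 1L,
                       n_turns = 200L, depth = 5L,
                       max_attempts_factor = 30, accept_floor = 0.01,
                       priors = abc_priors(), constants = env_constants()) {
  stopifnot(B >= 2, T_gen >= 1, percentile > 0, percentile < 1)
  structure(list(B = B, T_gen = T_gen, percentile = percentile, seed = seed,
                 n_turns = n_turns, depth = depth,
                 max_attempts_factor = max_attempts_factor,
                 accept_floor = accept_floor, priors = priors,
                 constants = constants),
            class = "abc_config")
}

#' Fit agent parameters to observed statistics by ABC-SMC
#'
#' Sequential Monte Carlo approximate Bayesian computation in the standard
#' sequential importance-resampling scheme: generation 0 draws particles
#' from the uniform priors and accepts all of them; each later generation
#' resamples the previous population proportionally to its weights,
#' perturbs with a diagonal Gaussian kernel whose per-dimension bandwidth
#' follows the Silverman heuristic, rejects proposals outside prior support
#' (including the Beta variance constraint), simulates the agent, and
#' accepts when the normalised L1 distance to `observed` is at most
#' \eqn{\epsilon_t}, the lowest 30-percentile of the previous generation's
#' accepted distances; accepted particles get importance weights
#' \eqn{w \propto \pi(\theta) / \sum_j w_j K_t(\theta \mid \theta_j)}. The
#' threshold sequence is non-increasing by construction. A generation that
#' exhausts its retry budget returns the populations accumulated so far
#' with a warning; fitting also stops early when the acceptance rate
#' collapses below the configured floor.
#'
#' @param observed Observed `stat_vector` (from [extract_statistics()] or
#'   [model_statistics()]); its `group` attribute fixes the statistic
#'   schema that simulated trajectories are summarised into.
#' @param config An [abc_config()].
#' @param verbose Print a line per generation.
#' @return An `abc_fit`: list of populations, each with `particles` (B x 9
#'   matrix), `weights`, `distances`, `epsilon`, `generation`, and
#'   `acceptance_rate`.
#' @export
run_abcsmc <- function(observed, config = abc_config(), verbose = FALSE) {
  stopifnot(inherits(observed, "stat_vector"), inherits(config, "abc_config"))
  group <- attr(observed, "group")
  priors <- config$priors
  set.seed(config$seed)

  sim_distance <- function(theta) {
    traj <- simulate_agent(theta_to_params(theta), n_turns = config$n_turns,
                           constants = config$constants, depth = config$depth)
    abc_distance(model_statistics(traj, group = group)$stats, observed)
  }

  B <- config$B
  populations <- vector("list", config$T_gen)

  particles <- t(vapply(seq_len(B), function(i) sample_prior(priors),
                        numeric(9)))
  colnames(particles) <- PARAM_NAMES
  distances <- apply(particles, 1L, sim_distance)
  weights <- rep(1 / B, B)
  populations[[1]] <- list(particles = particles, weights = weights,
                           distances = distances, epsilon = Inf,
                           generation = 0L, acceptance_rate = 1)
  if (verbose) {
    message(sprintf("gen 0: mean distance %.4f", mean(distances)))
  }

  for (t in seq_len(config$T_gen - 1L)) {
    eps <- as.numeric(stats::quantile(distances, config$percentile,
                                      names = FALSE))
    bw <- silverman_bandwidth(particles)
    new_particles <- matrix(NA_real_, B, 9,
                            dimnames = list(NULL, PARAM_NAMES))
    new_weights <- numeric(B)
    new_distances <- numeric(B)
    accepted <- 0L
    attempts <- 0L
    budget <- ceiling(config$max_attempts_factor * B)
    while (accepted < B && attempts < budget) {
      attempts <- attempts + 1L
      j <- sample.int(B, 1L, prob = weights)
      theta <- particles[j, ] + stats::rnorm(9, 0, bw)
      if (!in_prior_support(theta, priors)) next
      d <- sim_distance(theta)
      if (d > eps) next
      accepted <- accepted + 1L
      kern <- vapply(seq_len(B), function(k) {
        prod(stats::dnorm(theta, particles[k, ], bw))
      }, numeric(1))
      new_particles[accepted, ] <- theta
      new_weights[accepted] <- prior_density(theta, priors) /
        sum(weights * kern)
      new_distances[accepted] <- d
    }
    if (accepted == 0L) {
      warning("ABC-SMC generation ", t, ": no acceptances within the retry ",
              "budget (", budget, " proposals) at epsilon = ",
              signif(eps, 4), "; returning the populations fitted so far",
              call. = FALSE)
      break
    }
    particles <- new_particles[seq_len(accepted), , drop = FALSE]
    weights <- new_weights[seq_len(accepted)] /
      sum(new_weights[seq_len(accepted)])
    distances <- new_distances[seq_len(accepted)]
    rate <- accepted / attempts
    populations[[t + 1L]] <- list(particles = particles, weights = weights,
                                  distances = distances, epsilon = eps,
                                  generation = t, acceptance_rate = rate)
    if (verbose) {
      message(sprintf("gen %d: eps %.4f, %d/%d accepted, mean distance %.4f",
                      t, eps, accepted, attempts, mean(distances)))
    }
    if (accepted < B) {
      warning("ABC-SMC generation ", t, ": only ", accepted, " of ", B,
              " particles accepted within the retry budget", call. = FALSE)
      break
    }
    if (rate < config$accept_floor) break
  }
  populations <- populations[!vapply(populations, is.null, logical(1))]
  structure(list(populations = populations, observed = observed,
                 config = config), class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat(sprintf("<abc_fit> %d populations (target group %s)\n",
              length(x$populations), attr(x$observed, "group")))
  for (p in x$populations) {
    cat(sprintf("  gen %2d: eps %8.4f  mean dist %.4f  n %d\n",
                p$generation, p$epsilon, mean(p$distances),
                length(p$distances)))
  }
  invisible(x)
}

#' Flatten an ABC-SMC fit into one data frame of particles
#'
#' @param x An `abc_fit`.
#' @param ... Unused.
#' @return A data frame with the nine parameters plus `weight`, `distance`,
#'   and `generation` columns, one row per particle.
#' @export
as.data.frame.abc_fit <- function(x, ...) {
  do.call(rbind, lapply(x$populations, function(p) {
    df <- as.data.frame(p$particles)
    df$weight <- p$weights
    df$distance <- p$distances
    df$generation <- p$generation
    df
  }))
}
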