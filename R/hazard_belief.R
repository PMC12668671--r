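#' Convert a (mean, variance) Beta parameterisation to pseudocounts
#'
#' The hazard prior over each per-turn detection probability is specified by
#' its mean \eqn{\mu} and variance \eqn{v} because these give a more uniform
#' parameter space for fitting; inference works with pseudocounts
#' \eqn{(a, b)} to exploit Beta--Bernoulli conjugacy. The identities are
#' \deqn{a = -\mu(\mu^2 - \mu + v)/v, \qquad b = (\mu - 1)(\mu^2 - \mu + v)/v.}
#' A Beta distribution with mean \eqn{\mu} can only have variance
#' \eqn{v < \mu - \mu^2}, so the constraint is enforced strictly.
#'
#' @param mu Mean, strictly inside (0, 1).
#' @param v Variance, strictly inside (0, mu - mu^2).
#' @return An object of class `beta_param`: a list with elements `a`, `b`,
#'   `mean`, `var`.
#' @examples
#' beta_from_mean_var(0.5, 1/12)  # Beta(1, 1), the uniform distribution
#' @export
beta_from_mean_var <- function(mu, v) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(v), length(v) == 1L)
  if (!(mu > 0 && mu < 1)) {
    stop("`mu` must lie strictly in (0, 1); got ", mu, call. = FALSE)
  }
  if (!(v > 0)) {
    stop("`v` must be strictly positive; got ", v, call. = FALSE)
  }
  if (!(v < mu - mu^2)) {
    stop("`v` must be strictly less than mu - mu^2 = ", mu - mu^2,
         " (otherwise pseudocounts are non-positive); got ", v, call. = FALSE)
  }
  common <- (mu^2 - mu + v) / v  # negative under the constraints above
  a <- -mu * common
  b <- (mu - 1) * common
  structure(list(a = a, b = b, mean = mu, var = v), class = "beta_param")
}

#' Recompute the mean and variance of a Beta(a, b) distribution
#'
#' Moment round-trip companion of [beta_from_mean_var()].
#'
#' @param a,b Positive pseudocounts.
#' @return Named numeric vector with elements `mean` and `var`.
#' @export
beta_moments <- function(a, b) {
  stopifnot(a > 0, b > 0)
  m <- a / (a + b)
  c(mean = m, var = a * b / ((a + b)^2 * (a + b + 1)))
}

#' Construct a noisy-or hazard belief
#'
#' The probability that a lurking predator has detected the agent after
#' \eqn{\tau} turns at the object is modelled as a noisy-or over independent
#' per-turn Bernoulli detection causes \eqn{Z_j \sim \mathrm{Bernoulli}(\theta_j)}:
#' \deqn{h(\tau) = 1 - \prod_{j=1}^{\tau} (1 - \theta_j),}
#' with \eqn{\theta_1 = 0} structurally (the approach turn itself is safe,
#' which also codes the act of approaching) and independent Beta priors on
#' \eqn{\theta_2, \theta_3, \theta_4}. The construction guarantees a
#' monotonically non-decreasing hazard, the agent's inductive bias that a
#' predator accumulates evidence about its presence.
#'
#' @param mu Numeric vector of length 3: prior means for tau = 2, 3, 4.
#' @param v Numeric vector of length 3: prior variances for tau = 2, 3, 4;
#'   each must satisfy `0 < v < mu - mu^2`.
#' @return An object of class `hazard_belief`: a list with numeric vectors
#'   `a` and `b` (named "2", "3", "4").
#' @examples
#' bel <- hazard_belief(mu = c(0.28, 0.4, 0.5), v = c(0.01, 0.01, 0.01))
#' hazard_predictive(bel, 4)
#' @export
hazard_belief <- function(mu, v) {
  stopifnot(length(mu) == 3L, length(v) == 3L)
  ab <- mapply(function(m, vv) {
    p <- beta_from_mean_var(m, vv)
    c(p$a, p$b)
  }, mu, v)
  structure(
    list(a = stats::setNames(ab[1, ], c("2", "3", "4")),
         b = stats::setNames(ab[2, ], c("2", "3", "4"))),
    class = "hazard_belief"
  )
}

#' @export
print.hazard_belief <- function(x, ...) {
  mu <- x$a / (x$a + x$b)
  cat("<hazard_belief>\n")
  for (j in 1:3) {
    cat(sprintf("  tau=%d: Beta(a=%.4g, b=%.4g), mean=%.4f\n",
                j + 1L, x$a[[j]], x$b[[j]], mu[[j]]))
  }
  cat(sprintf("  h(2)=%.4f h(3)=%.4f h(4)=%.4f\n",
              hazard_predictive(x, 2), hazard_predictive(x, 3),
              hazard_predictive(x, 4)))
  invisible(x)
}

# Posterior means (mu_2, mu_3, mu_4) of the per-turn detection causes.
posterior_means <- function(belief) belief$a / (belief$a + belief$b)

#' Posterior predictive hazard
#'
#' Probability of having been detected by turn `tau` at the object under the
#' current belief: \eqn{h(\tau) = 1 - \prod_{j=1}^{\tau} (1 - \mu_j)} with
#' \eqn{\mu_j} the posterior mean of \eqn{\theta_j} and \eqn{\mu_1 = 0}.
#' Equivalently, by recursion,
#' \eqn{h(\tau) = h(\tau-1) + (1 - h(\tau-1))\,\mu_\tau}.
#'
#' @param belief A [hazard_belief()].
#' @param tau Integer number of turns at the object, in 1..4.
#' @return Probability in \[0, 1\].
#' @export
hazard_predictive <- function(belief, tau) {
  stopifnot(inherits(belief, "hazard_belief"))
  if (!(length(tau) == 1L && tau %in% 1:4)) {
    stop("`tau` must be a single integer in 1..4; got ", tau, call. = FALSE)
  }
  if (tau == 1L) return(0)
  mu <- posterior_means(belief)
  1 - prod(1 - mu[seq_len(tau - 1L)])
}

#' Update the hazard belief after a safe bout
#'
#' A completed bout of length `tau` with no detection is the observation
#' \eqn{X_\tau = 0}, i.e. every per-turn cause \eqn{Z_j, j \le \tau} was 0.
#' The conjugate posterior simply increments the failure pseudocount
#' \eqn{b_j} for every \eqn{j \in \{2, \dots, \tau\}}; beliefs for longer
#' stays than experienced are untouched directly, but the predictive hazard
#' at every horizon still decreases (the noisy-or generalises across bout
#' lengths). Positive (detection) observations never occur in this
#' environment, so only this closed-form branch of the noisy-or posterior is
#' needed. The input belief is never mutated.
#'
#' @param belief A [hazard_belief()].
#' @param tau Realised bout length in turns, in 2..4.
#' @return A new `hazard_belief`.
#' @export
observe_safe_bout <- function(belief, tau) {
  stopifnot(inherits(belief, "hazard_belief"))
  if (!(length(tau) == 1L && tau %in% 2:4)) {
    stop("`tau` must be a single integer in 2..4; got ", tau, call. = FALSE)
  }
  out <- belief
  idx <- seq_len(tau - 1L)  # positions for j = 2..tau
  out$b[idx] <- out$b[idx] + 1
  out
}

#' Serialize a hazard belief to JSON
#'
#' Writes the pseudocounts as `{"2": {"a": ..., "b": ...}, ...}` for
#' checkpointing fits.
#'
#' @param belief A [hazard_belief()].
#' @return A JSON string.
#' @export
belief_to_json <- function(belief) {
  stopifnot(inherits(belief, "hazard_belief"))
  obj <- lapply(stats::setNames(1:3, names(belief$a)), function(j) {
    list(a = belief$a[[j]], b = belief$b[[j]])
  })
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Restore a hazard belief from JSON
#'
#' @param json A string produced by [belief_to_json()].
#' @return A `hazard_belief`.
#' @export
belief_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  stopifnot(setequal(names(obj), c("2", "3", "4")))
  structure(
    list(a = vapply(c("2", "3", "4"), function(k) obj[[k]]$a, numeric(1)),
         b = vapply(c("2", "3", "4"), function(k) obj[[k]]$b, numeric(1))),
    class = "hazard_belief"
  )
}
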