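stat_vec <- function(values, types, group = "timid") {
  structure(as.numeric(values), stat_types = types, group = group,
            class = "stat_vector")
}

test_that("the normalised L1 distance uses the documented per-type normalisers", {
  x <- stat_vec(c(30, 2, 2, 3), c("time", "duration", "duration", "ratio"))
  expect_equal(abc_distance(x, x), 0)

  # a single duration statistic: |4 - 0| / 4 = 1
  expect_equal(abc_distance(stat_vec(4, "duration"), stat_vec(0, "duration")),
               1)

  # transition-time normaliser: C(5) = 10, capped at 30 for large values
  expect_equal(riskbout:::stat_normalizer(5, "time"), 10)
  expect_equal(riskbout:::stat_normalizer(40, "time"), 30)
  # frequency-ratio normaliser: C(1) = 2, C(20) = 20
  expect_equal(riskbout:::stat_normalizer(1, "ratio"), 2)
  expect_equal(riskbout:::stat_normalizer(20, "ratio"), 20)
  expect_equal(riskbout:::stat_normalizer(7, "duration"), 4)

  # asymmetry: the normaliser is evaluated at the simulated (first) value
  a <- stat_vec(5, "time"); b <- stat_vec(45, "time")
  expect_equal(abc_distance(a, b), 40 / 10)
  expect_equal(abc_distance(b, a), 40 / 30)

  expect_error(abc_distance(stat_vec(c(1, 2), c("time", "ratio")),
                            stat_vec(1, "time")), "different lengths")
})

test_that("the Silverman bandwidth follows the rule of thumb", {
  set.seed(71)
  x <- matrix(rnorm(100 * 2), 100, 2)
  bw <- silverman_bandwidth(x)
  for (j in 1:2) {
    expected <- 0.9 * min(sd(x[, j]), IQR(x[, j]) / 1.34) * 100^(-1 / 5)
    expect_equal(bw[j], expected)
  }
  # a degenerate dimension gets the positive floor
  y <- cbind(rnorm(50), rep(2, 50))
  expect_equal(silverman_bandwidth(y)[2], 1e-8)
  # homogeneity: doubling the particles doubles the scale
  expect_equal(silverman_bandwidth(2 * x), 2 * bw, tolerance = 1e-12)
})

test_that("prior draws respect their ranges and the Beta variance constraint", {
  set.seed(72)
  pr <- abc_priors()
  for (i in 1:200) {
    th <- riskbout:::sample_prior(pr)
    expect_true(riskbout:::in_prior_support(th, pr))
    expect_true(all(th[4:6] < th[1:3] - th[1:3]^2))
    p <- theta_to_params(th)  # must construct without error
    expect_s3_class(p, "agent_params")
  }
  out <- c(mu2 = 0.5, mu3 = 0.5, mu4 = 0.5, v2 = 0.26, v3 = 0.1, v4 = 0.1,
           alpha = 0.5, G0 = 10, f = 1)
  expect_false(riskbout:::in_prior_support(out, pr))  # v2 >= mu - mu^2
})

test_that("a tiny ABC-SMC run is well-formed and self-consistent", {
  target <- generate_model_target(phenotype_params("timid"), n_turns = 100)
  # the generating parameters themselves are at distance zero
  self_stats <- model_statistics(
    simulate_agent(phenotype_params("timid"), n_turns = 100),
    group = "timid")$stats
  expect_equal(abc_distance(self_stats, target), 0)

  cfg <- abc_config(B = 8L, T_gen = 3L, seed = 7L, n_turns = 100L)
  fit <- run_abcsmc(target, cfg)
  expect_s3_class(fit, "abc_fit")
  expect_gte(length(fit$populations), 2)
  for (p in fit$populations) {
    expect_equal(sum(p$weights), 1, tolerance = 1e-9)
    expect_true(all(p$distances <= p$epsilon))
    expect_true(all(apply(p$particles, 1, riskbout:::in_prior_support,
                          priors = cfg$priors)))
  }
  eps <- vapply(fit$populations[-1], `[[`, numeric(1), "epsilon")
  expect_true(all(diff(eps) <= 1e-12))

  df <- as.data.frame(fit)
  expect_true(all(c("mu2", "alpha", "weight", "distance", "generation") %in%
                    names(df)))

  # same seed, same fit
  fit2 <- run_abcsmc(target, cfg)
  expect_identical(fit$populations[[length(fit$populations)]]$particles,
                   fit2$populations[[length(fit2$populations)]]$particles)
})
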