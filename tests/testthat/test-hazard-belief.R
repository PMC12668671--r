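test_that("mean/variance to pseudocount transform matches known Betas and round-trips", {
  p <- beta_from_mean_var(0.5, 1 / 12)
  expect_equal(p$a, 1, tolerance = 1e-12)
  expect_equal(p$b, 1, tolerance = 1e-12)

  p <- beta_from_mean_var(0.5, 0.125)
  expect_equal(p$a, 0.5, tolerance = 1e-12)
  expect_equal(p$b, 0.5, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    mu <- runif(1, 0.01, 0.99)
    v <- runif(1, 1e-6, 1) * (mu - mu^2) * 0.999
    p <- beta_from_mean_var(mu, v)
    expect_gt(p$a, 0)
    expect_gt(p$b, 0)
    m <- beta_moments(p$a, p$b)
    expect_equal(unname(m["mean"]), mu, tolerance = 1e-12)
    expect_equal(unname(m["var"]), v, tolerance = 1e-12)
  }
})

test_that("the variance bound and mean range are enforced by name", {
  expect_error(beta_from_mean_var(0.5, 0.25), "mu - mu\\^2")
  expect_error(beta_from_mean_var(0.5, 0.3), "mu - mu\\^2")
  expect_error(beta_from_mean_var(1.2, 0.01), "\\(0, 1\\)")
  expect_error(beta_from_mean_var(0.5, 0), "positive")
})

test_that("predictive hazard follows the noisy-or product and its recursion", {
  bel <- hazard_belief(c(0.5, 0.5, 0.3), c(0.05, 0.05, 0.05))
  expect_identical(hazard_predictive(bel, 1), 0)
  expect_equal(hazard_predictive(bel, 3), 0.75)  # 1 - (1-.5)(1-.5)
  expect_equal(hazard_predictive(bel, 4), 1 - 0.5 * 0.5 * 0.7)

  set.seed(12)
  for (i in 1:20) {
    mu <- runif(3, 0.01, 0.9)
    bel <- hazard_belief(mu, runif(3, 0.1, 0.9) * (mu - mu^2))
    mus <- bel$a / (bel$a + bel$b)
    for (tau in 2:4) {
      h_prev <- hazard_predictive(bel, tau - 1)
      expect_equal(hazard_predictive(bel, tau),
                   h_prev + (1 - h_prev) * mus[[tau - 1]], tolerance = 1e-12)
      expect_gte(hazard_predictive(bel, tau), h_prev)  # monotone hazard
    }
  }
  expect_error(hazard_predictive(bel, 5), "1..4")
})

test_that("safe-bout updates increment failure counts up to tau and lower hazard", {
  bel <- hazard_belief(c(0.5, 0.5, 0.5), c(0.05, 0.05, 0.05))
  bel11 <- bel
  bel11$a[] <- 1; bel11$b[] <- 1  # Beta(1,1) everywhere
  up <- observe_safe_bout(bel11, 3)
  expect_equal(unname(up$b), c(2, 2, 1))
  expect_equal(unname(up$a), c(1, 1, 1))
  expect_equal(hazard_predictive(up, 3), 5 / 9, tolerance = 1e-12)

  # only j <= tau changes
  up2 <- observe_safe_bout(bel, 2)
  expect_equal(unname(up2$b[2:3]), unname(bel$b[2:3]))
  expect_gt(unname(bel$b[1]) + 1 - unname(up2$b[1]), -1e-15)

  # input belief untouched (value semantics)
  expect_equal(unname(bel11$b), c(1, 1, 1))

  # posterior predictive never increases, for every horizon
  for (tau in 2:4) {
    for (k in 1:4) {
      expect_lte(hazard_predictive(observe_safe_bout(bel, tau), k),
                 hazard_predictive(bel, k) + 1e-15)
    }
  }

  # repeated safe bouts drive the hazard to zero monotonically
  h_seq <- numeric(200)
  cur <- bel
  for (i in 1:200) {
    cur <- observe_safe_bout(cur, 4)
    h_seq[i] <- hazard_predictive(cur, 4)
  }
  expect_true(all(diff(h_seq) < 0))
  expect_lt(h_seq[200], 0.05)
})

test_that("learning about short stays generalises to longer ones", {
  bel <- hazard_belief(c(0.3, 0.4, 0.5), c(0.02, 0.02, 0.02))
  up <- observe_safe_bout(bel, 2)
  expect_lt(hazard_predictive(up, 3), hazard_predictive(bel, 3))
  expect_lt(hazard_predictive(up, 4), hazard_predictive(bel, 4))
})

test_that("closed-form posterior predictive matches grid integration", {
  mu <- c(0.3, 0.45, 0.5)
  v <- c(0.04, 0.05, 0.06)
  cases <- list(2L, c(2L, 2L, 2L), c(2L, 3L), c(3L, 4L, 4L),
                rep(4L, 10), c(2L, 2L, 3L, 3L, 4L))
  for (bouts in cases) {
    bel <- hazard_belief(mu, v)
    for (tau in bouts) bel <- observe_safe_bout(bel, tau)
    for (tau in 2:4) {
      expect_equal(hazard_predictive(bel, tau),
                   grid_posterior_hazard(mu, v, bouts, tau),
                   tolerance = 1e-3)
    }
  }
})

test_that("beliefs serialise to and from JSON losslessly", {
  bel <- observe_safe_bout(hazard_belief(c(0.2, 0.3, 0.4),
                                         c(0.01, 0.02, 0.03)), 3)
  js <- belief_to_json(bel)
  expect_match(js, "\"2\"")
  back <- belief_from_json(js)
  expect_equal(unname(back$a), unname(bel$a), tolerance = 1e-12)
  expect_equal(unname(back$b), unname(bel$b), tolerance = 1e-12)
})
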