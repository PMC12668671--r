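test_that("action sets encode the bout structure", {
  expect_setequal(available_actions("nest"),
                  c("stay_nest", "approach_cautious", "approach_confident"))
  expect_identical(available_actions("cautious_object", 1L), "stay_object")
  expect_setequal(available_actions("cautious_object", 2L),
                  c("stay_object", "retreat"))
  expect_setequal(available_actions("confident_object", 3L),
                  c("stay_object", "retreat"))
  expect_identical(available_actions("confident_object", 4L), "retreat")
  expect_length(available_actions("dead"), 0)
  expect_error(available_actions("cautious_detect"), "chance nodes")
  expect_error(available_actions("lair"), "unknown state")
})

test_that("environment constants validate their orderings", {
  expect_error(env_constants(p1 = 0.3, p2 = 0.6))
  expect_error(env_constants(dying_cost = 0))
  cc <- env_constants()
  expect_lt(cc$p2, cc$p1)
  expect_lt(cc$dying_cost, cc$travel_cost)
})

make_belief <- function(mu, vf = 0.3) hazard_belief(mu, vf * (mu - mu^2))

test_that("transition probabilities are normalised for every state-action pair", {
  bel <- make_belief(c(0.3, 0.4, 0.5))
  pool <- pool_state(8, 0.2)
  cc <- env_constants()
  cases <- list(
    list("nest", 0L, "stay_nest"), list("nest", 0L, "approach_cautious"),
    list("nest", 0L, "approach_confident"),
    list("cautious_object", 1L, "stay_object"),
    list("cautious_object", 2L, "stay_object"),
    list("cautious_object", 3L, "retreat"),
    list("confident_object", 3L, "stay_object"),
    list("confident_object", 4L, "retreat"),
    list("cautious_detect", 2L, "resolve"),
    list("confident_detect", 3L, "resolve")
  )
  for (cs in cases) {
    outs <- transition_distribution(cs[[1]], cs[[2]], cs[[3]], bel, pool, cc)
    expect_equal(sum(vapply(outs, `[[`, numeric(1), "prob")), 1,
                 tolerance = 1e-12)
    expect_true(all(vapply(outs, `[[`, numeric(1), "prob") >= 0))
  }
  expect_error(transition_distribution("nest", 0L, "retreat", bel, pool, cc),
               "not available")
  expect_error(transition_distribution("cautious_detect", 2L, "stay_object",
                                       bel, pool, cc), "resolve")
})

test_that("the first stay decision is exposed to exactly the tau=2 hazard", {
  bel <- make_belief(c(0.5, 0.4, 0.4))
  pool <- pool_state(10, 0.1)
  outs <- transition_distribution("cautious_object", 1L, "stay_object", bel,
                                  pool, env_constants())
  det <- outs[[1]]
  expect_identical(det$label, "cautious_detect")
  expect_equal(det$prob, 0.5)  # h(2) = mu2 since h(1) = 0
})

test_that("stage detect probabilities equal the cumulative noisy-or hazard", {
  bel <- make_belief(c(0.25, 0.35, 0.45))
  pool <- pool_state(6, 0.3)
  cc <- env_constants()
  for (tau in 1:3) {
    outs <- transition_distribution("confident_object", tau, "stay_object",
                                    bel, pool, cc)
    expect_equal(outs[[1]]$prob, hazard_predictive(bel, tau + 1L),
                 tolerance = 1e-12)
    # safe branch carries the incremental belief update for turn tau+1
    expect_equal(unname(outs[[2]]$belief$b[tau]), unname(bel$b[tau]) + 1)
  }
  # a near-zero hazard belief makes staying a near point mass
  tiny <- hazard_belief(rep(1e-6, 3), rep(1e-13, 3))
  outs <- transition_distribution("cautious_object", 2L, "stay_object", tiny,
                                  pool, cc)
  expect_lt(outs[[1]]$prob, 1e-5)
  expect_gt(outs[[2]]$prob, 1 - 1e-5)
})

test_that("detect states resolve into death or escape with the posture-specific risk", {
  bel <- make_belief(c(0.3, 0.3, 0.3))
  pool <- pool_state(5, 0)
  cc <- env_constants(p1 = 0.6, p2 = 0.3, dying_cost = -4)
  for (lab in c("cautious_detect", "confident_detect")) {
    outs <- transition_distribution(lab, 3L, "resolve", bel, pool, cc)
    p_die <- if (lab == "confident_detect") 0.6 else 0.3
    expect_equal(outs[[1]]$prob, p_die)
    expect_identical(outs[[1]]$label, "dead")
    expect_equal(outs[[1]]$reward, -4)
    expect_identical(outs[[2]]$label, "nest")
    expect_identical(outs[[2]]$tau, 0L)
  }
})

test_that("rewards sit on the documented edges and tau resets at the nest", {
  bel <- make_belief(c(0.3, 0.3, 0.3))
  pool <- pool_state(10, 0.2, G = 7)
  cc <- env_constants()
  app <- transition_distribution("nest", 0L, "approach_confident", bel, pool,
                                 cc)[[1]]
  expect_equal(app$reward, cc$travel_cost + imagined_reward(pool, "confident"))
  expect_identical(app$tau, 1L)
  # the approach turn harvests: the successor pool is depleted
  expect_equal(app$pool$G, min((1 - pool$omega_confident) * 7 + 0.2, 10))

  ret <- transition_distribution("cautious_object", 3L, "retreat", bel, pool,
                                 cc)[[1]]
  expect_identical(ret$label, "nest")
  expect_identical(ret$tau, 0L)
  expect_equal(ret$reward, cc$travel_cost)

  stay <- transition_distribution("nest", 0L, "stay_nest", bel, pool, cc)[[1]]
  expect_equal(stay$reward, 0)
})
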