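test_that("unit mappings are the documented linear maps and invert on their domain", {
  expect_identical(agent_duration_to_seconds(2), 0.75)
  expect_identical(agent_duration_to_seconds(4), 3.75)
  expect_identical(agent_duration_to_seconds(3), 2.25)
  expect_identical(map_turns_to_minutes(200), 100)
  expect_identical(map_turns_to_minutes(1), 0.5)
  # invertibility on the discrete domain
  d <- c(2, 3, 4)
  expect_equal((agent_duration_to_seconds(d) - 0.75) / 1.5 + 2, d)
  expect_error(agent_duration_to_seconds(5), "\\{2, 3, 4\\}")
  expect_error(agent_duration_to_seconds(1.5), "\\{2, 3, 4\\}")
})

test_that("boxcar fitting recovers exact steps and declines constant series", {
  fit <- fit_boxcar(c(10, 10, 10, 0, 0))
  expect_identical(fit$changepoint, 4L)
  expect_equal(fit$levels, c(10, 0))

  fit <- fit_boxcar(rep(3.2, 20))
  expect_true(is.na(fit$changepoint))
  expect_equal(fit$levels, 3.2)

  set.seed(61)
  for (i in 1:10) {
    k <- sample(5:45, 1)
    x <- c(rep(8, k - 1), rep(2, 50 - k + 1)) + rnorm(50, 0, 0.3)
    expect_identical(fit_boxcar(x)$changepoint, k)
  }
})

make_record <- function(cau, con, dur = rep(1, length(cau)),
                        freq = rep(1, length(cau))) {
  data.frame(minute = seq_along(cau), pct_cautious = cau, pct_confident = con,
             duration_s = dur, bouts_per_min = freq)
}

test_that("group classification follows the confident-time ratio rule", {
  n <- 60
  no_conf <- make_record(rep(10, n), rep(0, n))
  expect_identical(classify_group(no_conf), "timid")

  # confident time decays from peak to steady state: y = 2 > 1
  conf <- c(rep(0, 20), rep(20, 20), rep(10, 20))
  expect_identical(classify_group(make_record(c(rep(10, 20), rep(0, 40)),
                                              conf)), "brave")

  # steady confident approach: y = 0.8 < 1
  conf <- c(rep(0, 20), rep(8, 20), rep(10, 20))
  expect_identical(classify_group(make_record(c(rep(10, 20), rep(0, 40)),
                                              conf)), "intermediate")

  # the y = 1 boundary is assigned to intermediate
  conf <- c(rep(0, 20), rep(10, 40))
  expect_identical(classify_group(make_record(c(rep(10, 20), rep(0, 40)),
                                              conf)), "intermediate")

  short <- make_record(rep(10, 5), c(0, 0, 5, 5, 5))
  expect_error(classify_group(short), "too short")
})

test_that("statistic extraction is group-specific with the intermediate clamp", {
  rec <- make_record(
    cau = c(rep(10, 20), rep(0, 80)),
    con = c(rep(0, 20), rep(24, 30), rep(6, 50)),
    dur = c(rep(0.75, 20), rep(3.75, 30), rep(2.25, 50)),
    freq = c(rep(1, 20), rep(3, 30), rep(1, 50)))
  ph <- summarize_record(rec)
  expect_identical(ph$group, "brave")
  sv <- extract_statistics(ph)
  expect_identical(names(sv)[1], "t_cautious_to_confident")
  expect_equal(as.numeric(sv), c(21, 51, 0.75, 3.75, 3))

  # intermediate: frequency ratio is clamped at 1 when frequency rises
  rec <- make_record(
    cau = c(rep(10, 30), rep(0, 70)),
    con = c(rep(0, 30), rep(15, 70)),
    dur = c(rep(0.75, 30), rep(2.25, 70)),
    freq = c(rep(0.5, 30), rep(2, 70)))
  sv <- extract_statistics(summarize_record(rec))
  expect_identical(attr(sv, "group"), "intermediate")
  expect_equal(unname(sv["f_ratio"]), 1)
  expect_length(sv, 4)

  # timid: four statistics from the cautious curve alone
  rec <- make_record(
    cau = c(rep(12, 40), rep(4, 60)),
    con = rep(0, 100),
    dur = rep(0.75, 100),
    freq = c(rep(1, 40), rep(0.25, 60)))
  sv <- extract_statistics(summarize_record(rec))
  expect_identical(attr(sv, "group"), "timid")
  expect_equal(as.numeric(sv), c(41, 0.75, 0.75, 4))
})

test_that("model statistics map turns into the animal statistic space", {
  # alternating 1 nest turn / 2 object turns: period 3, frequency 1/3
  spec <- data.frame(gap = rep(1, 20), length = rep(2, 20), type = "cautious")
  tr <- build_trajectory(spec, tail_nest = 1L)
  ms <- model_statistics(tr)
  expect_identical(attr(ms$stats, "group"), "timid")
  expect_equal(ms$phases$peak$frequency, 1 / 3)

  # a confident bout starting at turn 50 maps to a 25-minute transition
  spec <- data.frame(gap = c(1, rep(2, 11), 2, rep(6, 3)),
                     length = c(rep(2, 12), rep(3, 4)),
                     type = c(rep("cautious", 12), rep("confident", 4)))
  tr <- build_trajectory(spec)
  b <- parse_bouts(tr)
  expect_equal(b$start[13], 50)
  ms <- model_statistics(tr)
  expect_identical(attr(ms$stats, "group"), "brave")
  expect_equal(unname(ms$stats["t_cautious_to_confident"]), 25)
  expect_gt(unname(ms$stats["t_peak_to_steady"]),
            unname(ms$stats["t_cautious_to_confident"]))

  # timid simulation: four statistics
  ms <- model_statistics(simulate_agent(phenotype_params("timid")))
  expect_length(ms$stats, 4)

  # no bouts at all: degenerate, maximally timid summary
  all_nest <- data.frame(turn = 1:200, state = "nest", tau = 0L,
                         action = "stay_nest", G = 1)
  ms <- model_statistics(all_nest)
  expect_true(attr(ms$stats, "degenerate"))
  expect_equal(unname(ms$stats["t_peak_to_steady"]), 100)
})

test_that("forcing a statistic schema keeps vectors comparable across groups", {
  traj <- simulate_agent(phenotype_params("timid"))
  sv <- model_statistics(traj, group = "brave")$stats
  expect_identical(attr(sv, "group"), "brave")
  expect_length(sv, 5)
  # a timid trajectory has no confident bouts: the transition is at the end
  expect_equal(unname(sv["t_cautious_to_confident"]), 100)
})
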