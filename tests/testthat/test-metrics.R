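# minimal hand-built event log (no config attached)
tiny_log <- function(choice, active, background, is_switch = NULL,
                     reinforced = NULL) {
  n <- length(choice)
  structure(
    data.frame(index = seq_len(n), session_time = cumsum(rep(1, n)),
               choice = choice, generated_irt = rep(1, n),
               is_switch = is_switch %||% rep(FALSE, n),
               active_time = active, background_time = background,
               reinforced = reinforced %||% rep(FALSE, n),
               stringsAsFactors = FALSE),
    class = c("event_log", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("proportion rich counts choices of the smaller-interval side", {
  log <- tiny_log(c("A", "A", "A", "B"), rep(1, 4), rep(1, 4))
  expect_equal(proportion_rich(log, tail = 4, rich = "A"), 0.75)
  expect_equal(proportion_rich(log, tail = 4, rich = "B"), 0.25)
  expect_equal(proportion_rich(log, tail = 1, rich = "A"), 0)
  expect_error(proportion_rich(log, tail = 10, rich = "A"), "exceeds")
  expect_error(proportion_rich(log, tail = 4), "no configuration")
})

test_that("the M statistic accumulates probability-difference mass by
           correctness", {
  # three stays at A under unit mean intervals; active/background times
  # chosen so the stay/switch probabilities are (.5,.3), (.6,.3), (.3,.4):
  # correct diffs {.2, .3}, incorrect {.1} -> m = 0.5 / 0.6
  t <- function(p) -log(1 - p)
  log <- tiny_log(rep("A", 3),
                  active = t(c(.5, .6, .3)),
                  background = t(c(.3, .3, .4)))
  res <- m_statistic(log, vi_a = 1, vi_b = 1, switch_cost = 0.3,
                     include_cost = FALSE, tail = 3)
  expect_s3_class(res, "m_stat")
  expect_equal(res$sum_correct, 0.5)
  expect_equal(res$sum_incorrect, 0.1)
  expect_equal(res$m, 0.5 / 0.6)

  # minimizing chooser: swap the chosen side -> m = 0
  worst <- tiny_log(rep("A", 2), active = t(c(.2, .3)),
                    background = t(c(.5, .6)))
  expect_equal(m_statistic(worst, vi_a = 1, vi_b = 1, switch_cost = 0,
                           include_cost = FALSE, tail = 2)$m, 0)

  # all exact ties -> undefined
  tie <- tiny_log("A", active = 2, background = 2)
  res <- m_statistic(tie, vi_a = 1, vi_b = 1, switch_cost = 0,
                     include_cost = FALSE, tail = 1)
  expect_true(res$undefined)
  expect_true(is.na(res$m))
})

test_that("momentary maximizing scores M = 1 exactly under the decision
           convention", {
  log <- std_session("momentary_max")
  res <- m_statistic(log)
  expect_identical(res$m, 1)
  expect_gt(res$sum_correct, 0)
  expect_identical(res$sum_incorrect, 0)
})

test_that("a probability-blind random chooser scores M near one half", {
  cfg <- session_config(20, 60, model = "setstar",
                        model_params = list(switch_prob_a = .5,
                                            switch_prob_b = .5),
                        seed = 41)
  log <- run_session(cfg)
  expect_lt(abs(m_statistic(log, tail = 20000)$m - 0.5), 0.05)
})

test_that("clock spaces carry the schedule-ratio indifference slope and
           round-trip with the raw log", {
  log <- std_session("momentary_max", vis = c(60, 180), n = 2000L,
                     tail = 500L)
  cs <- clock_space(log)
  expect_identical(attr(cs, "slope"), 3)        # 180 / 60
  expect_identical(nrow(cs), 500L)
  expect_true(all(cs$active_t >= 0 & cs$background_t >= 0))
  expect_identical(attr(clock_space(log, vi_a = 45, vi_b = 45), "slope"), 1)

  rec <- reconstruct_clocks(log[1:300, ])
  expect_equal(log$active_time[1:300], rec$active, tolerance = 1e-10)
  expect_equal(log$background_time[1:300], rec$background,
               tolerance = 1e-10)

  # perseveration shows as a stream of points with growing background time
  stays <- which(!log$is_switch & !c(TRUE, log$is_switch[-nrow(log)]))
  runs <- stays[which(diff(stays) == 1)[1] + 0:1]
  expect_gt(log$background_time[runs[2]], log$background_time[runs[1]])
})

test_that("run-length switch functions are flat for stochastic switchers
           and rising for momentary maximizing", {
  # SET* with equal switch probabilities: every bin near the constant p
  cfg <- session_config(20, 60, model = "setstar",
                        model_params = list(switch_prob_a = .4,
                                            switch_prob_b = .4),
                        seed = 43)
  rl <- runlength_switch_function(run_session(cfg), state = "A",
                                  tail = 20000)
  ok <- !rl$low_n
  expect_true(any(ok))
  se <- sqrt(.4 * .6 / rl$n[ok])
  expect_true(all(abs(rl$p_switch[ok] - 0.4) < 3.5 * se))

  # momentary maximizing: switching out of the rich schedule grows with
  # time spent there
  rl <- runlength_switch_function(std_session("momentary_max"),
                                  state = "A", tail = 20000)
  ok <- !rl$low_n
  fit <- stats::lm(p_switch ~ mid, data = rl[ok, ], weights = rl$n[ok])
  expect_gt(stats::confint(fit)["mid", 1], 0)

  # a log with no switches has an all-zero function
  none <- tiny_log(rep("A", 50), active = rep(1, 50),
                   background = cumsum(rep(1, 50)))
  rl <- runlength_switch_function(none, switch_cost = 0.3, tail = 50)
  expect_true(all(rl$p_switch == 0))
})
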