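test_that("active time function lookup is total with right-open bins", {
  expect_error(active_time_function(c(1, 0.5), c(.1, .2, .3)), "increasing")
  expect_error(active_time_function(1, c(.1, 1.5)), "\\[0, 1\\]")
  expect_error(active_time_function(c(1, 2), c(.1, .2)), "per bin")

  fo <- atm_preset("atm_fo_vi20_60")
  rich <- active_time_function(fo$bins, fo$rich)
  lean <- active_time_function(fo$bins, fo$lean)
  expect_identical(atf_lookup(rich, 0.3), 0.43)
  expect_identical(atf_lookup(lean, 0.3), 0.90)
  expect_identical(atf_lookup(rich, 0.5), 0.36)   # right-open edges
  expect_identical(atf_lookup(rich, 100), 0.18)   # unbounded final bin
  expect_identical(atf_lookup(lean, c(1.4, 3.6)), c(0.80, 0.88))
})

test_that("ATM decisions are Bernoulli in the looked-up probability", {
  fo <- atm_preset("atm_fo_vi20_60")
  rich <- active_time_function(fo$bins, fo$rich)
  set.seed(21)
  hits <- mean(replicate(20000, atm_decide(rich, 0.3)) == "switch")
  expect_lt(abs(hits - 0.43), 3 * sqrt(0.43 * 0.57 / 20000))
})

test_that("melioration compares local reinforcement rates", {
  buf <- data.frame(
    choice = c("A", "A", "A", "B", "B"),
    irt = c(4, 3, 3, 10, 10),
    reinforced = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(melioration_local_rates(buf), c(A = 0.2, B = 0.05))
  set.seed(1)
  expect_identical(melioration_decide(buf), "A")  # deterministic

  empty <- data.frame(choice = character(0), irt = numeric(0),
                      reinforced = logical(0))
  expect_equal(melioration_local_rates(empty), c(A = 0, B = 0))
  set.seed(2)
  picks <- replicate(2000, melioration_decide(empty))
  expect_lt(abs(mean(picks == "A") - 0.5), 3 * sqrt(0.25 / 2000))

  tied <- data.frame(choice = c("A", "B"), irt = c(5, 5),
                     reinforced = c(TRUE, TRUE))
  set.seed(3)
  picks <- replicate(2000, melioration_decide(tied))
  expect_lt(abs(mean(picks == "A") - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("SET* switch probabilities follow the molar rate ratio", {
  expect_identical(setstar_switch_probability(1 / 60, 1 / 180), 0.25)
  expect_identical(setstar_switch_probability(1 / 180, 1 / 60), 0.75)
  expect_identical(setstar_switch_probability(2, 2), 0.5)
  expect_error(setstar_switch_probability(0, 1), "positive")
  expect_error(setstar_switch_probability(1, -1), "positive")
})

test_that("SET* simulated preference matches the two-state stationary law", {
  for (pq in list(c(.25, .75), c(.5, .5), c(.1, .3))) {
    cfg <- session_config(20, 60, model = "setstar",
                          model_params = list(switch_prob_a = pq[1],
                                              switch_prob_b = pq[2]),
                          seed = 17)
    log <- run_session(cfg)
    pi_a <- pq[2] / sum(pq)
    # autocorrelated chain: inflate the binomial SE by (1+rho)/(1-rho)
    rho <- 1 - sum(pq)
    se <- sqrt(pi_a * (1 - pi_a) / 2000 * (1 + rho) / (1 - rho))
    expect_lt(abs(mean(log$choice[18001:20000] == "A") - pi_a), 3 * se)
  }
})

test_that("momentary maximizing picks the larger instantaneous probability", {
  d <- momentary_max_decide(5, 5, 20, 60, 0.3)
  expect_identical(as.character(d), "stay")
  expect_equal(attr(d, "p_stay"), 1 - exp(-0.25))
  expect_equal(attr(d, "p_switch"), 1 - exp(-5.3 / 60))

  expect_identical(as.character(momentary_max_decide(1, 1e6, 20, 60)),
                   "switch")

  # constructed exact tie: equal schedules, background = active - cost
  set.seed(4)
  picks <- replicate(2000,
    as.character(momentary_max_decide(5, 4.7, 60, 60, 0.3)))
  expect_lt(abs(mean(picks == "stay") - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("momentary maximizing at a constant rate locks into a fixed
           choice pattern", {
  # one response every 6 s on concurrent VI 20 / VI 60 with a 0.3-s
  # changeover: the rule deterministically repeats A,A,B (hand-traced)
  clk <- c(A = 0, B = 0); cur <- "A"; seqn <- character(21)
  for (i in 1:21) {
    oth <- setdiff(c("A", "B"), cur)
    mi <- c(A = 20, B = 60)
    t_cur <- clk[[cur]] + 6; t_oth <- clk[[oth]] + 6
    d <- momentary_max_decide(t_cur, t_oth, mi[[cur]], mi[[oth]], 0.3)
    choice <- if (d == "stay") cur else oth
    if (choice != cur) { t_cur <- t_cur + 0.3; t_oth <- t_oth + 0.3 }
    clk[[cur]] <- t_cur; clk[[oth]] <- t_oth
    clk[[choice]] <- 0
    cur <- choice; seqn[i] <- choice
  }
  expect_identical(seqn, rep(c("A", "A", "B"), 7))
  expect_equal(mean(seqn == "A"), 2 / 3)
})

test_that("ATM steady-state preference matches its stationary oracle when
           rewards are disabled", {
  fo <- atm_preset("atm_fo_vi20_60")
  cfg <- session_config(20, 60, model = "atm", reward_duration = 0,
                        seed = 23)
  log <- run_session(cfg)
  # independent oracle: integrate each binned function against the
  # shifted-exponential IRT density using exponential tail masses
  edges <- c(0, fo$bins, Inf)
  mass <- stats::pexp(pmax(edges[-1] - 0.2, 0), 1) -
    stats::pexp(pmax(edges[-length(edges)] - 0.2, 0), 1)
  e_rich <- sum(fo$rich * mass)
  e_lean <- sum(fo$lean * mass)
  pi_rich <- e_lean / (e_rich + e_lean)
  rho <- 1 - e_rich - e_lean
  se <- sqrt(pi_rich * (1 - pi_rich) / 2000 * (1 + rho) / (1 - rho))
  expect_lt(abs(proportion_rich(log) - pi_rich), 3 * se)
})

test_that("ATM and SET* switching is independent of background time given
           the IRT", {
  for (m in c("atm", "setstar")) {
    log <- std_session(m)
    sel <- 1001:20000
    irt_bin <- cut(log$generated_irt[sel], c(0, 0.5, 1, 1.5, 2, 3, Inf))
    state <- ifelse(log$is_switch[sel],
                    ifelse(log$choice[sel] == "A", "B", "A"),
                    log$choice[sel])   # resident state before the decision
    bg <- ifelse(log$is_switch[sel],   # pre-decision other-alternative clock
                 log$active_time[sel] - 0.3, log$background_time[sel])
    fit <- stats::glm(log$is_switch[sel] ~ bg + irt_bin + factor(state),
                      family = stats::binomial())
    z <- summary(fit)$coefficients[2, "z value"]
    expect_lt(abs(z), 3)
  }
})
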