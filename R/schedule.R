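#' Per-response reinforcement probability of a constant-probability VI
#'
#' On a variable-interval schedule programmed as a memoryless (Poisson)
#' set-up process, the probability that a response is reinforced after `t`
#' seconds of neglect is `1 - exp(-t / mean_interval)`: it starts at 0,
#' increases monotonically and saturates at 1. `mean_interval` is the VI
#' value in seconds (VI 60 means a mean programmed interval of 60 s).
#'
#' @param t Time since this alternative was last chosen, seconds.
#' @param mean_interval Mean programmed interreinforcement interval, s.
#' @return Probability of reinforcement (vectorised over `t`).
#' @examples
#' reinforcement_probability(60, 60)  # 1 - exp(-1)
#' @export
reinforcement_probability <- function(t, mean_interval) {
  if (any(!is.finite(mean_interval)) || any(mean_interval <= 0))
    stop("`mean_interval` must be positive", call. = FALSE)
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  1 - exp(-t / mean_interval)
}

#' Session configuration
#'
#' Full specification of one simulated concurrent VI VI session. Defaults
#' are the standard conditions: 0.3-s changeover time, 2-s reward periods,
#' 20,000 responses with analyses computed over the final 2,000.
#'
#' Model parameter blocks (`model_params`):
#' * `atm`: `bins` (interior bin edges), `rich`, `lean` (switch
#'   probabilities). Defaults to the preset matching the procedure
#'   ([atm_preset()] `"atm_fo_vi20_60"` or `"atm_dt"`). The `rich`
#'   function is assigned to the alternative with the smaller mean
#'   interval.
#' * `melioration`: `window` (buffer length; 15, 30 or 60 are the standard
#'   sizes; default 60).
#' * `setstar`: `switch_prob_a`, `switch_prob_b`; by default derived from
#'   the programmed rates via [setstar_switch_probability()].
#' * `momentary_max`: no parameters.
#'
#' @param vi_a,vi_b Mean programmed intervals of alternatives A and B, s.
#' @param irt An [irt_spec()].
#' @param model One of `"atm"`, `"melioration"`, `"setstar"`,
#'   `"momentary_max"`.
#' @param model_params Model-specific list, see Details.
#' @param switch_cost Changeover time, seconds.
#' @param reward_duration Reward period, seconds.
#' @param total_responses Responses per session.
#' @param tail_responses Responses at the end of the session over which
#'   summary statistics are computed.
#' @param seed Integer seed; every source of randomness in the session.
#' @return An object of class `session_config`.
#' @export
session_config <- function(vi_a, vi_b,
                           irt = irt_spec(),
                           model = c("atm", "melioration", "setstar",
                                     "momentary_max"),
                           model_params = list(),
                           switch_cost = 0.3,
                           reward_duration = 2,
                           total_responses = 20000L,
                           tail_responses = 2000L,
                           seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(irt, "irt_spec"))
  if (!is.numeric(vi_a) || vi_a <= 0 || !is.numeric(vi_b) || vi_b <= 0)
    stop("VI values must be positive mean intervals in seconds",
         call. = FALSE)
  if (switch_cost < 0 || reward_duration < 0)
    stop("`switch_cost` and `reward_duration` must be nonnegative",
         call. = FALSE)
  total_responses <- as.integer(total_responses)
  tail_responses <- as.integer(tail_responses)
  if (is.na(total_responses) || is.na(tail_responses) ||
      total_responses < tail_responses || tail_responses < 1L)
    stop("need total_responses >= tail_responses >= 1", call. = FALSE)

  model_params <- complete_model_params(model, model_params, vi_a, vi_b, irt)

  structure(
    list(vi_a = as.numeric(vi_a), vi_b = as.numeric(vi_b), irt = irt,
         model = model, model_params = model_params,
         switch_cost = as.numeric(switch_cost),
         reward_duration = as.numeric(reward_duration),
         total_responses = total_responses,
         tail_responses = tail_responses, seed = as.integer(seed)),
    class = "session_config")
}

# fill defaults and validate the model-specific block
complete_model_params <- function(model, mp, vi_a, vi_b, irt) {
  if (!is.list(mp)) stop("`model_params` must be a list", call. = FALSE)
  known <- switch(model,
    atm = c("bins", "rich", "lean"),
    melioration = "window",
    setstar = c("switch_prob_a", "switch_prob_b"),
    momentary_max = character(0))
  extra <- setdiff(names(mp), known)
  if (length(extra))
    stop("unknown ", model, " parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (model == "atm") {
    if (is.null(mp$bins) || is.null(mp$rich) || is.null(mp$lean)) {
      preset <- atm_preset(
        if (irt$procedure == "free_operant") "atm_fo_vi20_60" else "atm_dt")
      mp <- utils::modifyList(preset, mp)
    }
    # validates edges/probabilities
    active_time_function(mp$bins, mp$rich)
    active_time_function(mp$bins, mp$lean)
  } else if (model == "melioration") {
    if (is.null(mp$window)) mp$window <- 60L
    mp$window <- as.integer(mp$window)
    if (is.na(mp$window) || mp$window < 1L)
      stop("melioration `window` must be a positive integer", call. = FALSE)
  } else if (model == "setstar") {
    if (is.null(mp$switch_prob_a))
      mp$switch_prob_a <- setstar_switch_probability(1 / vi_a, 1 / vi_b)
    if (is.null(mp$switch_prob_b))
      mp$switch_prob_b <- setstar_switch_probability(1 / vi_b, 1 / vi_a)
    if (any(c(mp$switch_prob_a, mp$switch_prob_b) < 0) ||
        any(c(mp$switch_prob_a, mp$switch_prob_b) > 1))
      stop("SET* switch probabilities must lie in [0, 1]", call. = FALSE)
  }
  mp
}

#' Run one concurrent VI VI session
#'
#' Discrete-event simulation driven by the configured decision model. Per
#' response the random stream is consumed in a fixed order — IRT draw,
#' then decision draw (when the rule needs one), then reinforcement draw —
#' so runs are bit-reproducible given `config$seed`.
#'
#' Engine semantics: both schedule clocks advance during each IRT and
#' during the extra `switch_cost` on changeovers. A response is reinforced
#' with probability `1 - exp(-t/vi)` where `t` is the chosen alternative's
#' clock at the moment of the response; the chosen clock then resets to 0.
#' A reinforcer freezes the reinforced alternative's clock for
#' `reward_duration` seconds while the other clock (and session time)
#' keeps running, so reward time inflates only the other clock.
#'
#' @param config A [session_config()].
#' @return An event log: a data.frame of class `event_log` with one row
#'   per response and columns `index`, `session_time`, `choice`
#'   (`"A"`/`"B"`), `generated_irt`, `is_switch`, `active_time`
#'   (chosen alternative's clock at the response), `background_time`
#'   (other alternative's clock), `reinforced`, and model diagnostics
#'   `diag_stay`, `diag_switch` (the two candidate quantities the rule
#'   compared: switch probabilities, local rates, or instantaneous
#'   reinforcement probabilities). The configuration is attached as
#'   `attr(, "config")`.
#' @examples
#' cfg <- session_config(20, 60, model = "setstar",
#'                       total_responses = 500, tail_responses = 100,
#'                       seed = 42)
#' log <- run_session(cfg)
#' proportion_rich(log)
#' @export
run_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  n <- config$total_responses
  mi <- c(config$vi_a, config$vi_b)
  sc <- config$switch_cost
  rd <- config$reward_duration
  spec <- config$irt
  model <- config$model
  mp <- config$model_params
  fo <- spec$procedure == "free_operant"
  fo_rate <- spec$rate; fo_off <- spec$offset
  dt_sd <- sqrt(spec$dt_variance)
  dt_mean <- spec$dt_mean; dt_min <- spec$dt_min; dt_max <- spec$dt_max

  if (model == "atm") {
    rich_alt <- if (mi[1] <= mi[2]) 1L else 2L
    fns <- vector("list", 2L)
    fns[[rich_alt]] <- active_time_function(mp$bins, mp$rich)
    fns[[3L - rich_alt]] <- active_time_function(mp$bins, mp$lean)
    edges1 <- fns[[1L]]$bin_edges; probs1 <- fns[[1L]]$switch_probs
    edges2 <- fns[[2L]]$bin_edges; probs2 <- fns[[2L]]$switch_probs
  } else if (model == "setstar") {
    psw <- c(mp$switch_prob_a, mp$switch_prob_b)
  } else if (model == "melioration") {
    w <- mp$window
    buf_choice <- integer(w); buf_irt <- numeric(w); buf_rf <- numeric(w)
    buf_n <- 0L; buf_pos <- 0L
    sum_irt <- c(0, 0); sum_rf <- c(0, 0)
  }

  v_time <- numeric(n); v_choice <- integer(n); v_irt <- numeric(n)
  v_switch <- logical(n); v_at <- numeric(n); v_bt <- numeric(n)
  v_rf <- logical(n); v_d1 <- numeric(n); v_d2 <- numeric(n)

  cur <- if (stats::runif(1L) < 0.5) 1L else 2L  # fair-coin start
  clk <- c(0, 0)       # reward-pause-adjusted time since each alt chosen
  stime <- 0
  pend <- 0            # reward pause owed from the previous response

  for (i in seq_len(n)) {
    # (1) IRT draw
    if (fo) {
      irt <- fo_off - log(stats::runif(1L)) / fo_rate
    } else {
      repeat {
        irt <- stats::rnorm(1L, dt_mean, dt_sd)
        if (irt >= dt_min && irt <= dt_max) break
      }
    }
    oth <- 3L - cur
    t_cur <- clk[cur] + irt   # clocks at the moment of the response
    t_oth <- clk[oth] + irt

    # (2) decision
    if (model == "atm") {
      if (cur == 1L) p <- probs1[findInterval(irt, edges1) + 1L]
      else           p <- probs2[findInterval(irt, edges2) + 1L]
      choice <- if (stats::runif(1L) < p) oth else cur
      d1 <- 1 - p; d2 <- p
    } else if (model == "setstar") {
      p <- psw[cur]
      choice <- if (stats::runif(1L) < p) oth else cur
      d1 <- 1 - p; d2 <- p
    } else if (model == "melioration") {
      r1 <- if (sum_irt[1L] > 0) sum_rf[1L] / sum_irt[1L] else 0
      r2 <- if (sum_irt[2L] > 0) sum_rf[2L] / sum_irt[2L] else 0
      choice <- if (r1 > r2) 1L else if (r2 > r1) 2L
        else if (stats::runif(1L) < 0.5) 1L else 2L
      d1 <- if (cur == 1L) r1 else r2
      d2 <- if (cur == 1L) r2 else r1
    } else { # momentary_max
      p_stay <- 1 - exp(-t_cur / mi[cur])
      p_sw <- 1 - exp(-(t_oth + sc) / mi[oth])
      choice <- if (p_stay > p_sw) cur else if (p_sw > p_stay) oth
        else if (stats::runif(1L) < 0.5) cur else oth
      d1 <- p_stay; d2 <- p_sw
    }

    sw <- choice != cur
    if (sw) { t_cur <- t_cur + sc; t_oth <- t_oth + sc }
    t_chosen <- if (sw) t_oth else t_cur
    t_other <- if (sw) t_cur else t_oth

    # (3) reinforcement draw
    rf <- stats::runif(1L) < 1 - exp(-t_chosen / mi[choice])

    stime <- stime + pend + irt + if (sw) sc else 0
    v_time[i] <- stime; v_choice[i] <- choice; v_irt[i] <- irt
    v_switch[i] <- sw; v_at[i] <- t_chosen; v_bt[i] <- t_other
    v_rf[i] <- rf; v_d1[i] <- d1; v_d2[i] <- d2

    clk[choice] <- 0
    clk[3L - choice] <- t_other
    pend <- 0
    if (rf) {
      clk[3L - choice] <- clk[3L - choice] + rd  # other clock runs on
      pend <- rd
    }
    cur <- choice

    if (model == "melioration") {
      buf_pos <- if (buf_pos == w) 1L else buf_pos + 1L
      if (buf_n == w) {
        old <- buf_choice[buf_pos]
        sum_irt[old] <- sum_irt[old] - buf_irt[buf_pos]
        sum_rf[old] <- sum_rf[old] - buf_rf[buf_pos]
      } else buf_n <- buf_n + 1L
      buf_choice[buf_pos] <- choice
      buf_irt[buf_pos] <- irt
      buf_rf[buf_pos] <- as.numeric(rf)
      sum_irt[choice] <- sum_irt[choice] + irt
      sum_rf[choice] <- sum_rf[choice] + rf
    }
  }

  log <- data.frame(
    index = seq_len(n),
    session_time = v_time,
    choice = c("A", "B")[v_choice],
    generated_irt = v_irt,
    is_switch = v_switch,
    active_time = v_at,
    background_time = v_bt,
    reinforced = v_rf,
    diag_stay = v_d1,
    diag_switch = v_d2,
    stringsAsFactors = FALSE)
  attr(log, "config") <- config
  class(log) <- c("event_log", "data.frame")
  log
}

# config attached to a log, or informative error
log_config <- function(log) {
  cfg <- attr(log, "config")
  if (is.null(cfg))
    stop("event log carries no configuration; pass schedule parameters ",
         "explicitly", call. = FALSE)
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("Concurrent VI", x$vi_a, "- VI", x$vi_b, "session\n")
  cat("  model:", x$model, " procedure:", x$irt$procedure, "\n")
  cat("  responses:", x$total_responses,
      " (tail:", x$tail_responses, ") seed:", x$seed, "\n")
  invisible(x)
}
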