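#' Proportion of responses to the richer schedule
#'
#' Fraction of the final `tail` responses made to the richer alternative
#' (the one with the smaller mean programmed interval). The matching law
#' predicts this equals the scheduled reinforcement share (0.75 for a 3:1
#' pair); values nearer 0.5 are undermatching.
#'
#' @param log An `event_log` from [run_session()] or [read_event_log()].
#' @param tail Number of final responses to use; defaults to the session's
#'   configured `tail_responses` (or the whole log if no config).
#' @param rich `"A"` or `"B"`; inferred from the configured VI values when
#'   omitted.
#' @return Proportion in `[0, 1]`.
#' @export
proportion_rich <- function(log, tail = NULL, rich = NULL) {
  sel <- tail_rows(log, tail)
  if (!length(sel)) stop("empty tail selection", call. = FALSE)
  if (is.null(rich)) {
    cfg <- log_config(log)
    if (cfg$vi_a == cfg$vi_b)
      stop("equal schedules: specify `rich` explicitly", call. = FALSE)
    rich <- if (cfg$vi_a < cfg$vi_b) "A" else "B"
  }
  mean(log$choice[sel] == rich)
}

# indices of the final `tail` responses
tail_rows <- function(log, tail = NULL) {
  n <- nrow(log)
  if (is.null(tail)) {
    cfg <- attr(log, "config")
    tail <- if (is.null(cfg)) n else cfg$tail_responses
  }
  if (tail > n) stop("`tail` exceeds log length", call. = FALSE)
  seq.int(n - tail + 1L, n)
}

# Reconstruct, for every response, the pre-decision quantities the rule
# saw: which alternative was occupied before the decision and both
# schedule clocks at the moment of the response, before any switch cost.
pre_decision <- function(log, switch_cost) {
  sw <- log$is_switch
  chosen_a <- log$choice == "A"
  stay_alt <- ifelse(sw, ifelse(chosen_a, "B", "A"), log$choice)
  t_stay <- ifelse(sw, log$background_time - switch_cost, log$active_time)
  t_switch <- ifelse(sw, log$active_time - switch_cost, log$background_time)
  list(stay_alt = stay_alt, t_stay = t_stay, t_switch = t_switch)
}

#' M statistic: probability tracking of a choice sequence
#'
#' For every response the instantaneous reinforcement probabilities of the
#' stay and switch options are recomputed from the pre-decision schedule
#' clocks (the same reward-pause-adjusted quantities decisions see). The
#' absolute probability difference accrues to `sum_correct` when the
#' chosen option had the larger probability and to `sum_incorrect`
#' otherwise; exact ties contribute nothing. The statistic
#' `m = sum_correct / (sum_correct + sum_incorrect)` is 1 for perfect
#' momentary maximizing, 0.5 for probability-blind choice, and below 0.5
#' for systematically probability-averse choice.
#'
#' With `include_cost = TRUE` (default) the switch option's probability is
#' evaluated at `background clock + switch_cost`, mirroring the
#' momentary-maximizing decision rule, under which that rule scores
#' exactly 1; the flag is exposed because the convention is a choice.
#'
#' @param log An `event_log`.
#' @param vi_a,vi_b Mean intervals, seconds; default from the log's config.
#' @param switch_cost Changeover time, seconds; default from the config.
#' @param include_cost Add `switch_cost` to the switch option's clock.
#' @param tail Final responses to score; default the configured tail.
#' @return An object of class `m_stat`: list with `m`, `sum_correct`,
#'   `sum_incorrect`, `n`, and `undefined` (TRUE when every comparison
#'   tied, leaving `m` as `NA`).
#' @export
m_statistic <- function(log, vi_a = NULL, vi_b = NULL, switch_cost = NULL,
                        include_cost = TRUE, tail = NULL) {
  if (is.null(vi_a) || is.null(vi_b) || is.null(switch_cost)) {
    cfg <- log_config(log)
    if (is.null(vi_a)) vi_a <- cfg$vi_a
    if (is.null(vi_b)) vi_b <- cfg$vi_b
    if (is.null(switch_cost)) switch_cost <- cfg$switch_cost
  }
  sel <- tail_rows(log, tail)
  if (!length(sel)) stop("empty log", call. = FALSE)
  mi <- c(A = vi_a, B = vi_b)
  pd <- pre_decision(log[sel, , drop = FALSE], switch_cost)
  oth_alt <- ifelse(pd$stay_alt == "A", "B", "A")
  p_stay <- reinforcement_probability(pd$t_stay, mi[pd$stay_alt])
  cost <- if (include_cost) switch_cost else 0
  p_switch <- reinforcement_probability(pd$t_switch + cost, mi[oth_alt])
  sw <- log$is_switch[sel]
  p_chosen <- ifelse(sw, p_switch, p_stay)
  p_unchosen <- ifelse(sw, p_stay, p_switch)
  d <- p_chosen - p_unchosen
  sum_correct <- sum(d[d > 0])
  sum_incorrect <- -sum(d[d < 0])
  denom <- sum_correct + sum_incorrect
  structure(
    list(m = if (denom > 0) sum_correct / denom else NA_real_,
         sum_correct = sum_correct, sum_incorrect = sum_incorrect,
         n = length(sel), undefined = denom == 0),
    class = "m_stat")
}

#' @export
print.m_stat <- function(x, ...) {
  if (x$undefined) cat("M statistic: undefined (all comparisons tied)\n")
  else cat(sprintf("M statistic: %.3f  (correct mass %.2f, incorrect %.2f, n = %d)\n",
                   x$m, x$sum_correct, x$sum_incorrect, x$n))
  invisible(x)
}

#' Clock space of an event log
#'
#' Each response plotted by its temporal distance from the most recent
#' response to each alternative: `active_t` (chosen alternative's clock)
#' against `background_t` (other alternative's clock), partitioned by
#' choice. The indifference line — equal instantaneous reinforcement
#' probabilities — through the space of (time since last A response,
#' time since last B response) has slope `vi_b / vi_a`.
#'
#' @param log An `event_log`.
#' @param tail Final responses to include; default the configured tail.
#' @param vi_a,vi_b Mean intervals; default from the log's config.
#' @return Data.frame of class `clock_space` with columns `choice`,
#'   `active_t`, `background_t` and attribute `slope`.
#' @export
clock_space <- function(log, tail = NULL, vi_a = NULL, vi_b = NULL) {
  if (is.null(vi_a) || is.null(vi_b)) {
    cfg <- log_config(log)
    if (is.null(vi_a)) vi_a <- cfg$vi_a
    if (is.null(vi_b)) vi_b <- cfg$vi_b
  }
  sel <- tail_rows(log, tail)
  out <- data.frame(choice = log$choice[sel],
                    active_t = log$active_time[sel],
                    background_t = log$background_time[sel],
                    stringsAsFactors = FALSE)
  attr(out, "slope") <- vi_b / vi_a
  class(out) <- c("clock_space", "data.frame")
  out
}

#' Plot a clock space
#'
#' Minimal scatter of responses in clock coordinates (time since last A
#' response on x, time since last B response on y) with the indifference
#' line of slope `vi_b / vi_a`.
#'
#' @param x A [clock_space()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.clock_space <- function(x, ...) {
  ta <- ifelse(x$choice == "A", x$active_t, x$background_t)
  tb <- ifelse(x$choice == "A", x$background_t, x$active_t)
  graphics::plot(ta, tb, col = ifelse(x$choice == "A", "steelblue", "tomato"),
                 pch = 16, cex = 0.4,
                 xlab = "time since last A response (s)",
                 ylab = "time since last B response (s)", ...)
  graphics::abline(0, attr(x, "slope"), lty = 2)
  invisible(x)
}

#' Switch probability as a function of time at the current alternative
#'
#' Bins every response by how long the subject had been at its current
#' alternative when the interresponse interval began (the other
#' alternative's clock at the previous response — the current IRT itself
#' is excluded so that the conditioning variable does not share the IRT
#' with the decision) and returns the observed probability of switching
#' within each bin. The function is computed per resident schedule
#' (`state`), matching how perseveration plots are drawn; with
#' `state = NULL` all responses are pooled, but pooling mixes the two
#' schedules' very different switch levels and can mask or invert trends.
#' Flat per-schedule functions indicate run-length-independent switching;
#' an increasing function is the signature of momentary maximizing.
#'
#' @param log An `event_log`.
#' @param state `"A"` or `"B"`: restrict to responses made while that
#'   alternative was the resident one (pre-decision); `NULL` pools both.
#' @param bin_width Bin width, seconds.
#' @param switch_cost Changeover time; default from the log's config.
#' @param tail Final responses to use; default the configured tail.
#' @param min_n Bins with fewer observations are flagged `low_n`.
#' @return Data.frame with `bin_lo`, `bin_hi`, `mid`, `n`, `p_switch`,
#'   `low_n`.
#' @export
runlength_switch_function <- function(log, state = NULL, bin_width = 1,
                                      switch_cost = NULL, tail = NULL,
                                      min_n = 20L) {
  stopifnot(bin_width > 0)
  if (!nrow(log)) stop("empty log", call. = FALSE)
  if (is.null(switch_cost)) switch_cost <- log_config(log)$switch_cost
  sel <- tail_rows(log, tail)
  pd <- pre_decision(log[sel, , drop = FALSE], switch_cost)
  # other-alternative clock as of the previous response
  x <- pd$t_switch - log$generated_irt[sel]
  sw <- log$is_switch[sel]
  if (!is.null(state)) {
    keep <- pd$stay_alt == state
    x <- x[keep]; sw <- sw[keep]
    if (!length(x)) stop("no responses in state ", state, call. = FALSE)
  }
  bin <- floor(x / bin_width)
  agg <- tapply(sw, bin, function(z) c(n = length(z), p = mean(z)))
  bins <- as.numeric(names(agg))
  out <- data.frame(
    bin_lo = bins * bin_width,
    bin_hi = (bins + 1) * bin_width,
    mid = (bins + 0.5) * bin_width,
    n = vapply(agg, `[[`, numeric(1), "n"),
    p_switch = vapply(agg, `[[`, numeric(1), "p"))
  out$low_n <- out$n < min_n
  rownames(out) <- NULL
  out[order(out$bin_lo), ]
}

#' Summarise one session into a table row
#'
#' Runs [proportion_rich()] and [m_statistic()] on a log and returns the
#' one-row summary used by the table-reproduction machinery.
#'
#' @param log An `event_log` with an attached config.
#' @param model,procedure,pair,param Optional label overrides.
#' @param tail Final responses to score.
#' @return One-row data.frame: `model`, `procedure`, `pair`, `param`,
#'   `proportion_rich`, `m_value`.
#' @export
summarise_session <- function(log, model = NULL, procedure = NULL,
                              pair = NULL, param = "", tail = NULL) {
  cfg <- log_config(log)
  data.frame(
    model = model %||% cfg$model,
    procedure = procedure %||% cfg$irt$procedure,
    pair = pair %||% paste0("VI", cfg$vi_a, "-VI", cfg$vi_b),
    param = as.character(param),
    proportion_rich = proportion_rich(log, tail = tail),
    m_value = m_statistic(log, tail = tail)$m,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
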