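#' Active time function
#'
#' A binned mapping from active time (the interval since the most recent
#' response) to the probability of switching to the other alternative.
#' Bins are right-open; `bin_edges` are the interior edges, so
#' `length(switch_probs) == length(bin_edges) + 1` and the final bin is
#' unbounded. Lookup is total: every `t >= 0` falls in exactly one bin.
#'
#' @param bin_edges Strictly increasing interior bin edges, seconds.
#' @param switch_probs One switch probability per bin, in `[0, 1]`.
#' @return An object of class `active_time_function`.
#' @examples
#' f <- active_time_function(seq(0.5, 3.5, 0.5),
#'                           c(.43, .36, .19, .13, .08, .08, .18, .18))
#' atf_lookup(f, c(0.3, 1.2, 9))
#' @export
active_time_function <- function(bin_edges, switch_probs) {
  bin_edges <- as.numeric(bin_edges)
  switch_probs <- as.numeric(switch_probs)
  if (length(bin_edges) && (any(!is.finite(bin_edges)) ||
                            any(diff(bin_edges) <= 0) || any(bin_edges <= 0)))
    stop("`bin_edges` must be positive and strictly increasing", call. = FALSE)
  if (length(switch_probs) != length(bin_edges) + 1L)
    stop("need exactly one switch probability per bin ",
         "(length(bin_edges) + 1)", call. = FALSE)
  if (any(switch_probs < 0 | switch_probs > 1))
    stop("switch probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(bin_edges = bin_edges, switch_probs = switch_probs),
            class = "active_time_function")
}

#' Evaluate an active time function
#'
#' @param f An [active_time_function()].
#' @param t Active times, seconds (vectorised).
#' @return Switch probabilities.
#' @export
atf_lookup <- function(f, t) {
  stopifnot(inherits(f, "active_time_function"), all(t >= 0))
  f$switch_probs[findInterval(t, f$bin_edges) + 1L]
}

#' Shipped active-time function presets
#'
#' Group-average switch functions measured from pigeons, used to drive the
#' active time model:
#' * `atm_fo_vi20_60` — free-operant VI 20-s VI 60-s averages, 0.5-s bins
#'   up to 3.5 s with an unbounded final bin; `rich` and `lean` functions.
#' * `atm_dt` — discrete-trial averages over bins <4, 4-5, 5-6, 6-7, 7-8
#'   and >8 s. The published rich function lists five values for six bins;
#'   the final value (.14) is reused for the >8-s bin, preserving the
#'   monotone decrease (under the truncated-Gaussian pacing fewer than 1%
#'   of IRTs exceed 8 s, so the extension is inconsequential).
#' * `atm_fo_vi60_180_rich` — the free-operant function for the VI 60-s
#'   member of a VI 60-s VI 180-s pair (a single function, returned as an
#'   [active_time_function()]).
#'
#' @param name Preset name.
#' @return For the paired presets, a list with elements `bins`, `rich`,
#'   `lean`; for `atm_fo_vi60_180_rich`, an [active_time_function()].
#' @export
atm_preset <- function(name = c("atm_fo_vi20_60", "atm_dt",
                                "atm_fo_vi60_180_rich")) {
  name <- match.arg(name)
  switch(name,
    atm_fo_vi20_60 = list(
      bins = seq(0.5, 3.5, by = 0.5),
      rich = c(.43, .36, .19, .13, .08, .08, .18, .18),
      lean = c(.90, .90, .80, .75, .73, .72, .80, .88)),
    atm_dt = list(
      bins = c(4, 5, 6, 7, 8),
      rich = c(.50, .42, .31, .21, .14, .14),
      lean = c(.63, .73, .79, .85, .89, .85)),
    atm_fo_vi60_180_rich = active_time_function(
      seq(0.5, 3.5, by = 0.5),
      c(.32, .29, .25, .18, .14, .13, .13, .13)))
}

#' Active-time stay/switch decision
#'
#' Switches with the probability the state's active time function assigns
#' to the generated IRT; Bernoulli draw from the global random stream.
#'
#' @param f The resident state's [active_time_function()].
#' @param irt Generated IRT, seconds.
#' @return `"stay"` or `"switch"`.
#' @export
atm_decide <- function(f, irt) {
  p <- atf_lookup(f, irt)
  if (stats::runif(1L) < p) "switch" else "stay"
}

#' Melioration local rates and decision
#'
#' Melioration keeps the last `window` (choice, IRT, reinforced) triples
#' and chooses the alternative with the higher local reinforcement rate:
#' reinforcers earned at that alternative divided by the summed IRTs spent
#' there, 0 when the buffer holds no entries for it. Equal rates
#' (including 0 = 0 at session start) resolve by a fair coin.
#'
#' @param buffer A data.frame (or list) with elements `choice` (`"A"`/`"B"`),
#'   `irt` (seconds), `reinforced` (logical); at most `window` rows, oldest
#'   evicted first. May be empty.
#' @return `melioration_local_rates()`: named numeric `c(A = , B = )`.
#'   `melioration_decide()`: `"A"` or `"B"`.
#' @export
melioration_local_rates <- function(buffer) {
  rate_for <- function(alt) {
    sel <- buffer$choice == alt
    tt <- sum(buffer$irt[sel])
    if (tt > 0) sum(buffer$reinforced[sel]) / tt else 0
  }
  c(A = rate_for("A"), B = rate_for("B"))
}

#' @rdname melioration_local_rates
#' @export
melioration_decide <- function(buffer) {
  r <- melioration_local_rates(buffer)
  if (r[["A"]] > r[["B"]]) return("A")
  if (r[["B"]] > r[["A"]]) return("B")
  if (stats::runif(1L) < 0.5) "A" else "B"
}

#' SET* per-decision switch probability
#'
#' In the reduced scalar-expectancy variant the probability of leaving a
#' state is set by the ratio of the molar reinforcement rates: the richer
#' the other alternative relative to the occupied one, the likelier the
#' switch. For the rich member of a 3:1 pair this gives 0.25, for the lean
#' member 0.75.
#'
#' @param rate_self Programmed reinforcement rate of the occupied
#'   alternative, reinforcers per second.
#' @param rate_other Rate of the other alternative.
#' @return Probability of switching away per decision.
#' @export
setstar_switch_probability <- function(rate_self, rate_other) {
  if (any(!is.finite(c(rate_self, rate_other))) ||
      any(c(rate_self, rate_other) <= 0))
    stop("reinforcement rates must be positive", call. = FALSE)
  rate_other / (rate_self + rate_other)
}

#' SET* stay/switch decision
#'
#' Bernoulli draw on the resident state's fixed switch probability,
#' independent of the generated IRT.
#'
#' @param p_switch Probability of leaving the resident state.
#' @return `"stay"` or `"switch"`.
#' @export
setstar_decide <- function(p_switch) {
  stopifnot(p_switch >= 0, p_switch <= 1)
  if (stats::runif(1L) < p_switch) "switch" else "stay"
}

#' Momentary-maximizing stay/switch decision
#'
#' Compares the instantaneous reinforcement probabilities
#' `1 - exp(-t/vi)` of staying (active clock) and switching (background
#' clock plus the hypothetical switch cost) and takes the strictly larger;
#' exact ties resolve by a fair coin.
#'
#' @param active_t Time since the last response at the occupied
#'   alternative, seconds (including the just-elapsed IRT).
#' @param background_t Time since the last response at the other
#'   alternative, seconds.
#' @param vi_current,vi_other Mean programmed intervals, seconds.
#' @param switch_cost Changeover time added to the switch option, seconds.
#' @return `"stay"` or `"switch"`, with attributes `p_stay` and `p_switch`.
#' @export
momentary_max_decide <- function(active_t, background_t,
                                 vi_current, vi_other, switch_cost = 0.3) {
  stopifnot(active_t >= 0, background_t >= 0,
            vi_current > 0, vi_other > 0, switch_cost >= 0)
  p_stay <- 1 - exp(-active_t / vi_current)
  p_switch <- 1 - exp(-(background_t + switch_cost) / vi_other)
  d <- if (p_stay > p_switch) "stay"
       else if (p_switch > p_stay) "switch"
       else if (stats::runif(1L) < 0.5) "stay" else "switch"
  structure(d, p_stay = p_stay, p_switch = p_switch)
}

#' Expected switch probability of an active time function
#'
#' Integrates a binned switch function against the IRT distribution,
#' optionally restricted to an IRT window: the per-decision probability of
#' leaving a state whose switches are governed by `f` when IRTs come from
#' `spec`. Powers the closed-form stationary preferences used as analytic
#' companions to the simulations.
#'
#' @param f An [active_time_function()].
#' @param spec An [irt_spec()].
#' @param window Optional `c(min, max)` IRT restriction, seconds.
#' @return Expected switch probability.
#' @export
expected_switch_prob <- function(f, spec, window = NULL) {
  stopifnot(inherits(f, "active_time_function"), inherits(spec, "irt_spec"))
  lo <- c(0, f$bin_edges)
  hi <- c(f$bin_edges, Inf)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    lo <- pmax(lo, window[1]); hi <- pmin(hi, window[2])
    total <- pirt(window[2], spec) - pirt(window[1], spec)
    if (total <= 0) stop("IRT window excludes all support", call. = FALSE)
  } else total <- 1
  mass <- pmax(pirt(hi, spec) - pirt(lo, spec), 0)
  mass[hi <= lo] <- 0
  sum(f$switch_probs * mass) / total
}

#' Closed-form stationary choice proportion of a two-state switch process
#'
#' For a two-state chain where the per-decision probability of leaving
#' state A is `p_leave_a` and of leaving B is `p_leave_b`, the stationary
#' fraction of decisions made in state A is
#' `p_leave_b / (p_leave_a + p_leave_b)`.
#'
#' @param p_leave_a,p_leave_b Per-decision leave probabilities.
#' @return Stationary proportion of responses at A.
#' @export
stationary_proportion <- function(p_leave_a, p_leave_b) {
  stopifnot(p_leave_a >= 0, p_leave_b >= 0, p_leave_a + p_leave_b > 0)
  p_leave_b / (p_leave_a + p_leave_b)
}
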