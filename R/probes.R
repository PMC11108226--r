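#' A stimulus trained in a multiple concurrent VI VI schedule
#'
#' Carries everything a probe pairing needs to know about a stimulus from
#' its training context: the programmed VI value, its trained role (rich
#' or lean member of its pair), the active time function it acquired, the
#' overall reinforcement rate of its training pair (SET*'s sampling rate),
#' the local reinforcement rate measured during training (melioration),
#' and the SET* per-decision switch probability.
#'
#' Labels follow the field's convention: `VI60_180` is the VI 60-s
#' stimulus trained alongside a VI 180-s schedule (the rich member),
#' `VI60_20` the VI 60-s stimulus trained alongside a VI 20-s (lean).
#'
#' @param label Identifier, e.g. `"VI60_180"`.
#' @param vi_value Programmed mean interval, seconds.
#' @param role `"rich"` or `"lean"` within the training pair.
#' @param atm_function An [active_time_function()], or `NULL`.
#' @param context_overall_rate Summed programmed reinforcement rate of the
#'   training pair, reinforcers per second.
#' @param local_rate Trained local reinforcement rate, reinforcers per
#'   second of allocated time (`NA` until measured, see
#'   [train_local_rates()]).
#' @param setstar_switch_prob Per-decision probability of switching away.
#' @return An object of class `trained_stimulus`.
#' @export
trained_stimulus <- function(label, vi_value, role = c("rich", "lean"),
                             atm_function = NULL,
                             context_overall_rate = NULL,
                             local_rate = NA_real_,
                             setstar_switch_prob = NULL) {
  role <- match.arg(role)
  stopifnot(vi_value > 0)
  if (!is.null(atm_function))
    stopifnot(inherits(atm_function, "active_time_function"))
  if (!is.null(context_overall_rate)) stopifnot(context_overall_rate > 0)
  if (!is.null(setstar_switch_prob))
    stopifnot(setstar_switch_prob >= 0, setstar_switch_prob <= 1)
  structure(
    list(label = label, vi_value = vi_value, role = role,
         atm_function = atm_function,
         context_overall_rate = context_overall_rate,
         local_rate = local_rate,
         setstar_switch_prob = setstar_switch_prob),
    class = "trained_stimulus")
}

#' Preset stimuli from VI 20/60 and VI 60/180 training contexts
#'
#' The four stimuli of the standard multiple-concurrent arrangement: the
#' rich and lean members of a concurrent VI 20-s VI 60-s pair and of a
#' concurrent VI 60-s VI 180-s pair, with the free-operant group-average
#' active time functions attached by trained role (the VI 60_180 stimulus
#' gets its own measured function; the other rich stimulus the rich
#' VI 20/60 average; both lean stimuli the lean average). SET* switch
#' probabilities are 0.25 for rich members and 0.75 for lean members of
#' these 3:1 pairs; context overall rates are 1/20 + 1/60 and
#' 1/60 + 1/180 reinforcers per second.
#'
#' @return Named list of [trained_stimulus()] objects: `VI20_60`,
#'   `VI60_20`, `VI60_180`, `VI180_60`.
#' @export
preset_trained_stimuli <- function() {
  fo <- atm_preset("atm_fo_vi20_60")
  f_rich <- active_time_function(fo$bins, fo$rich)
  f_lean <- active_time_function(fo$bins, fo$lean)
  rate_2060 <- 1 / 20 + 1 / 60
  rate_60180 <- 1 / 60 + 1 / 180
  list(
    VI20_60 = trained_stimulus("VI20_60", 20, "rich", f_rich,
                               rate_2060, setstar_switch_prob = 0.25),
    VI60_20 = trained_stimulus("VI60_20", 60, "lean", f_lean,
                               rate_2060, setstar_switch_prob = 0.75),
    VI60_180 = trained_stimulus("VI60_180", 60, "rich",
                                atm_preset("atm_fo_vi60_180_rich"),
                                rate_60180, setstar_switch_prob = 0.25),
    VI180_60 = trained_stimulus("VI180_60", 180, "lean", f_lean,
                                rate_60180, setstar_switch_prob = 0.75))
}

#' ATM preference in a probe pairing
#'
#' Simulates the two-state semi-Markov process in extinction: each
#' response's IRT is drawn from `irt` (restricted to `window` by
#' rejection when given) and the resident stimulus's own active time
#' function converts it into a switch probability. Returns the simulated
#' choice proportion for `stim_a` together with its closed-form stationary
#' companion `E[A_b(N)] / (E[A_a(N)] + E[A_b(N)])`, the expectations taken
#' over the (window-restricted) IRT distribution.
#'
#' @param stim_a,stim_b [trained_stimulus()] objects carrying ATM
#'   functions.
#' @param irt An [irt_spec()].
#' @param window Optional `c(min, max)` IRT restriction, seconds.
#' @param n Number of probe responses.
#' @param seed Integer seed.
#' @param max_rejections Bound on rejection retries per draw.
#' @return List with `proportion_a`, `analytic_a`, `n`.
#' @export
atm_probe_preference <- function(stim_a, stim_b, irt = irt_spec(),
                                 window = NULL, n = 20000L, seed = 1L,
                                 max_rejections = 10000L) {
  stopifnot(inherits(stim_a, "trained_stimulus"),
            inherits(stim_b, "trained_stimulus"))
  fa <- stim_a$atm_function; fb <- stim_b$atm_function
  if (is.null(fa) || is.null(fb))
    stop("both stimuli need active time functions", call. = FALSE)
  ea <- expected_switch_prob(fa, irt, window)  # errors on empty window
  eb <- expected_switch_prob(fb, irt, window)
  analytic <- stationary_proportion(ea, eb)

  set.seed(seed)
  fns <- list(fa, fb)
  state <- if (stats::runif(1L) < 0.5) 1L else 2L
  n_a <- 0L
  for (i in seq_len(n)) {
    x <- draw_irt1(irt)
    if (!is.null(window)) {
      tries <- 0L
      while (x < window[1] || x >= window[2]) {
        tries <- tries + 1L
        if (tries > max_rejections)
          stop("IRT window rejection failed after ", max_rejections,
               " retries", call. = FALSE)
        x <- draw_irt1(irt)
      }
    }
    if (state == 1L) n_a <- n_a + 1L
    p <- atf_lookup(fns[[state]], x)
    if (stats::runif(1L) < p) state <- 3L - state
  }
  list(proportion_a = n_a / n, analytic_a = analytic, n = n)
}

#' SET* preference in a probe pairing
#'
#' Closed-form time-allocation preference. SET* samples each stimulus's
#' fixed switch probability at a rate proportional to the overall
#' reinforcement rate of its training context, so the expected sojourn
#' time in a state is `1 / (switch_prob * context_rate)` and the
#' preference for `stim_a` is its sojourn share. Pairing the lean
#' `VI60_20` (p = .75, fast sampling) against the rich `VI60_180`
#' (p = .25, slow sampling) yields a 9:1 preference for the `VI60_180`;
#' pairing `VI20_60` against `VI60_180` (equal p = .25, 3:1 sampling
#' rates) yields 3:1 for the `VI60_180`. The share is invariant to
#' rescaling both context rates by a common factor.
#'
#' @param stim_a,stim_b [trained_stimulus()] objects with switch
#'   probabilities and context rates.
#' @param simulate Also run a stochastic cross-check (geometric sojourns).
#' @param n_sojourns Sojourn pairs to simulate.
#' @param seed Integer seed for the cross-check.
#' @return List with `preference_a` (time-allocation share),
#'   `ratio` (preference_a / preference_b), and when `simulate = TRUE`
#'   `simulated_a`.
#' @export
setstar_probe_preference <- function(stim_a, stim_b, simulate = FALSE,
                                     n_sojourns = 5000L, seed = 1L) {
  stopifnot(inherits(stim_a, "trained_stimulus"),
            inherits(stim_b, "trained_stimulus"))
  pa <- stim_a$setstar_switch_prob; pb <- stim_b$setstar_switch_prob
  ra <- stim_a$context_overall_rate; rb <- stim_b$context_overall_rate
  if (is.null(pa) || is.null(pb) || is.null(ra) || is.null(rb))
    stop("both stimuli need switch probabilities and context rates",
         call. = FALSE)
  if (pa <= 0 || pb <= 0)
    stop("zero switch probability gives an infinite sojourn", call. = FALSE)
  sa <- 1 / (pa * ra)
  sb <- 1 / (pb * rb)
  out <- list(preference_a = sa / (sa + sb), ratio = sa / sb)
  if (simulate) {
    set.seed(seed)
    # decisions until leaving ~ Geometric(p); each decision takes 1/rate
    ta <- sum(stats::rgeom(n_sojourns, pa) + 1) / ra
    tb <- sum(stats::rgeom(n_sojourns, pb) + 1) / rb
    out$simulated_a <- ta / (ta + tb)
  }
  out
}

#' Melioration prediction for a probe pairing
#'
#' Melioration carries the local reinforcement rates accumulated during
#' training into the probe and prefers the stimulus with the higher rate;
#' the prediction is categorical (a strong preference), reported with the
#' trained-rate ratio. Ties are flagged.
#'
#' @param stim_a,stim_b [trained_stimulus()] objects whose `local_rate`
#'   has been measured (see [train_local_rates()]).
#' @return List with `preferred` (label or `NA` on tie), `ratio`
#'   (rate_a / rate_b), `tie`.
#' @export
melioration_probe_preference <- function(stim_a, stim_b) {
  stopifnot(inherits(stim_a, "trained_stimulus"),
            inherits(stim_b, "trained_stimulus"))
  ra <- stim_a$local_rate; rb <- stim_b$local_rate
  if (is.na(ra) || is.na(rb))
    stop("trained local rates not measured; run train_local_rates() first",
         call. = FALSE)
  tie <- ra == rb
  list(preferred = if (tie) NA_character_
                   else if (ra > rb) stim_a$label else stim_b$label,
       ratio = ra / rb, tie = tie)
}

#' Measure trained local reinforcement rates
#'
#' Runs a melioration training session on a concurrent pair and returns
#' the local reinforcement rate of each alternative over the analysis
#' tail: reinforcers earned there divided by the summed IRTs spent there
#' (melioration's own bookkeeping).
#'
#' @param vi_a,vi_b Mean intervals of the training pair, seconds.
#' @param window Melioration buffer length.
#' @param irt An [irt_spec()].
#' @param seed Integer seed.
#' @param ... Passed to [session_config()].
#' @return Named numeric `c(A = , B = )`, reinforcers per second.
#' @export
train_local_rates <- function(vi_a, vi_b, window = 60L, irt = irt_spec(),
                              seed = 1L, ...) {
  cfg <- session_config(vi_a, vi_b, irt = irt, model = "melioration",
                        model_params = list(window = window),
                        seed = seed, ...)
  log <- run_session(cfg)
  sel <- tail_rows(log)
  rate_for <- function(alt) {
    s <- sel[log$choice[sel] == alt]
    sum(log$reinforced[s]) / sum(log$generated_irt[s])
  }
  c(A = rate_for("A"), B = rate_for("B"))
}

#' Momentary-maximizing preference in a probe pairing
#'
#' Simulates momentary maximizing between the two stimuli in extinction,
#' using each stimulus's original VI value to map its clock into an
#' instantaneous reinforcement probability; the switch option's clock
#' carries the hypothetical switch cost. Identical VI values predict
#' indifference; unequal values a preference for the shorter (richer) VI.
#'
#' @param stim_a,stim_b [trained_stimulus()] objects.
#' @param irt An [irt_spec()].
#' @param n Probe responses.
#' @param seed Integer seed.
#' @param switch_cost Changeover time, seconds.
#' @return List with `proportion_a`, `n`.
#' @export
momentary_max_probe_preference <- function(stim_a, stim_b,
                                           irt = irt_spec(), n = 20000L,
                                           seed = 1L, switch_cost = 0.3) {
  stopifnot(inherits(stim_a, "trained_stimulus"),
            inherits(stim_b, "trained_stimulus"))
  mi <- c(stim_a$vi_value, stim_b$vi_value)
  set.seed(seed)
  cur <- if (stats::runif(1L) < 0.5) 1L else 2L
  clk <- c(0, 0)
  n_a <- 0L
  for (i in seq_len(n)) {
    x <- draw_irt1(irt)
    oth <- 3L - cur
    t_cur <- clk[cur] + x
    t_oth <- clk[oth] + x
    p_stay <- 1 - exp(-t_cur / mi[cur])
    p_sw <- 1 - exp(-(t_oth + switch_cost) / mi[oth])
    choice <- if (p_stay > p_sw) cur else if (p_sw > p_stay) oth
      else if (stats::runif(1L) < 0.5) cur else oth
    if (choice != cur) { t_cur <- t_cur + switch_cost; t_oth <- t_oth + switch_cost }
    if (choice == 1L) n_a <- n_a + 1L
    clk[cur] <- t_cur; clk[oth] <- t_oth
    clk[choice] <- 0
    cur <- choice
  }
  list(proportion_a = n_a / n, n = n)
}
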