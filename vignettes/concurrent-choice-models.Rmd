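---
title: "Simulating steady-state choice on concurrent VI VI schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating steady-state choice on concurrent VI VI schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmsim)
```

## The problem

On a concurrent variable-interval (VI) VI schedule an animal works two
response alternatives at once. Each alternative pays off at unpredictable
times with a stated mean interval (a "VI 60-s" schedule arms a reinforcer
on average every 60 s, holds it until collected, and the first response
after arming is reinforced). Because an armed reinforcer waits, the
probability that a response is reinforced grows with the time the
alternative has been neglected:

$$P_i \;=\; 1 - e^{-t_i/\lambda_i},$$

where $t_i$ is the time since alternative $i$ was last chosen and
$\lambda_i$ is its mean programmed interval in seconds. This single
exposure curve is what makes concurrent VI VI schedules a sharp test bed
for choice theories: molar matching (choice ratios tracking
reinforcement ratios) can be produced by several entirely different
molecular mechanisms, and only finer-grained statistics separate them.

`atmsim` simulates one steady-state session of such a schedule under
four decision models and computes the statistics that discriminate among
them.

## The schedule engine

A session is a discrete-event loop over responses. Each response is
timed by an interresponse-time (IRT) generator, fed to the model's
stay/switch rule, and then scored against the schedule:

* **Free-operant pacing**: IRT $= 0.2 - \ln(u)/\lambda$ with $u$ uniform
  on (0, 1] and $\lambda$ the response rate (default 1/s), i.e. a shifted
  exponential with a 0.2-s floor.
* **Discrete-trial pacing**: a Gaussian with mean 6 s and variance
  1 s², truncated to [2, 10] s by rejection. Rejection rather than
  clipping is used because clipping would put point masses at the
  bounds that paced procedures do not show; with these parameters fewer
  than 0.01% of draws are rejected, so the choice is near-inconsequential.
* Switching costs 0.3 s in addition to the IRT; the raw IRT — not the
  cost, not reward time — is what the decision rule sees.
* Reinforcement is a Bernoulli draw with $p = 1 - e^{-t/\lambda}$ from
  the chosen alternative's clock. This per-response form is exactly
  equivalent to an armed-and-held (hold = 1) memoryless set-up process,
  because a non-reinforced response certifies that nothing was pending.
* A reinforcer occupies 2 s during which the reinforced alternative's
  clock is frozen while the other alternative's clock and session time
  keep running: reward time inflates only the *other* clock.
* Sessions run 20,000 responses; summary statistics use the final 2,000
  (both configurable). The tail convention is a choice — the source
  analyses do not state whether whole-session or saved-tail statistics
  were used — and every metric exposes a `tail` argument.

The random stream is consumed in a fixed order per response (IRT draw,
then decision draw where the rule needs one, then reinforcement draw),
so a session is bit-reproducible from its seed. Decision rules that
compare strict inequalities (melioration, momentary maximizing) consume
a uniform only on exact ties, which are resolved by a fair coin.

## The four decision models

**Active time model (ATM).** The controlling stimulus is the *active
time* — the just-generated IRT. Each schedule state carries a binned
*active time function* $A(t)$ mapping that interval to a switch
probability; the process is semi-Markov. The shipped free-operant
functions are group averages measured from pigeons on a concurrent
VI 20-s VI 60-s schedule (rich: .43, .36, .19, .13, .08, .08, .18, .18;
lean: .90, .90, .80, .75, .73, .72, .80, .88) over 0.5-s bins. Eight
values require eight bins, so the interior edges are 0.5 … 3.5 s with an
unbounded final bin. The discrete-trial averages use the named bins
<4, 4–5, 5–6, 6–7, 7–8, >8 s; the published rich function lists five
values for those six bins, and we reuse the final value (.14) for the
>8-s bin — the monotone-decrease-preserving extension, and one that is
inert in practice because the truncated-Gaussian pacing almost never
produces IRTs above 8 s. Functions are assigned by *trained role* (rich
vs lean member of the pair), not by absolute VI value; that distinction
is the entire point of the probe experiments below.

**Melioration.** Keeps the last *n* (choice, IRT, reinforced) triples
(n = 15, 30 or 60; partial buffers at session start are used as-is) and
chooses the alternative with the higher local reinforcement rate —
reinforcers divided by summed IRTs, per alternative, zero when an
alternative has no entries. Equal rates (including 0 = 0) fall back to a
fair coin. A caveat worth knowing: with the larger windows this rule is
nearly absorbing at the rich schedule (the unvisited alternative's local
rate is zero while the rich window rarely empties of reinforcers), so
its tail statistics are strongly seed-dependent — the across-seed spread
of the window-60 rich proportion is an order of magnitude wider than the
binomial error of any single run.

**SET\* (reduced scalar-expectancy variant).** Remembered
interreinforcement intervals are summarised into fixed per-state switch
probabilities given by the molar rate ratio:
$p_{\text{leave}} = r_{\text{other}}/(r_{\text{self}} + r_{\text{other}})$,
sampled once per response, independent of the IRT. The memory-sampling
derivation itself is not simulated — only its behavioural consequence,
which is how the theory's own proponents reduce it for this procedure.
The stationary choice proportion is $q/(p+q)$ in closed form, used
throughout as an oracle.

**Momentary maximizing.** Chooses the strictly larger of
$1 - e^{-t_{\text{active}}/\lambda_{\text{cur}}}$ and
$1 - e^{-(t_{\text{background}} + 0.3)/\lambda_{\text{other}}}$, the 0.3-s
being the hypothetical changeover cost (not added to the clocks when the
rule stays).

## Analyses

`proportion_rich()` is the matching statistic. `m_statistic()` is the
probability-tracking index

$$M = \frac{\sum |p_i - p_j|_{\text{corr}}}
           {\sum |p_i - p_j|_{\text{corr}} + \sum |p_i - p_j|_{\text{inc}}},$$

accumulated over responses: the stay and switch probabilities are
recomputed from the pre-decision schedule clocks (the same
reward-pause-adjusted quantities decisions see), the absolute difference
going to the "correct" mass when the chosen option had the larger
probability. By default the switch option's clock carries the 0.3-s
cost (`include_cost = TRUE`): under that convention the
momentary-maximizing model scores exactly 1 by construction, which pins
the otherwise-arbitrary convention; it is exposed as a flag because the
source analyses do not state theirs.

`clock_space()` plots each response by its temporal distance from the
most recent response to each alternative, with the indifference line of
slope $\lambda_2/\lambda_1$ (equal instantaneous probabilities).
`runlength_switch_function()` bins responses by the time already spent
at the resident alternative when the IRT began and reports per-bin
switch probabilities, per schedule. Two numerical choices matter here
and are deliberate: the conditioning variable excludes the current IRT
(otherwise short IRTs simultaneously produce short times-at-alternative
and, under ATM, high switch probabilities, manufacturing a spurious
decline), and the function is computed per resident schedule (pooling
mixes the lean schedule's high switch level at short runs with the rich
schedule's low level at long runs and can invert the trend).

```{r}
cfg <- session_config(20, 60, model = "setstar", seed = 42)
log <- run_session(cfg)
proportion_rich(log)
m_statistic(log)
head(runlength_switch_function(log, state = "A"), 3)
```

## Probe experiments

Training two pairs (say VI 20/VI 60 and VI 60/VI 180) in one session and
then pairing the stimuli in novel combinations separates the models
sharply, because each model carries a different trained quantity into
the probe:

* **ATM** carries the active time function; pairing the rich-trained
  VI 60 against the lean-trained VI 60 yields about 3:1 for the former,
  and restricting probe IRTs to long intervals (where the rich/lean
  function gap is widest) makes the preference more extreme than
  short-IRT probes — the package's default windows for that contrast are
  [0.2, 1) s and [3.5, ∞) s, and only the ordering is asserted.
* **SET\*** carries a switch probability *and* a sampling rate
  proportional to the training context's overall reinforcement rate;
  time allocation is proportional to $1/(p \cdot \text{rate})$. This is
  a time-allocation (sojourn-share) reading — the only one under which
  the 9:1 (lean-fast vs rich-slow) and 3:1 (equal p, 3:1 rates)
  predictions are simultaneously consistent, since a choice-count
  reading collapses both to 3:1.
* **Melioration** carries trained local rates, measured here by actually
  running the training sessions; its probe prediction is categorical.
* **Momentary maximizing** carries only the programmed VI values.

Probes run in extinction by default (the predictions derive from trained
quantities, and the experiments they model use unreinforced probes).

```{r}
stims <- preset_trained_stimuli()
setstar_probe_preference(stims$VI60_180, stims$VI60_20)[c("preference_a", "ratio")]
atm_probe_preference(stims$VI60_180, stims$VI60_20, seed = 1)[c("proportion_a", "analytic_a")]
```

## What the simulations do and do not show

The generator defaults *are* the study conditions: exponential 1/s
free-operant pacing, the 6 ± 1 s discrete-trial Gaussian, 0.3-s
changeovers, 2-s rewards, 20,000-response sessions. Within those
conditions the test suite checks the simulators against independent
closed forms (two-state stationary laws, numerically integrated switch
expectations, truncated-normal moments) at three-standard-error
tolerances, and checks the published table cells at the ±0.05 level that
the under-specified analysis conventions warrant. Passing these says the
models behave as specified under idealised pacing; it says nothing about
real birds, whose IRT distributions are neither exponential nor
stationary, who warm up and satiate, and whose active time functions
are individual rather than group averages.

Two cells deserve explicit caveats. First, the published free-operant
ATM proportions differ between the VI 20/VI 60 and VI 60/VI 180 pairs at
the same response rate; the model as stated decides from the generated
IRT alone, so its stationary preference is provably pair-independent
(rewards interrupt timing but never enter the decision), and the package
asserts that property instead of the second cell. Second, the
melioration window-60 proportion is a lottery over seeds (see above);
single-run values between 0.61 and 1.00 are all ordinary draws.

## Problem sizes

All analyses in the tests and scripts use the standard 20,000-response
sessions (about a quarter second each in pure R); the complete 28-cell
table grid runs in well under a minute, and the structural tests use
shorter sessions where only bookkeeping is exercised.
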