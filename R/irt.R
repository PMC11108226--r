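#' Interresponse-time generator specification
#'
#' Defines the process that times every decision in a simulated session.
#' Free-operant responding uses a shifted exponential: each interresponse
#' time (IRT) is `offset - log(u)/rate` with `u` uniform on (0, 1], so no
#' IRT is shorter than `offset`. Discrete-trial responding draws from a
#' Gaussian with mean `dt_mean` and variance `dt_variance`, truncated to
#' `[dt_min, dt_max]` by rejection (redraw until inside the bounds), which
#' avoids the point masses at the bounds that clipping would create.
#'
#' @param procedure `"free_operant"` or `"discrete_trial"`.
#' @param rate Free-operant response rate, responses per second.
#' @param offset Free-operant minimum IRT, seconds.
#' @param dt_mean Discrete-trial Gaussian mean, seconds.
#' @param dt_variance Discrete-trial Gaussian variance, seconds squared.
#' @param dt_min,dt_max Discrete-trial truncation bounds, seconds.
#' @return An object of class `irt_spec`.
#' @examples
#' spec <- irt_spec("free_operant", rate = 1)
#' summary(draw_irt(spec, 1000))
#' @export
irt_spec <- function(procedure = c("free_operant", "discrete_trial"),
                     rate = 1, offset = 0.2,
                     dt_mean = 6, dt_variance = 1,
                     dt_min = 2, dt_max = 10) {
  procedure <- match.arg(procedure)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) || offset < 0)
    stop("`offset` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(dt_variance) || length(dt_variance) != 1L || dt_variance <= 0)
    stop("`dt_variance` must be positive", call. = FALSE)
  if (!(dt_min < dt_mean && dt_mean < dt_max))
    stop("discrete-trial bounds must satisfy dt_min < dt_mean < dt_max",
         call. = FALSE)
  structure(
    list(procedure = procedure, rate = as.numeric(rate),
         offset = as.numeric(offset), dt_mean = as.numeric(dt_mean),
         dt_variance = as.numeric(dt_variance),
         dt_min = as.numeric(dt_min), dt_max = as.numeric(dt_max)),
    class = "irt_spec")
}

# shifted-exponential transform; u in (0, 1]
fo_irt_from_u <- function(u, spec) spec$offset - log(u) / spec$rate

#' Draw interresponse times
#'
#' Samples `n` IRTs from the generator described by `spec`, consuming the
#' global R random stream (seed it with [set.seed()] for reproducibility).
#'
#' @param spec An [irt_spec()].
#' @param n Number of draws.
#' @return Numeric vector of durations in seconds.
#' @export
draw_irt <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "irt_spec"), n >= 0)
  if (n == 0L) return(numeric(0))
  if (spec$procedure == "free_operant") {
    fo_irt_from_u(stats::runif(n), spec)
  } else {
    sd <- sqrt(spec$dt_variance)
    x <- stats::rnorm(n, spec$dt_mean, sd)
    bad <- which(x < spec$dt_min | x > spec$dt_max)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), spec$dt_mean, sd)
      bad <- bad[x[bad] < spec$dt_min | x[bad] > spec$dt_max]
    }
    x
  }
}

# one draw, used inside the session loop (avoids vector bookkeeping)
draw_irt1 <- function(spec) {
  if (spec$procedure == "free_operant")
    return(spec$offset - log(stats::runif(1L)) / spec$rate)
  sd <- sqrt(spec$dt_variance)
  repeat {
    x <- stats::rnorm(1L, spec$dt_mean, sd)
    if (x >= spec$dt_min && x <= spec$dt_max) return(x)
  }
}

#' Cumulative distribution of the IRT generator
#'
#' `P(IRT <= q)` under `spec`, by closed form. Used by the analytic
#' companions to simulated preferences.
#'
#' @param q Quantiles, seconds.
#' @param spec An [irt_spec()].
#' @return Probabilities.
#' @export
pirt <- function(q, spec) {
  stopifnot(inherits(spec, "irt_spec"))
  if (spec$procedure == "free_operant") {
    stats::pexp(pmax(q - spec$offset, 0), rate = spec$rate)
  } else {
    sd <- sqrt(spec$dt_variance)
    lo <- stats::pnorm(spec$dt_min, spec$dt_mean, sd)
    hi <- stats::pnorm(spec$dt_max, spec$dt_mean, sd)
    p <- (stats::pnorm(pmin(pmax(q, spec$dt_min), spec$dt_max),
                       spec$dt_mean, sd) - lo) / (hi - lo)
    ifelse(q < spec$dt_min, 0, ifelse(q > spec$dt_max, 1, p))
  }
}

#' Mean of the IRT generator
#'
#' Analytic for the free-operant shifted exponential
#' (`offset + 1/rate`); numerical integration for the truncated Gaussian.
#'
#' @param spec An [irt_spec()].
#' @return Mean IRT, seconds.
#' @export
irt_mean <- function(spec) {
  stopifnot(inherits(spec, "irt_spec"))
  if (spec$procedure == "free_operant") return(spec$offset + 1 / spec$rate)
  sd <- sqrt(spec$dt_variance)
  z <- stats::integrate(function(x) x * stats::dnorm(x, spec$dt_mean, sd),
                        spec$dt_min, spec$dt_max)$value
  mass <- stats::pnorm(spec$dt_max, spec$dt_mean, sd) -
    stats::pnorm(spec$dt_min, spec$dt_mean, sd)
  z / mass
}
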