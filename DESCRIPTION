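Package: atmsim
Title: Steady-State Simulation of Concurrent Variable-Interval Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-event simulation of two-alternative concurrent
    variable-interval (VI VI) schedules of reinforcement at steady state.
    Implements a schedule engine with per-alternative clocks, switch costs
    and reward pauses; four stay/switch decision models (the active time
    model, melioration, a reduced scalar-expectancy variant, and momentary
    maximizing); molecular and molar analyses of the resulting event logs
    (matching proportions, the M probability-tracking statistic, clock
    spaces, run-length switch functions); and probe experiments that pair
    stimuli trained in multiple concurrent VI VI schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
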