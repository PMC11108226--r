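# Shared fixtures: sessions are generated in code at test time and cached
# per test run so several test files can reuse the same logs.

fo_spec <- irt_spec("free_operant", rate = 1)
dt_spec <- irt_spec("discrete_trial")

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, config) {
  if (is.null(.session_cache[[key]]))
    .session_cache[[key]] <- run_session(config)
  .session_cache[[key]]
}

std_session <- function(model, procedure = "free_operant", vis = c(20, 60),
                        model_params = list(), seed = 101,
                        n = 20000L, tail = 2000L) {
  irt <- if (procedure == "free_operant") fo_spec else dt_spec
  key <- paste(model, procedure, paste(vis, collapse = "-"),
               paste(unlist(model_params), collapse = "-"), seed, n,
               sep = "|")
  cached_session(key, session_config(
    vis[1], vis[2], irt = irt, model = model, model_params = model_params,
    seed = seed, total_responses = n, tail_responses = tail))
}

# independent clock reconstruction from the raw log columns (used by
# round-trip and conservation checks)
reconstruct_clocks <- function(log, switch_cost = 0.3, reward_duration = 2) {
  n <- nrow(log)
  clk <- c(A = 0, B = 0)
  active <- numeric(n); background <- numeric(n)
  for (i in seq_len(n)) {
    elapsed <- log$generated_irt[i] + switch_cost * log$is_switch[i]
    clk <- clk + elapsed
    ch <- log$choice[i]; ot <- setdiff(c("A", "B"), ch)
    active[i] <- clk[[ch]]; background[i] <- clk[[ot]]
    clk[[ch]] <- 0
    if (log$reinforced[i]) clk[[ot]] <- clk[[ot]] + reward_duration
  }
  data.frame(active = active, background = background)
}
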