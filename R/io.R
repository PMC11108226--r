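#' Write an event log to CSV
#'
#' One row per response with the fixed header
#' `index,session_time,choice,generated_irt,is_switch,active_time,background_time,reinforced`;
#' times carry 6 decimal places, flags are 0/1. Model diagnostics are not
#' part of the interchange format and are dropped.
#'
#' @param log An `event_log`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  num <- function(x) sprintf("%.6f", x)
  lines <- paste(log$index, num(log$session_time), log$choice,
                 num(log$generated_irt), as.integer(log$is_switch),
                 num(log$active_time), num(log$background_time),
                 as.integer(log$reinforced), sep = ",")
  writeLines(c(paste("index", "session_time", "choice", "generated_irt",
                     "is_switch", "active_time", "background_time",
                     "reinforced", sep = ","), lines), path)
  invisible(path)
}

#' Read an event log from CSV
#'
#' Counterpart of [write_event_log()]. The returned log carries no
#' configuration, so metrics needing schedule parameters must receive
#' them explicitly.
#'
#' @param path CSV file written by [write_event_log()].
#' @return An `event_log` data.frame.
#' @export
read_event_log <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("index", "session_time", "choice", "generated_irt",
                "is_switch", "active_time", "background_time", "reinforced")
  if (!identical(names(x), expected))
    stop("not an event-log CSV: header mismatch", call. = FALSE)
  x$is_switch <- as.logical(x$is_switch)
  x$reinforced <- as.logical(x$reinforced)
  class(x) <- c("event_log", "data.frame")
  x
}

#' Serialise a session configuration to JSON
#'
#' Every configuration field is a key; [config_from_json()] rejects
#' unknown keys so that a manifest plus configuration reproduces a run
#' bit for bit.
#'
#' @param config A [session_config()].
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "session_config"))
  x <- unclass(config)
  x$irt <- unclass(x$irt)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname config_to_json
#' @param json JSON string or path to a JSON file.
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  top <- c("vi_a", "vi_b", "irt", "model", "model_params", "switch_cost",
           "reward_duration", "total_responses", "tail_responses", "seed")
  extra <- setdiff(names(x), top)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("vi_a", "vi_b", "model", "seed"), names(x))
  if (length(miss))
    stop("missing configuration key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  irt <- if (is.null(x$irt)) irt_spec() else {
    irt_keys <- c("procedure", "rate", "offset", "dt_mean", "dt_variance",
                  "dt_min", "dt_max")
    bad <- setdiff(names(x$irt), irt_keys)
    if (length(bad))
      stop("unknown irt key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    do.call(irt_spec, x$irt)
  }
  mp <- x$model_params %||% list()
  if (!is.null(mp$bins)) mp$bins <- as.numeric(mp$bins)
  args <- list(vi_a = x$vi_a, vi_b = x$vi_b, irt = irt, model = x$model,
               model_params = mp, seed = x$seed)
  for (k in c("switch_cost", "reward_duration", "total_responses",
              "tail_responses"))
    if (!is.null(x[[k]])) args[[k]] <- x[[k]]
  do.call(session_config, args)
}

#' Run manifest
#'
#' Written before a simulation starts: the configuration snapshot, seed,
#' package version and output paths suffice to reproduce the run exactly.
#'
#' @param config A [session_config()].
#' @param outputs Named character vector of output file paths.
#' @param path File to write the manifest JSON to.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, outputs, path) {
  man <- list(
    config = jsonlite::fromJSON(config_to_json(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("atmsim")),
    outputs = as.list(outputs),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(man)
}

#' Deterministic per-session seeds from one master seed
#'
#' Child seeds are the first `n` values of `sample.int(2^31 - 2)` under
#' the master seed, drawn on a private RNG state so the caller's stream
#' is untouched.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master)
  sample.int(2147483646L, n)
}

#' Reproduce the full model-comparison tables
#'
#' Runs the complete grid — free-operant and discrete-trial procedures,
#' concurrent VI 20-s VI 60-s and VI 60-s VI 180-s pairs, and seven model
#' rows (melioration with windows 15/30/60, momentary maximizing, SET*,
#' and the active time model at 1/s and 2/s response rates) — and returns
#' the 28 summary rows of matching proportions and M values. One master
#' seed spawns the per-session seeds via [derive_seeds()]. In the
#' discrete-trial procedure response pacing is fixed by the truncated
#' Gaussian, so the two ATM rows are replicate runs there.
#'
#' @param seed Master seed.
#' @param total_responses,tail_responses Session length and analysis
#'   tail.
#' @return Data.frame with columns `model`, `procedure`, `pair`, `param`,
#'   `proportion_rich`, `m_value`.
#' @export
reproduce_tables <- function(seed = 1L, total_responses = 20000L,
                             tail_responses = 2000L) {
  grid <- expand.grid(
    procedure = c("free_operant", "discrete_trial"),
    pair = c("VI20-VI60", "VI60-VI180"),
    cell = c("melioration_15", "melioration_30", "melioration_60",
             "momentary_max", "setstar", "atm_1s", "atm_2s"),
    stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    vis <- if (g$pair == "VI20-VI60") c(20, 60) else c(60, 180)
    irt <- if (g$procedure == "free_operant") {
      irt_spec("free_operant", rate = if (g$cell == "atm_2s") 2 else 1)
    } else irt_spec("discrete_trial")
    parts <- strsplit(g$cell, "_")[[1]]
    model <- if (parts[1] == "melioration") "melioration"
      else if (parts[1] == "atm") "atm"
      else g$cell
    mp <- if (model == "melioration")
      list(window = as.integer(parts[2])) else list()
    cfg <- session_config(vis[1], vis[2], irt = irt, model = model,
                          model_params = mp, seed = seeds[i],
                          total_responses = total_responses,
                          tail_responses = tail_responses)
    param <- if (model == "melioration") parts[2]
      else if (model == "atm") paste0(sub("s$", "", parts[2]), "/s")
      else ""
    rows[[i]] <- summarise_session(run_session(cfg), model = model,
                                   procedure = g$procedure, pair = g$pair,
                                   param = param)
  }
  do.call(rbind, rows)
}

#' Reproduce the probe-pairing predictions
#'
#' All four models' predicted preferences for the two standard novel
#' pairings of multiply-trained stimuli: `VI60_20` vs `VI60_180` and
#' `VI20_60` vs `VI60_180`. ATM and momentary maximizing are simulated
#' (ATM also reports its closed-form companion); SET* is closed form;
#' melioration first measures trained local rates by simulating both
#' training contexts and reports its categorical preference as 1 or 0
#' for the first-listed stimulus, with the rate ratio as the analytic
#' column.
#'
#' @param seed Master seed.
#' @param n Probe responses per simulated pairing.
#' @param total_responses Training-session length for melioration.
#' @return Data.frame with columns `model`, `stim_a`, `stim_b`,
#'   `preference_a`, `analytic_preference_a`.
#' @export
probe_table <- function(seed = 1L, n = 20000L, total_responses = 20000L) {
  stims <- preset_trained_stimuli()
  seeds <- derive_seeds(seed, 6L)
  pairings <- list(c("VI60_20", "VI60_180"), c("VI20_60", "VI60_180"))

  # melioration training contexts
  lr_2060 <- train_local_rates(20, 60, seed = seeds[5],
                               total_responses = total_responses,
                               tail_responses = min(2000L, total_responses))
  lr_60180 <- train_local_rates(60, 180, seed = seeds[6],
                                total_responses = total_responses,
                                tail_responses = min(2000L, total_responses))
  stims$VI20_60$local_rate <- lr_2060[["A"]]
  stims$VI60_20$local_rate <- lr_2060[["B"]]
  stims$VI60_180$local_rate <- lr_60180[["A"]]
  stims$VI180_60$local_rate <- lr_60180[["B"]]

  rows <- list()
  k <- 0L
  for (j in seq_along(pairings)) {
    a <- stims[[pairings[[j]][1]]]; b <- stims[[pairings[[j]][2]]]
    atm <- atm_probe_preference(a, b, n = n, seed = seeds[j])
    ss <- setstar_probe_preference(a, b)
    mel <- melioration_probe_preference(a, b)
    mm <- momentary_max_probe_preference(a, b, n = n, seed = seeds[j + 2])
    add <- function(model, pref, analytic) {
      k <<- k + 1L
      rows[[k]] <<- data.frame(
        model = model, stim_a = a$label, stim_b = b$label,
        preference_a = pref, analytic_preference_a = analytic,
        stringsAsFactors = FALSE)
    }
    add("atm", atm$proportion_a, atm$analytic_a)
    add("setstar", ss$preference_a, ss$preference_a)
    add("melioration",
        as.numeric(identical(mel$preferred, a$label)), mel$ratio)
    add("momentary_max", mm$proportion_a,
        (1 / a$vi_value) / (1 / a$vi_value + 1 / b$vi_value))
  }
  do.call(rbind, rows)
}

#' Command entry points
#'
#' Thin wrappers used by the `atmsim` command-line script
#' (`system.file("cli", "atmsim.R", package = "atmsim")`):
#' `cmd_simulate()` validates a JSON configuration, writes a manifest,
#' runs the session and writes the event-log CSV plus a one-row summary;
#' `cmd_reproduce_tables()` writes the 28-row model-comparison summary;
#' `cmd_probe()` writes the probe-pairing predictions;
#' `cmd_metrics()` recomputes summaries from an existing event-log CSV.
#'
#' @param config_path Path to a session-configuration JSON file.
#' @param out_dir Output directory for `cmd_simulate()`.
#' @param out Output CSV path.
#' @param seed Master seed.
#' @param tail Analysis tail (responses).
#' @param quiet Suppress progress messages.
#' @return Paths of the files written, invisibly.
#' @name cmd
NULL

#' @rdname cmd
#' @export
cmd_simulate <- function(config_path, out_dir = ".", quiet = FALSE) {
  config <- config_from_json(config_path)  # errors before any output
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stem <- file.path(out_dir,
                    paste0("session_", config$model, "_", config$seed))
  paths <- c(manifest = paste0(stem, "_manifest.json"),
             events = paste0(stem, "_events.csv"),
             summary = paste0(stem, "_summary.csv"))
  write_manifest(config, paths, paths[["manifest"]])
  if (!quiet) message("simulating ", config$total_responses, " responses (",
                      config$model, ")")
  log <- run_session(config)
  write_event_log(log, paths[["events"]])
  utils::write.csv(summarise_session(log), paths[["summary"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @rdname cmd
#' @export
cmd_reproduce_tables <- function(out = "tables.csv", seed = 1L,
                                 quiet = FALSE) {
  if (!quiet) message("running the 28-cell model comparison grid")
  tab <- reproduce_tables(seed = seed)
  utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @rdname cmd
#' @export
cmd_probe <- function(out = "probes.csv", seed = 1L, quiet = FALSE) {
  if (!quiet) message("running probe pairings for all four models")
  tab <- probe_table(seed = seed)
  utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @rdname cmd
#' @param log_path Event-log CSV path.
#' @param vi_a,vi_b Mean intervals of the pair the log was generated
#'   under, seconds.
#' @param switch_cost Changeover time used in the simulation, seconds.
#' @export
cmd_metrics <- function(log_path, vi_a, vi_b, switch_cost = 0.3,
                        out = "summary.csv", tail = NULL) {
  log <- read_event_log(log_path)
  rich <- if (vi_a < vi_b) "A" else if (vi_b < vi_a) "B" else
    stop("equal schedules: no rich alternative", call. = FALSE)
  res <- data.frame(
    proportion_rich = proportion_rich(log, tail = tail %||% nrow(log),
                                      rich = rich),
    m_value = m_statistic(log, vi_a = vi_a, vi_b = vi_b,
                          switch_cost = switch_cost,
                          tail = tail %||% nrow(log))$m)
  utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}
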