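# Figure presets: parameter/protocol bundles reproducing the model panels,
# shipped as YAML files under inst/extdata/presets. Each file separates the
# source figure's printed parameter values (`params`) from fields the figure
# does not print (`assumed`), which were fixed once against the printed
# thresholds/behaviours and are documented in the methods vignette.

preset_dir <- function() {
  system.file("extdata", "presets", package = "mnbistab", mustWork = TRUE)
}

#' List the shipped figure presets
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  sort(sub("\\.yaml$", "", basename(list.files(preset_dir(),
                                               pattern = "\\.yaml$"))))
}

#' Load a figure preset
#'
#' @param name preset name (see [list_presets()]) or a path to a preset YAML
#'   file.
#' @return A list of class `mn_preset`: `name`, `figure`, `note`, `expect`
#'   (qualitative outcome tag), `params` (resolved `mn_params`), `assumed`
#'   (named fields taken from the assumed block), `protocol`, `analysis`.
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name
          else file.path(preset_dir(), paste0(name, ".yaml"))
  if (!file.exists(path)) stop("unknown preset: ", name)
  cfg <- yaml::read_yaml(path)
  need <- c("name", "expect", "protocol", "analysis")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("preset file lacks field(s): ",
                         paste(miss, collapse = ", "))
  over <- c(cfg$params, cfg$assumed)
  params <- do.call(mn_params, as.list(over))
  out <- list(name = cfg$name, figure = cfg$figure, note = cfg$note,
              expect = cfg$expect, params = params,
              assumed = cfg$assumed, protocol = cfg$protocol,
              analysis = cfg$analysis)
  class(out) <- "mn_preset"
  out
}

#' Load a model configuration file
#'
#' Accepts either a flat key-value parameter mapping (see [read_params()]) or
#' a structured config with a `params` block (plus optional `assumed` and
#' `protocol` blocks, as in the shipped presets). Defaults are applied first,
#' file values layered on top, and unknown parameter keys rejected with an
#' error naming the key. The resolved configuration is echoed to `stderr`.
#'
#' @param path YAML or JSON config path.
#' @param quiet suppress the config echo.
#' @return A list: `params` (an `mn_params`) and `program` (a
#'   `current_program`, or `NULL` if the file defines no protocol).
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping")
  structured <- any(c("params", "assumed", "protocol") %in% names(cfg))
  over <- if (structured) c(cfg$params, cfg$assumed) else cfg
  params <- do.call(mn_params, as.list(over))
  program <- if (structured && !is.null(cfg$protocol)) {
    parse_protocol(cfg$protocol, params)$program
  } else NULL
  if (!quiet) {
    message("resolved configuration from ", path, ":")
    for (nm in names(unclass(params)))
      message(sprintf("  %-13s = %g", nm, params[[nm]]))
  }
  list(params = params, program = program)
}

# Builds the current program (and bookkeeping times) described by a preset
# protocol block.
parse_protocol <- function(proto, params) {
  switch(proto$type,
    ramp = {
      list(kind = "ramp",
           max_I = proto$max_I,
           phase_duration = proto$phase_duration %||% 5000,
           program = make_ramp(proto$max_I, proto$phase_duration %||% 5000))
    },
    step = {
      dwell <- proto$dwell %||% 2000
      list(kind = "step", dwell = dwell,
           I_mid = proto$I_mid, I_high = proto$I_high,
           program = make_step_validation(proto$I_mid, proto$I_high, dwell))
    },
    pulse = {
      pre <- proto$pre %||% 500
      onset <- proto$onset_ramp %||% 0
      dur <- proto$duration
      post <- proto$post %||% 8000
      segs_d <- c(pre, if (onset > 0) onset, dur, post)
      starts <- c(0, if (onset > 0) 0, proto$amplitude, 0)
      ends <- c(0, if (onset > 0) proto$amplitude, proto$amplitude, 0)
      list(kind = "pulse", pre = pre, onset = onset, dur = dur, post = post,
           stim_start = pre, stim_end = pre + onset + dur,
           program = current_program(segs_d, starts, ends))
    },
    stop("unknown protocol type: ", proto$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a figure preset
#'
#' Simulates the preset's protocol, applies its analysis (ramp hysteresis,
#' step history-dependence, sADP/AHP metrics, or firing-rate profile),
#' derives the qualitative outcome tag and compares it with the preset's
#' expected tag. Optionally writes the artifacts (trace CSV where a single
#' trace is produced, result JSON always) to a directory. All outputs are
#' deterministic.
#'
#' @param name preset name or path (see [load_preset()]).
#' @param out_dir optional output directory (created if needed).
#' @param ... overrides passed to the analysis stage
#'   (e.g. `initial_phase_duration` or `max_phase_duration` for ramp presets).
#' @return A list of class `mn_preset_result`: `preset`, `result` (analysis
#'   object), `tag` (observed outcome), `expect`, `pass` (tag matches).
#' @export
run_preset <- function(name, out_dir = NULL, ...) {
  ps <- load_preset(name)
  proto <- parse_protocol(ps$protocol, ps$params)
  an <- ps$analysis
  trace <- NULL
  result <- tag <- NULL
  if (an$type == "hysteresis") {
    result <- suppressWarnings(measure_hysteresis(
      ps$params, max_I = proto$max_I,
      initial_phase_duration = proto$phase_duration, ...))
    tag <- if (isTRUE(result$never_fires)) "silent"
           else if (is.finite(result$delta_I) && result$delta_I > 0.05)
             "bistable" else "tonic"
  } else if (an$type == "step_check") {
    init <- resting_state(ps$params, 0)
    trace <- simulate_program(ps$params, proto$program, init = init,
                              dt_out = an$dt_out %||% 0.5)
    st <- attr(trace, "spike_times")
    dwell <- proto$dwell
    n_first <- sum(st > dwell + 0.25 * dwell & st <= 2 * dwell)
    n_second <- sum(st > 3 * dwell + 0.25 * dwell & st <= 4 * dwell)
    result <- list(spikes_first_mid = n_first, spikes_second_mid = n_second,
                   history_dependent = n_first == 0 && n_second >= 2)
    tag <- if (result$history_dependent) "bistable" else "tonic"
  } else if (an$type == "sadp") {
    init <- resting_state(ps$params, 0)
    trace <- simulate_program(ps$params, proto$program, init = init,
                              dt_out = an$dt_out %||% 0.5)
    result <- sadp_metrics(trace, stim_end = proto$stim_end,
                           window = an$window %||% 7500,
                           stim_start = proto$stim_start)
    tag <- if (result$upstate) "bistable"
           else if (result$amplitude >= 0) "ADP" else "AHP"
  } else if (an$type == "rate") {
    init <- resting_state(ps$params, 0)
    trace <- simulate_program(ps$params, proto$program, init = init,
                              dt_out = an$dt_out %||% 0.5)
    st <- attr(trace, "spike_times")
    if (length(st) < 4) {
      result <- list(classification = "silent", n_spikes = length(st))
      tag <- "silent"
    } else {
      w <- if (identical(an$window, "train"))
        c(st[1] - 1, st[1] + (an$train_span %||% 4000))
      else c(proto$stim_start, proto$stim_end)
      result <- rate_profile(trace, w)
      result$first_spike_latency <- st[1] - proto$stim_start
      # a seconds-long silent stall before the first spike is the hallmark of
      # slowly inactivating Kv1.2: report it as delayed excitation when the
      # discharge itself has no trend
      tag <- if (result$classification == "flat" &&
                 result$first_spike_latency > 1000) "delayed"
             else result$classification
    }
  } else stop("unknown analysis type: ", an$type)

  out <- list(preset = ps, result = result, tag = tag, expect = ps$expect,
              pass = identical(tag, ps$expect))
  class(out) <- "mn_preset_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(trace))
      write_trace(trace, file.path(out_dir, paste0(ps$name, "_trace.csv")))
    res <- result
    class(res) <- NULL
    res$spike_times <- NULL; res$freq_times <- NULL; res$freq <- NULL
    jsonlite::write_json(
      list(preset = ps$name, expect = ps$expect, tag = tag, pass = out$pass,
           result = res),
      file.path(out_dir, paste0(ps$name, "_result.json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.mn_preset_result <- function(x, ...) {
  cat(sprintf("Preset %s (figure %s): outcome '%s', expected '%s' -> %s\n",
              x$preset$name, x$preset$figure %||% "?", x$tag, x$expect,
              if (x$pass) "PASS" else "MISMATCH"))
  invisible(x)
}
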