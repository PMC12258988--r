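#' Detect spikes in a voltage trace
#'
#' Upward crossings of a voltage threshold separated by at least a refractory
#' interval. Works on simulated traces (`mn_trace`) or any data frame with
#' `time_ms` and `V_mV` columns (e.g. imported recordings).
#'
#' @param trace a trace data frame (`time_ms`, `V_mV`).
#' @param threshold crossing threshold, mV (default -10: action potentials in
#'   this model overshoot well above it while plateaus stay below).
#' @param refractory minimal spacing between crossings, ms (default 2).
#' @return Numeric vector of crossing times, ms.
#' @export
detect_spikes <- function(trace, threshold = -10, refractory = 2) {
  t <- trace$time_ms
  v <- trace$V_mV
  if (is.null(t) || is.null(v)) stop("trace needs time_ms and V_mV columns")
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  times <- t[up]
  # enforce the refractory interval sequentially
  out <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory) {
      out <- c(out, tt)
      last <- tt
    }
  }
  out
}

#' Measure ramp hysteresis (I_up, I_down)
#'
#' Runs the symmetric triangular current ramp from the resting state, reads
#' the onset threshold `I_up` as the injected current at the first spike of
#' the ascending phase and the offset threshold `I_down` as the current at the
#' last spike of the descending phase, then doubles the phase duration until
#' both thresholds move by less than `threshold_tol` (quasi-static limit) or
#' the duration cap is reached. Bistability is indicated by
#' `delta_I = I_up - I_down > 0`.
#'
#' @param params an `mn_params` object.
#' @param max_I ramp peak, uA/cm2 (default 3; must exceed the expected I_up).
#' @param initial_phase_duration first ascending/descending phase duration,
#'   ms (default 5000).
#' @param threshold_tol convergence tolerance on both thresholds, uA/cm2
#'   (default 0.02).
#' @param max_phase_duration doubling cap, ms (default 80000).
#' @param spike_threshold,refractory spike detection settings.
#' @param rtol,atol solver tolerances.
#' @return An object of class `hysteresis_result`: list with `I_up`, `I_down`,
#'   `delta_I`, `ramp_duration` (per phase, ms), `converged`, `never_fires`
#'   (no spikes even at `max_I`), `spikes_at_zero` (spiking persisted to the
#'   end of the descent; `I_down` reported as 0) and `n_ramps`.
#' @examples
#' \donttest{
#' p <- mn_params(g_CAN = 0.5)
#' h <- measure_hysteresis(p)
#' h$delta_I > 0
#' }
#' @export
measure_hysteresis <- function(params, max_I = 3,
                               initial_phase_duration = 5000,
                               threshold_tol = 0.02,
                               max_phase_duration = 80000,
                               spike_threshold = -10, refractory = 2,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "mn_params"))
  init <- resting_state(params, I_inj = 0)
  dur <- initial_phase_duration
  prev <- NULL
  n_ramps <- 0L
  converged <- FALSE
  res <- NULL
  repeat {
    prog <- make_ramp(max_I, dur)
    sim <- simulate_program(params, prog, init = init, keep_trace = FALSE,
                            spike_threshold = spike_threshold,
                            refractory = refractory, rtol = rtol, atol = atol)
    n_ramps <- n_ramps + 1L
    st <- sim$spike_times
    si <- sim$spike_iinj
    if (length(st) == 0) {
      res <- list(I_up = NA_real_, I_down = NA_real_, delta_I = NA_real_,
                  never_fires = TRUE, spikes_at_zero = FALSE)
    } else {
      asc <- st <= dur
      # a ramp that only fires on the descent would be pathological; guard
      I_up <- if (any(asc)) si[which(asc)[1]] else NA_real_
      last <- length(st)
      I_down <- si[last]
      spikes_at_zero <- FALSE
      if (st[last] > 2 * dur - 5 * refractory) {
        # still firing when the current returned to zero
        I_down <- 0
        spikes_at_zero <- TRUE
      }
      res <- list(I_up = I_up, I_down = I_down,
                  delta_I = I_up - I_down,
                  never_fires = FALSE, spikes_at_zero = spikes_at_zero)
    }
    if (!is.null(prev) && !res$never_fires && !is.na(res$I_up) &&
        !is.na(prev$I_up)) {
      if (abs(res$I_up - prev$I_up) < threshold_tol &&
          abs(res$I_down - prev$I_down) < threshold_tol) {
        converged <- TRUE
        break
      }
    }
    if (res$never_fires && !is.null(prev) && prev$never_fires) break
    if (2 * dur > max_phase_duration) break
    prev <- res
    dur <- 2 * dur
  }
  out <- c(res, list(ramp_duration = dur, converged = converged,
                     n_ramps = n_ramps, max_I = max_I,
                     threshold_tol = threshold_tol))
  class(out) <- "hysteresis_result"
  out
}

#' @export
print.hysteresis_result <- function(x, ...) {
  if (isTRUE(x$never_fires)) {
    cat("Ramp hysteresis: no spikes up to max_I =", x$max_I, "uA/cm2\n")
  } else {
    cat(sprintf(
      "Ramp hysteresis: I_up = %.4f, I_down = %.4f, delta_I = %.4f uA/cm2\n",
      x$I_up, x$I_down, x$delta_I))
    cat(sprintf("  phase duration %g ms, converged: %s%s\n", x$ramp_duration,
                x$converged,
                if (isTRUE(x$spikes_at_zero)) " (still firing at I = 0)" else ""))
  }
  invisible(x)
}

#' Confirm ramp-detected bistability with the step protocol
#'
#' At the midpoint current of the hysteresis interval, the five-plateau step
#' program (`0, I_mid, I_high, I_mid, 0`) must leave the cell silent on the
#' first `I_mid` plateau and firing on the second (after activation at
#' `I_high`). Disagreement with the ramp result is flagged with a warning,
#' never silently ignored.
#'
#' @param params an `mn_params` object.
#' @param hyst a converged `hysteresis_result` with `delta_I > 0`.
#' @param dwell plateau duration, ms (default 2000).
#' @param I_high current above I_up (default `I_up + 1`).
#' @param spike_threshold spike detection threshold, mV.
#' @return `TRUE` if the history dependence is confirmed, `FALSE` otherwise
#'   (with a warning describing the disagreement).
#' @export
confirm_bistability_by_steps <- function(params, hyst, dwell = 2000,
                                         I_high = NULL,
                                         spike_threshold = -10) {
  stopifnot(inherits(hyst, "hysteresis_result"))
  if (!is.finite(hyst$delta_I) || hyst$delta_I <= 0)
    stop("step confirmation requires a hysteresis result with delta_I > 0")
  I_mid <- (hyst$I_up + hyst$I_down) / 2
  if (is.null(I_high)) I_high <- hyst$I_up + 1
  prog <- make_step_validation(I_mid, I_high, dwell)
  sim <- simulate_program(params, prog, init = resting_state(params, 0),
                          keep_trace = FALSE,
                          spike_threshold = spike_threshold)
  st <- sim$spike_times
  # plateau windows (skip the first 25% of each plateau as settling time)
  in_win <- function(a, b) sum(st > a + 0.25 * dwell & st <= b)
  silent_before <- in_win(dwell, 2 * dwell) == 0
  firing_after <- in_win(3 * dwell, 4 * dwell) >= 2
  ok <- silent_before && firing_after
  if (!ok)
    warning(sprintf(paste0(
      "step protocol disagrees with ramp hysteresis at I_mid = %.3f: ",
      "first plateau %s, post-activation plateau %s"),
      I_mid, if (silent_before) "silent" else "firing",
      if (firing_after) "firing" else "silent"))
  ok
}

#' Scan one parameter for the onset of bistability
#'
#' Runs [measure_hysteresis()] at each value of one model parameter, holding
#' everything else fixed.
#'
#' @param params baseline `mn_params`.
#' @param param name of the swept `mn_params` field (e.g. `"g_CAN"`).
#' @param values grid of parameter values.
#' @param ... passed to [measure_hysteresis()].
#' @return A data frame with columns `value`, `I_up`, `I_down`, `delta_I`,
#'   `converged`, `never_fires`.
#' @export
hysteresis_scan <- function(params, param, values, ...) {
  stopifnot(param %in% names(mn_param_defaults()))
  rows <- lapply(values, function(v) {
    p <- do.call(set_params, c(list(params), setNames(list(v), param)))
    h <- tryCatch(measure_hysteresis(p, ...), error = function(e) NULL)
    if (is.null(h))
      return(data.frame(value = v, I_up = NA, I_down = NA, delta_I = NA,
                        converged = FALSE, never_fires = NA))
    data.frame(value = v,
               I_up = if (is.null(h$I_up)) NA else h$I_up,
               I_down = if (is.null(h$I_down)) NA else h$I_down,
               delta_I = if (is.null(h$delta_I)) NA else h$delta_I,
               converged = h$converged, never_fires = h$never_fires)
  })
  out <- do.call(rbind, rows)
  attr(out, "param") <- param
  out
}

#' Smallest parameter value with bistability in a scan
#'
#' @param scan result of [hysteresis_scan()].
#' @param delta_tol minimal hysteresis width counted as bistable, uA/cm2
#'   (default 0.05).
#' @return The smallest scanned value whose `delta_I > delta_tol`, or `NA` if
#'   none qualifies.
#' @export
first_bistable <- function(scan, delta_tol = 0.05) {
  ok <- !is.na(scan$delta_I) & scan$delta_I > delta_tol
  if (!any(ok)) return(NA_real_)
  min(scan$value[ok])
}

#' Two-parameter bistability map
#'
#' Tiles a plane of two model parameters with converged ramp-hysteresis
#' measurements and records the hysteresis width `delta_I` per cell.
#'
#' @param params baseline `mn_params`.
#' @param axisA,axisB lists `list(name = <mn_params field>, grid = <numeric>)`.
#' @param ... passed to [measure_hysteresis()].
#' @return An object of class `bistability_map`: list with `axisA`, `axisB`,
#'   `delta_I` (matrix, rows = axisA grid, cols = axisB grid; `NA` where the
#'   cell never fires or fails), `I_up`, `I_down` (same shape), `long`
#'   (long-form data frame) and `failures` (character).
#' @export
sweep_bistability_2d <- function(params, axisA, axisB, ...) {
  stopifnot(axisA$name %in% names(mn_param_defaults()),
            axisB$name %in% names(mn_param_defaults()))
  na <- length(axisA$grid)
  nb <- length(axisB$grid)
  dI <- iu <- id <- matrix(NA_real_, na, nb)
  conv <- matrix(FALSE, na, nb)
  failures <- character(0)
  for (j in seq_len(nb)) {
    for (i in seq_len(na)) {
      over <- setNames(list(axisA$grid[i], axisB$grid[j]),
                       c(axisA$name, axisB$name))
      h <- tryCatch(
        suppressWarnings(
          measure_hysteresis(do.call(set_params, c(list(params), over)), ...)),
        error = function(e) e)
      if (inherits(h, "error")) {
        failures <- c(failures, sprintf("%s=%g, %s=%g: %s", axisA$name,
                                        axisA$grid[i], axisB$name,
                                        axisB$grid[j], conditionMessage(h)))
        next
      }
      if (!h$never_fires) {
        dI[i, j] <- max(h$delta_I, 0)
        iu[i, j] <- h$I_up
        id[i, j] <- h$I_down
      } else {
        dI[i, j] <- 0
      }
      conv[i, j] <- h$converged
    }
  }
  long <- data.frame(
    axisA = rep(axisA$grid, times = nb),
    axisB = rep(axisB$grid, each = na),
    I_up = as.vector(iu), I_down = as.vector(id),
    delta_I = as.vector(dI), converged = as.vector(conv))
  names(long)[1:2] <- c(axisA$name, axisB$name)
  out <- list(axisA = axisA, axisB = axisB, delta_I = dI, I_up = iu,
              I_down = id, converged = conv, long = long,
              failures = failures)
  class(out) <- "bistability_map"
  out
}

#' Per-column bistability threshold of a 2D map
#'
#' For each value of axis B, the smallest axis-A value whose hysteresis width
#' exceeds `delta_tol`.
#'
#' @param map a `bistability_map`.
#' @param delta_tol minimal width counted as bistable (default 0.05 uA/cm2).
#' @return Data frame with the axis-B grid and the corresponding axis-A
#'   thresholds (`NA` where no grid point is bistable).
#' @export
bistability_threshold <- function(map, delta_tol = 0.05) {
  stopifnot(inherits(map, "bistability_map"))
  thr <- apply(map$delta_I, 2, function(col) {
    ok <- !is.na(col) & col > delta_tol
    if (!any(ok)) NA_real_ else min(map$axisA$grid[ok])
  })
  out <- data.frame(map$axisB$grid, thr)
  names(out) <- c(map$axisB$name, paste0(map$axisA$name, "_threshold"))
  out
}

#' Export a bistability map as long-form CSV (+ JSON metadata)
#'
#' @param map a `bistability_map`.
#' @param path CSV path; metadata is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_bistability_map <- function(map, path) {
  stopifnot(inherits(map, "bistability_map"))
  utils::write.csv(map$long, path, row.names = FALSE)
  meta <- list(axisA = map$axisA, axisB = map$axisB,
               failures = map$failures)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
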