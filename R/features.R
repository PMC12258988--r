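# Electrophysiological quantification of voltage traces: slow
# afterdepolarization (sADP) / afterhyperpolarization (AHP) metrics,
# firing-rate profiles, and the three-criterion bistability assessment used
# on holding-ladder protocols. Works on simulated traces or imported
# time/voltage tables.

#' Slow afterdepolarization / afterhyperpolarization metrics
#'
#' Quantifies the post-stimulus membrane-potential deflection relative to the
#' holding potential: signed peak amplitude (positive = ADP, negative = AHP),
#' duration at half-maximal amplitude, and area (integral of `V - holding_V`)
#' over the window between stimulus end and (by default) 7.5 s later.
#'
#' The half-max duration is measured on a smoothed copy of the trace (moving
#' mean, default 50 ms) to suppress channel-kinetics ripple; set
#' `smooth_ms = 0` for the raw trace. If spikes persist in the window the
#' deflection is not a passive tail; metrics are still returned but flagged
#' `upstate = TRUE`.
#'
#' @param trace a trace data frame (`time_ms`, `V_mV`).
#' @param stim_end stimulus end time, ms.
#' @param window post-stimulus analysis window, ms (default 7500).
#' @param holding_V holding potential, mV. Default: mean voltage over the
#'   500 ms preceding `stim_start` (which then must be supplied).
#' @param stim_start optional stimulus onset, ms (used only for the default
#'   `holding_V`).
#' @param smooth_ms moving-mean width for the half-max duration, ms.
#' @param margin settle time after `stim_end` excluded from the amplitude and
#'   duration measurements (ms, default 100: a few membrane time constants,
#'   so the passive repolarization from the stimulus level does not masquerade
#'   as a slow deflection). The area integral always starts at `stim_end`.
#' @param spike_threshold spike threshold used for the upstate flag, mV.
#' @return A list of class `sadp_metrics`: `amplitude` (mV, signed),
#'   `duration_at_half_max` (ms), `area` (mV ms), `window`, `holding_V`,
#'   `upstate`.
#' @export
sadp_metrics <- function(trace, stim_end, window = 7500, holding_V = NULL,
                         stim_start = NULL, smooth_ms = 50, margin = 100,
                         spike_threshold = -10) {
  t <- trace$time_ms
  v <- trace$V_mV
  if (max(t) < stim_end + window - 1e-6)
    stop("trace ends before the analysis window: extend the simulation or ",
         "shrink `window`")
  if (is.null(holding_V)) {
    if (is.null(stim_start))
      stop("supply either holding_V or stim_start (for the 500 ms ",
           "pre-stimulus mean)")
    pre <- t >= stim_start - 500 & t < stim_start
    if (!any(pre)) stop("no samples in the 500 ms before stim_start")
    holding_V <- mean(v[pre])
  }
  sel <- t >= stim_end & t <= stim_end + window
  tw <- t[sel]
  dev <- v[sel] - holding_V
  spikes <- detect_spikes(data.frame(time_ms = tw, V_mV = v[sel]),
                          threshold = spike_threshold)
  upstate <- length(spikes) > 0
  area <- trapz(tw, dev)
  # amplitude and half-max duration on the smoothed deflection past the
  # settle margin: the moving mean suppresses channel-kinetics ripple and the
  # margin drops the passive repolarization transient
  keep <- tw >= stim_end + margin
  tm <- tw[keep]
  devs <- if (smooth_ms > 0) moving_mean(tm, dev[keep], smooth_ms)
          else dev[keep]
  ipk <- which.max(abs(devs))
  amplitude <- devs[ipk]
  half <- devs[ipk] / 2
  above <- if (devs[ipk] >= 0) devs >= half else devs <= half
  duration <- sum(diff(tm)[above[-length(above)] & above[-1]])
  out <- list(amplitude = amplitude, duration_at_half_max = duration,
              area = area, window = window, holding_V = holding_V,
              upstate = upstate)
  class(out) <- "sadp_metrics"
  out
}

#' @export
print.sadp_metrics <- function(x, ...) {
  kind <- if (x$upstate) "upstate (spiking persists)"
          else if (x$amplitude >= 0) "sADP" else "AHP"
  cat(sprintf(
    "%s: amplitude %.3f mV, half-max duration %.0f ms, area %.0f mV*ms\n",
    kind, x$amplitude, x$duration_at_half_max, x$area))
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

moving_mean <- function(t, y, width_ms) {
  if (length(y) < 3) return(y)
  dt <- median(diff(t))
  k <- max(1L, as.integer(round(width_ms / dt)))
  if (k %% 2 == 0) k <- k + 1L
  if (k >= length(y)) k <- length(y) - (1 - length(y) %% 2)
  pad <- (k - 1L) %/% 2L
  yy <- c(rep(y[1], pad), y, rep(y[length(y)], pad))
  as.numeric(stats::filter(yy, rep(1 / k, k), sides = 2))[pad + seq_along(y)]
}

#' Instantaneous firing-rate profile and its trend
#'
#' Spike times within the stimulus window, instantaneous frequencies
#' (reciprocal inter-spike intervals placed at interval midpoints), the
#' least-squares linear trend of frequency over time, and a classification:
#' `ramping` (accelerating), `adapting` (decelerating) or `flat`, using a
#' dead-band of +/- 5 percent of the mean rate per second.
#'
#' @param trace a trace data frame (`time_ms`, `V_mV`).
#' @param window `c(start, end)` analysis window, ms.
#' @param spike_threshold,refractory spike detection settings.
#' @param deadband_frac dead-band as a fraction of mean rate per second
#'   (default 0.05).
#' @return A list of class `rate_profile`: `spike_times`, `freq_times` (ms),
#'   `freq` (Hz), `slope` (Hz/s), `mean_rate` (Hz), `classification`.
#'   With fewer than 4 spikes an error of class `mn_insufficient_spikes` is
#'   thrown.
#' @export
rate_profile <- function(trace, window, spike_threshold = -10,
                         refractory = 2, deadband_frac = 0.05) {
  # simulated traces carry spike times detected on the dense solver output;
  # prefer those over re-detection on the (possibly coarser) sample grid
  st <- attr(trace, "spike_times")
  if (is.null(st)) st <- detect_spikes(trace, spike_threshold, refractory)
  st <- st[st >= window[1] & st <= window[2]]
  if (length(st) < 4)
    stop(structure(class = c("mn_insufficient_spikes", "error", "condition"),
                   list(message = sprintf(
                     "rate profile needs >= 4 spikes in the window (got %d)",
                     length(st)), call = sys.call(-1))))
  isi <- diff(st)
  freq <- 1000 / isi
  mids <- st[-length(st)] + isi / 2
  fit <- lm(freq ~ mids)
  slope <- unname(coef(fit)[2]) * 1000  # Hz per s
  mean_rate <- mean(freq)
  band <- deadband_frac * mean_rate
  cls <- if (slope > band) "ramping" else if (slope < -band) "adapting"
         else "flat"
  out <- list(spike_times = st, freq_times = mids, freq = freq,
              slope = slope, mean_rate = mean_rate, classification = cls)
  class(out) <- "rate_profile"
  out
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("Rate profile: %d spikes, mean %.2f Hz, trend %+.3f Hz/s -> %s\n",
              length(x$spike_times), x$mean_rate, x$slope, x$classification))
  invisible(x)
}

#' Run a holding-current ladder
#'
#' Simulates every program of a [make_holding_ladder()] protocol from the
#' resting state at its holding current (levels with no resting state are
#' recorded as such and excluded from the bistability assessment).
#'
#' @param params an `mn_params` object.
#' @param ladder a `holding_ladder`.
#' @param dt_out sampling interval, ms (default 0.5: ladder traces are long
#'   and only spike times/levels are needed downstream).
#' @param ... passed to [simulate_program()].
#' @return A list of `mn_trace` (or `NULL` where no resting state exists),
#'   with the ladder attached as attribute `ladder`.
#' @export
run_holding_ladder <- function(params, ladder, dt_out = 0.5, ...) {
  stopifnot(inherits(ladder, "holding_ladder"))
  holding <- attr(ladder, "holding")
  traces <- lapply(seq_along(ladder), function(i) {
    init <- tryCatch(resting_state(params, I_inj = holding[i]),
                     error = function(e) NULL)
    if (is.null(init)) return(NULL)
    simulate_program(params, ladder[[i]], init = init, dt_out = dt_out, ...)
  })
  attr(traces, "ladder") <- ladder
  traces
}

#' Three-criterion bistability assessment on holding-ladder traces
#'
#' A holding level counts as bistable when (1) the pre-stimulus membrane
#' potential stays hyperpolarized below the spike threshold (downstate, no
#' spikes before the pulse), (2) self-sustained firing persists after the
#' pulse until the hyperpolarizing probe (upstate), and (3) the probe resets
#' the cell to the downstate (no spikes in the tail). The voltage range
#' `delta_V = Vh_max - Vh_min` spans the pre-pulse potentials of the
#' qualifying levels, and `delta_I_holding` the corresponding holding
#' currents.
#'
#' @param traces result of [run_holding_ladder()] (the ladder metadata rides
#'   along as an attribute).
#' @param spike_threshold spike threshold, mV.
#' @return A list of class `bistability_assessment`: `is_bistable`, `Vh_min`,
#'   `Vh_max`, `delta_V`, `I_min`, `I_max`, `delta_I_holding`, and `per_level`
#'   (data frame with the three criterion booleans per holding value).
#' @export
assess_bistability <- function(traces, spike_threshold = -10) {
  ladder <- attr(traces, "ladder")
  if (is.null(ladder)) stop("traces must carry a `ladder` attribute ",
                            "(use run_holding_ladder())")
  holding <- attr(ladder, "holding")
  pulse_on <- attr(ladder, "pulse_on")
  pulse_off <- attr(ladder, "pulse_off")
  probe_on <- attr(ladder, "probe_on")
  probe_off <- attr(ladder, "probe_off")
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (is.null(tr))
      return(data.frame(holding = holding[i], Vh = NA_real_,
                        downstate = FALSE, upstate = FALSE, resets = FALSE,
                        bistable = FALSE))
    st <- detect_spikes(tr, spike_threshold)
    pre <- tr$time_ms < pulse_on
    Vh <- mean(tr$V_mV[tr$time_ms >= pulse_on - 500 & tr$time_ms < pulse_on])
    downstate <- !any(st < pulse_on) && Vh < spike_threshold
    # self-sustained means firing persists all the way to the probe, not just
    # a decaying tail: require spikes throughout the post-pulse window
    post <- st[st > pulse_off + 200 & st < probe_on]
    upstate <- length(post) >= 2 && max(post) > probe_on - 1000
    resets <- !any(st > probe_off + 200)
    data.frame(holding = holding[i], Vh = Vh, downstate = downstate,
               upstate = upstate, resets = resets,
               bistable = downstate && upstate && resets)
  })
  per_level <- do.call(rbind, rows)
  ok <- per_level$bistable
  if (any(ok)) {
    out <- list(is_bistable = TRUE,
                Vh_min = min(per_level$Vh[ok]),
                Vh_max = max(per_level$Vh[ok]),
                I_min = min(per_level$holding[ok]),
                I_max = max(per_level$holding[ok]))
    out$delta_V <- out$Vh_max - out$Vh_min
    out$delta_I_holding <- out$I_max - out$I_min
  } else {
    out <- list(is_bistable = FALSE, Vh_min = NA_real_, Vh_max = NA_real_,
                delta_V = NA_real_, I_min = NA_real_, I_max = NA_real_,
                delta_I_holding = NA_real_)
  }
  out$per_level <- per_level
  class(out) <- "bistability_assessment"
  out
}

#' @export
print.bistability_assessment <- function(x, ...) {
  if (x$is_bistable) {
    cat(sprintf(paste0(
      "Bistable: Vh in [%.2f, %.2f] mV (delta_V = %.2f), holding I in ",
      "[%.3f, %.3f] (delta_I = %.3f)\n"),
      x$Vh_min, x$Vh_max, x$delta_V, x$I_min, x$I_max, x$delta_I_holding))
  } else cat("Not bistable under the three-criterion test\n")
  invisible(x)
}

#' Read a generic two-column time/voltage CSV
#'
#' Accepts external voltage recordings as CSV with two columns (time in ms,
#' voltage in mV; any header names) and returns a trace usable by the feature
#' functions.
#'
#' @param path CSV path.
#' @return A data frame with columns `time_ms`, `V_mV`, class `mn_trace`.
#' @export
read_voltage_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected at least two columns: time (ms), V (mV)")
  if (all(c("time_ms", "V_mV") %in% names(df))) {
    out <- df[c("time_ms", "V_mV")]
  } else {
    out <- df[1:2]
    names(out) <- c("time_ms", "V_mV")
  }
  if (is.unsorted(out$time_ms)) stop("time column must be increasing")
  class(out) <- c("mn_trace", "data.frame")
  out
}
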