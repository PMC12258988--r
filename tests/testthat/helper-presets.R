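# shared parameter sets and fast protocol options for the test suite

# bistable reference cell (CAN-driven); baseline fields documented in the
# fig2_ramp preset
fig2_params <- function(...) {
  mn_params(g_CAN = 0.5, g_KCa = 0.5, `g_Kv1.2` = 0.1, K_out = 8.2, ...)
}

# sodium-based bistable cell at elevated potassium
fig8_params <- function(...) {
  mn_params(g_CAN = 0, g_NaP = 0.4, K_out = 12, ...)
}

# passive membrane: only the leak current
passive_params <- function(...) {
  mn_params(g_NaF = 0, g_Kdr = 0, g_CaL = 0, ...)
}

# ramp options that trade quasi-static accuracy for speed in property tests
fast_ramp <- list(initial_phase_duration = 2000, max_phase_duration = 16000,
                  threshold_tol = 0.05)

measure_fast <- function(params, ...) {
  suppressWarnings(do.call(measure_hysteresis,
                           c(list(params), fast_ramp, list(...))))
}

# synthetic voltage trace with triangular spikes at given times
synthetic_spike_trace <- function(spike_times, dt = 0.1, t_end = NULL,
                                  base = -80, peak = 20, half_width = 1) {
  if (is.null(t_end)) t_end <- max(spike_times) + 50
  t <- seq(0, t_end, by = dt)
  v <- rep(base, length(t))
  for (s in spike_times) {
    d <- abs(t - s)
    lift <- pmax(0, 1 - d / half_width) * (peak - base)
    v <- pmax(v, base + lift)
  }
  structure(data.frame(time_ms = t, V_mV = v),
            class = c("mn_trace", "data.frame"))
}
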