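test_that("detect_spikes counts threshold crossings with refractoriness", {
  flat <- data.frame(time_ms = seq(0, 100, 0.1), V_mV = -80)
  expect_length(detect_spikes(flat), 0)
  tr <- synthetic_spike_trace(seq(100, 700, by = 100))
  expect_length(detect_spikes(tr, threshold = -10), 7)
  expect_length(detect_spikes(tr, threshold = 30), 0)
  # crossings closer than the refractory interval are merged
  tr2 <- synthetic_spike_trace(c(100, 100.6, 101.2, 200), half_width = 0.2)
  expect_length(detect_spikes(tr2, refractory = 2), 2)
})

test_that("sADP metrics recover the geometry of a synthetic deflection", {
  # isosceles triangle: peak +6 mV, base 1000 ms, starting at stimulus end
  t <- seq(0, 9000, by = 1)
  v <- -70 + pmax(0, 1 - abs(t - 1500) / 500) * 6
  tr <- data.frame(time_ms = t, V_mV = v)
  m <- sadp_metrics(tr, stim_end = 1000, window = 7500, holding_V = -70,
                    smooth_ms = 0, margin = 0)
  expect_equal(m$amplitude, 6, tolerance = 1e-9)
  expect_equal(m$duration_at_half_max, 500, tolerance = 1)
  expect_equal(m$area, 3000, tolerance = 1e-6)
  expect_false(m$upstate)
  # scaling the deflection scales amplitude and area exactly
  tr2 <- tr
  tr2$V_mV <- -70 + (tr$V_mV + 70) * 2.5
  m2 <- sadp_metrics(tr2, stim_end = 1000, window = 7500, holding_V = -70,
                     smooth_ms = 0, margin = 0)
  expect_equal(m2$amplitude, 2.5 * m$amplitude)
  expect_equal(m2$area, 2.5 * m$area)
  expect_equal(m2$duration_at_half_max, m$duration_at_half_max)
  # flat trace: null metrics
  fl <- data.frame(time_ms = t, V_mV = rep(-70, length(t)))
  m0 <- sadp_metrics(fl, stim_end = 1000, window = 7500, holding_V = -70)
  expect_equal(m0$amplitude, 0)
  expect_equal(m0$area, 0)
  # window must fit in the trace
  expect_error(sadp_metrics(tr, stim_end = 5000, window = 7500,
                            holding_V = -70), "window")
})

test_that("rate profiles classify flat, ramping and adapting trains", {
  # perfectly periodic train
  tr <- synthetic_spike_trace(seq(100, 2100, by = 100))
  rp <- rate_profile(tr, c(0, 2200))
  expect_equal(rp$classification, "flat")
  # spike times are quantized by the 0.1 ms sample grid
  expect_lt(abs(rp$slope), 1e-2)
  expect_equal(rp$mean_rate, 10, tolerance = 1e-4)
  # accelerating train: intervals shrink 100 -> 50 ms over 2 s
  st <- Reduce(function(t, isi) t + isi, seq(100, 50, length.out = 20),
               accumulate = TRUE, init = 100)
  rr <- rate_profile(synthetic_spike_trace(st), c(0, max(st) + 10))
  expect_equal(rr$classification, "ramping")
  expect_gt(rr$slope, 0)
  # decelerating train
  st2 <- Reduce(`+`, seq(50, 100, length.out = 20), accumulate = TRUE,
                init = 100)
  ra <- rate_profile(synthetic_spike_trace(st2), c(0, max(st2) + 10))
  expect_equal(ra$classification, "adapting")
  expect_lt(ra$slope, 0)
  # too few spikes is a typed error
  expect_error(rate_profile(synthetic_spike_trace(c(100, 200, 300)),
                            c(0, 400)),
               class = "mn_insufficient_spikes")
})

test_that("simulated ADP/AHP dichotomy follows the CAN/SK balance", {
  prog <- current_program(c(1000, 500, 8000), c(0, 3.5, 0))
  amp <- sapply(c(0, 0.7), function(g) {
    p <- mn_params(g_KCa = 0.5, g_CAN = g)
    tr <- simulate_program(p, prog, init = resting_state(p, 0), dt_out = 0.5)
    sadp_metrics(tr, stim_end = 1500, stim_start = 1000)$amplitude
  })
  expect_lt(amp[1], 0)  # SK only: afterhyperpolarization
  expect_gt(amp[2], 0)  # CAN dominant: slow afterdepolarization
})

test_that("three-criterion ladder assessment brackets the hysteresis interval", {
  p <- fig2_params()  # ramp interval about [1.12, 1.70] uA/cm2
  lad <- make_holding_ladder(pulse_amp = 2.5, holding_values = c(0.8, 1.3, 1.5))
  a <- assess_bistability(run_holding_ladder(p, lad))
  expect_true(a$is_bistable)
  # holding below I_down fails the sustained-upstate criterion
  expect_false(a$per_level$bistable[1])
  expect_true(all(a$per_level$bistable[2:3]))
  expect_equal(c(a$I_min, a$I_max), c(1.3, 1.5))
  expect_gt(a$delta_V, 0)
  # qualifying holdings are kept below threshold before the pulse and reset
  expect_true(all(a$per_level$downstate))
  expect_true(all(a$per_level$resets))
  # range nests inside the ramp-derived interval within one ladder step
  expect_gt(a$I_min, 1.12 - 0.2)
  expect_lt(a$I_max, 1.70 + 0.2)
  # the non-bistable control fails criterion 2 at every level
  a0 <- assess_bistability(run_holding_ladder(set_params(p, g_CAN = 0), lad))
  expect_false(a0$is_bistable)
  expect_false(any(a0$per_level$upstate))
})
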