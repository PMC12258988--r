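test_that("ramp hysteresis resolves onset and offset thresholds in order", {
  p <- fig8_params()
  h <- suppressWarnings(measure_hysteresis(p, max_I = 2))
  expect_s3_class(h, "hysteresis_result")
  expect_true(h$converged)
  expect_lte(h$I_down, h$I_up + h$threshold_tol)
  expect_gt(h$delta_I, 0.1)
  expect_false(h$never_fires)
  # whenever the interval is clearly open, the step protocol agrees
  expect_true(confirm_bistability_by_steps(p, h))
})

test_that("a cell that cannot fire below the ramp peak is reported as such", {
  p <- mn_params(`g_Kv1.2` = 2)  # strong Kv1.2 brake, rheobase above 3
  h <- suppressWarnings(measure_hysteresis(p, max_I = 3,
                                           initial_phase_duration = 1000,
                                           max_phase_duration = 2000))
  expect_true(h$never_fires)
  expect_true(is.na(h$delta_I))
})

test_that("monostable controls show no hysteresis and fail the step test", {
  p <- fig2_params(g_CAN = 0)
  # fully converged ramps: fast ramps leave a spurious rate-dependent gap
  h <- suppressWarnings(measure_hysteresis(p, max_I = 4))
  expect_lt(abs(h$delta_I), 0.05)
  # step confirmation refuses hysteresis results with no open interval
  h0 <- h
  h0$delta_I <- 0
  expect_error(confirm_bistability_by_steps(p, h0), "delta_I > 0")
})

test_that("plateaus that persist to zero current are flagged", {
  p <- mn_params(g_CAN = 1.2, g_KCa = 0.5)  # strong CAN: unbounded plateau
  h <- measure_fast(p, max_I = 3)
  expect_true(h$spikes_at_zero)
  expect_equal(h$I_down, 0)
})

test_that("parameter scans locate the onset of bistability", {
  p0 <- mn_params(g_CAN = 0, g_NaP = 0.25)
  sc <- suppressWarnings(hysteresis_scan(p0, "K_out", c(10, 12, 13),
                                         max_I = 2))
  expect_equal(nrow(sc), 3)
  expect_lt(sc$delta_I[1], 0.05)
  expect_gt(sc$delta_I[3], 0.1)
  expect_equal(first_bistable(sc), 12)
  expect_true(is.na(first_bistable(sc[1, ])))
})

test_that("two-parameter sweeps tile the plane and export cleanly", {
  p0 <- mn_params(g_CAN = 0)
  map <- sweep_bistability_2d(
    p0, axisA = list(name = "g_NaP", grid = c(0.25, 0.4)),
    axisB = list(name = "K_out", grid = c(10, 12)),
    max_I = 2, initial_phase_duration = 2000, max_phase_duration = 16000,
    threshold_tol = 0.05)
  expect_equal(dim(map$delta_I), c(2, 2))
  expect_true(all(map$delta_I[, 1] < 0.05))   # 10 mM: no bistability
  expect_true(all(map$delta_I[, 2] > 0.05))   # 12 mM: both g_NaP bistable
  thr <- bistability_threshold(map)
  expect_true(is.na(thr$g_NaP_threshold[1]))
  expect_equal(thr$g_NaP_threshold[2], 0.25)
  f <- tempfile(fileext = ".csv")
  write_bistability_map(map, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 4)
  expect_true(file.exists(paste0(f, ".json")))
  unlink(c(f, paste0(f, ".json")))
})
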