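test_that("passive configuration has a unique stable equilibrium at E_L + I/g_L", {
  p <- passive_params()
  for (I in c(0, 1)) {
    eq <- find_equilibria(p, I)
    expect_length(eq, 1)
    expect_equal(eq[[1]]$classification, "stable-node")
    expect_equal(eq[[1]]$state[["V"]], -80 + I / p$g_L, tolerance = 1e-8)
    expect_lt(eq[[1]]$residual, 1e-8)
  }
})

test_that("inside the bistable range rest and saddle coexist; above it rest is lost", {
  p <- fig2_params()
  eq_mid <- find_equilibria(p, 1.4)
  cls <- vapply(eq_mid, `[[`, "", "classification")
  expect_gte(sum(cls == "stable-node"), 1)
  expect_gte(sum(cls == "saddle"), 1)
  expect_true(all(vapply(eq_mid, `[[`, 0, "residual") < 1e-8))
  # every saddle has exactly one eigenvalue with positive real part
  for (e in eq_mid[cls == "saddle"])
    expect_equal(sum(Re(e$eigenvalues) > 0), 1)
  eq_hi <- find_equilibria(p, 2.5)
  expect_false(any(vapply(eq_hi, `[[`, "", "classification") == "stable-node"))
})

test_that("equilibrium classifications are confirmed by simulation", {
  p <- fig2_params()
  eq <- find_equilibria(p, 1.4)
  cls <- vapply(eq, `[[`, "", "classification")
  node <- eq[[which(cls == "stable-node")[1]]]
  # a small perturbation of the stable node relaxes back
  s <- node$state
  s[["V"]] <- s[["V"]] + 1
  out <- simulate_program(p, current_program(2000, 1.4), init = s,
                          keep_trace = FALSE)
  expect_length(out$spike_times, 0)
  expect_equal(out$final_state[["V"]], node$state[["V"]], tolerance = 1e-4)
})

test_that("limit-cycle summaries reflect spiking persistence and stationarity", {
  p <- fig2_params()
  rest <- resting_state(p, 0)
  # kick above I_up: sustained spiking
  kick <- simulate_program(p, current_program(c(500, 500), c(3, 2.5)),
                           init = rest, keep_trace = FALSE)
  lc <- trace_limit_cycle(p, 2.5, kick$final_state)
  expect_true(lc$exists)
  expect_gt(lc$max_V, 0)
  expect_lt(lc$min_V, -40)
  expect_gt(lc$frequency, 5)
  # halving the window leaves the frequency within 10%
  lc2 <- trace_limit_cycle(p, 2.5, kick$final_state, window = 1000)
  expect_lt(abs(lc2$frequency - lc$frequency) / lc$frequency, 0.1)
  # below I_down any init settles to silence
  lc0 <- trace_limit_cycle(p, 0.5, kick$final_state, settle = 5000)
  expect_false(lc0$exists)
})

test_that("continuation branches coexist over the hysteresis interval", {
  p <- fig2_params()
  d <- continuation_diagram(p, seq(0.8, 2.2, by = 0.2))
  expect_false(is.null(d$coexistence))
  # interval nests inside the converged ramp interval at grid resolution
  expect_gt(d$coexistence[1], 1.1 - 0.21)
  expect_lt(d$coexistence[2], 1.7 + 0.21)
  # sodium-based regime: resting branch lies below the limit-cycle voltage
  p8 <- fig8_params()
  d8 <- continuation_diagram(p8, seq(0.4, 1.0, by = 0.2))
  b <- d8$branches
  co <- b$I_inj >= d8$coexistence[1] & b$I_inj <= d8$coexistence[2]
  rest <- b[co & b$direction == "ascending" & !b$spiking, ]
  cyc <- b[co & b$direction == "descending" & b$spiking, ]
  m <- merge(rest[c("I_inj", "max_V")], cyc[c("I_inj", "min_V")], by = "I_inj")
  expect_gt(nrow(m), 0)
  expect_true(all(m$max_V < m$min_V))
})
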