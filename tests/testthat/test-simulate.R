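test_that("integration is bitwise deterministic", {
  p <- fig2_params()
  init <- resting_state(p, 0)
  prog <- current_program(c(100, 100), c(0, 2.5))
  a <- simulate_program(p, prog, init = init)
  b <- simulate_program(p, prog, init = init)
  expect_identical(a$V_mV, b$V_mV)
  expect_identical(a$Ca_mM, b$Ca_mM)
  expect_identical(attr(a, "spike_times"), attr(b, "spike_times"))
})

test_that("passive membrane relaxes mono-exponentially to E_L + I/g_L", {
  p <- passive_params()
  tr <- simulate_program(p, current_program(100, 1), init = mn_state(-80),
                         dt_out = 0.1)
  tau <- p$C / p$g_L
  theory <- -80 + (1 / p$g_L) * (1 - exp(-tr$time_ms / tau))
  expect_lt(max(abs(tr$V_mV - theory)), 1e-4)
})

test_that("with I_CaL removed, calcium decays as exp(-t/tau_eff)", {
  p <- mn_params(g_CaL = 0)
  tr <- simulate_program(p, current_program(500, 0),
                         init = mn_state(-80, Ca = 1e-3), dt_out = 1)
  teff <- effective_tau(p$k_CICR, p$tau_Ca)
  theory <- 1e-3 * exp(-tr$time_ms / teff)
  expect_lt(max(abs(tr$Ca_mM - theory) / theory), 1e-6)
})

test_that("gates stay in [0,1] and calcium non-negative while spiking", {
  p <- fig2_params()
  init <- resting_state(p, 0)
  tr <- simulate_program(p, current_program(500, 2.5), init = init)
  gates <- as.matrix(tr[, c("h_NaF", "m_Kdr", "m_Kv1.2", "h_Kv1.2",
                            "m_CaL", "h_CaL")])
  expect_gt(length(attr(tr, "spike_times")), 5)
  expect_true(all(gates >= -1e-9 & gates <= 1 + 1e-9))
  expect_true(all(tr$Ca_mM >= 0))
})

test_that("solutions are converged with respect to the solver tolerances", {
  p <- fig2_params()
  init <- resting_state(p, 0)
  prog <- current_program(500, 0.5)  # silent hold
  a <- simulate_program(p, prog, init = init, dt_out = 1)
  b <- simulate_program(p, prog, init = init, dt_out = 1,
                        rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(tail(a$V_mV, 1) - tail(b$V_mV, 1)), 1e-3)
  # spike counts are tolerance-invariant on a firing run
  prog2 <- current_program(1000, 2.5)
  s1 <- simulate_program(p, prog2, init = init, keep_trace = FALSE)
  s2 <- simulate_program(p, prog2, init = init, keep_trace = FALSE,
                         rtol = 1e-9, atol = 1e-11)
  expect_equal(length(s1$spike_times), length(s2$spike_times))
})

test_that("resting_state finds rest below I_up and signals its loss above", {
  p <- fig2_params()
  rs <- resting_state(p, 0)
  expect_lt(max(abs(mn_rhs(0, rs, 0, p))), 1e-8)
  expect_lt(rs[["V"]], -70)
  expect_error(resting_state(p, 3), class = "mn_no_rest")
  # passive rest is in the leak-reversal neighbourhood
  rp <- resting_state(passive_params(), 0)
  expect_equal(rp[["V"]], -80, tolerance = 1e-6)
})

test_that("after one spike without CICR, pumps clear calcium rapidly", {
  p <- mn_params(k_CICR = 0)
  init <- resting_state(p, 0)
  tr <- simulate_program(p, current_program(c(20, 3, 200), c(0, 15, 0)),
                         init = init)
  expect_length(attr(tr, "spike_times"), 1)
  pk <- which.max(tr$Ca_mM)
  t_pk <- tr$time_ms[pk]
  after <- tr$Ca_mM[tr$time_ms >= t_pk + 5.5 * p$tau_Ca][1]
  expect_lt(after / tr$Ca_mM[pk], 0.01)
})

test_that("traces round-trip through CSV and external tables are accepted", {
  p <- fig2_params()
  tr <- simulate_program(p, current_program(20, 0),
                         init = resting_state(p, 0), dt_out = 0.5)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$V_mV, tr$V_mV, tolerance = 1e-14)
  expect_equal(back$Ca_mM, tr$Ca_mM, tolerance = 1e-14)
  expect_equal(names(back), names(as.data.frame(tr)))
  unlink(f)
  # generic two-column table
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = c(0, 1, 2), mv = c(-80, -75, -80)), f2,
                   row.names = FALSE)
  g <- read_voltage_csv(f2)
  expect_equal(names(g), c("time_ms", "V_mV"))
  unlink(f2)
})
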