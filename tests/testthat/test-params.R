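test_that("defaults reproduce the published constants", {
  p <- mn_params()
  expect_equal(p$C, 1)
  expect_equal(p$g_NaF, 120)
  expect_equal(p$g_Kdr, 100)
  expect_equal(p$g_CaL, 0.05)
  expect_equal(p$g_L, 0.1)
  expect_equal(c(p$g_NaP, p$`g_Kv1.2`, p$g_CAN, p$g_KCa), rep(0, 4))
  expect_equal(c(p$E_Na, p$E_Ca, p$E_CAN, p$E_L), c(55, 80, 0, -80))
  expect_equal(c(p$K_out, p$K_in, p$nernst_coeff), c(4, 140, 26.54))
  expect_equal(c(p$K_CAN, p$K_d), c(0.74e-3, 0.2e-3))
  expect_equal(c(p$f, p$alpha, p$k_CICR, p$tau_Ca), c(0.01, 5e-4, 0.096, 10))
  expect_equal(c(p$tau_CaL_m, p$tau_CaL_h), c(0.5, 18))
})

test_that("parameter invariants are enforced", {
  expect_error(mn_params(g_CAN = -1), "conductance")
  expect_error(mn_params(C = 0), "C must be")
  expect_error(mn_params(K_out = 0), "potassium")
  expect_error(mn_params(tau_Ca = -1), "tau_Ca")
  expect_error(mn_params(bogus = 1), "unknown parameter")
  # CICR gain must stay below the pump rate
  expect_error(mn_params(k_CICR = 0.1), "k_CICR")
  expect_error(mn_params(k_CICR = 0.2), "k_CICR")
  expect_silent(p <- mn_params(k_CICR = 0.099))
  # operating-range edges warn but do not fail, so sweeps can probe them
  expect_warning(mn_params(K_out = 14), "outside the modelled range")
  expect_warning(mn_params(`g_Kv1.2` = 11), "outside the modelled range")
})

test_that("potassium Nernst potential follows coeff * ln(Kout/Kin)", {
  expect_equal(nernst_EK(140, 140), 0)
  expect_equal(nernst_EK(4, 140), 26.54 * log(4 / 140))
  expect_equal(nernst_EK(4, 140), -94.35894, tolerance = 1e-6)
  expect_gt(nernst_EK(12, 140), nernst_EK(8, 140))
  expect_gt(nernst_EK(8, 140), nernst_EK(4, 140))
  expect_error(nernst_EK(0, 140), "positive")
  expect_error(nernst_EK(4, -1), "positive")
})

test_that("effective calcium time constant and its runaway guard", {
  expect_equal(effective_tau(0.096, 10), 250)
  expect_equal(effective_tau(0, 10), 10)
  expect_equal(effective_tau(0.05, 10), 20)
  expect_error(effective_tau(0.1, 10), "runaway")
  expect_error(effective_tau(0.2, 10), "runaway")
})

test_that("alpha derives from Faraday constant and shell thickness", {
  a <- alpha_from_shell(9.648e4, 0.1)
  expect_lt(abs(a - 5e-4) / 5e-4, 0.05)
})

test_that("parameter sets round-trip through YAML and JSON configs", {
  p <- mn_params(g_CAN = 0.37, K_out = 6.5, k_CICR = 0.08)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    q <- read_params(f)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
    unlink(f)
  }
  # unknown keys in a config are rejected with the key named
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(g_CAN = 0.5, not_a_field = 1), f)
  expect_error(read_params(f), "not_a_field")
  unlink(f)
})

test_that("set_params overrides single fields and revalidates", {
  p <- mn_params()
  q <- set_params(p, g_CAN = 0.5)
  expect_equal(q$g_CAN, 0.5)
  q$g_CAN <- p$g_CAN
  expect_equal(unclass(q), unclass(p))
  expect_error(set_params(p, k_CICR = 0.2), "k_CICR")
})
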