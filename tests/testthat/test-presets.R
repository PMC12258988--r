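test_that("all figure panels with model presets ship and load", {
  names <- list_presets()
  expected <- c("fig1a", "fig1b", "fig2_ramp", "fig2_step", "fig2_nocan",
                "fig2_nocicr", "fig3c", "fig3d", "fig3e", "fig5c", "fig5d",
                "fig5e", "fig5f", "fig6c", "fig6d", "fig6e", "fig6f",
                "fig8d", "fig8e", "fig8f", "fig8g", "fig9a", "fig9b")
  expect_setequal(names, expected)
  for (nm in names) {
    ps <- load_preset(nm)
    expect_s3_class(ps$params, "mn_params")
    expect_true(nzchar(ps$expect), label = nm)
  }
  expect_error(load_preset("fig99"), "unknown preset")
})

test_that("config loading layers defaults, rejects unknown keys by name", {
  f <- tempfile(fileext = ".yaml")
  writeLines("{}", f)
  cfg <- load_config(f, quiet = TRUE)
  expect_equal(unclass(cfg$params), unclass(mn_params()))
  expect_null(cfg$program)
  yaml::write_yaml(list(g_CAN = 0.5), f)
  cfg <- load_config(f, quiet = TRUE)
  expect_equal(cfg$params$g_CAN, 0.5)
  q <- unclass(cfg$params); q$g_CAN <- 0
  expect_equal(q, unclass(mn_params()))
  yaml::write_yaml(list(k_CICR = 0.2), f)
  expect_error(load_config(f, quiet = TRUE), "k_CICR")
  yaml::write_yaml(list(g_wrong = 1), f)
  expect_error(load_config(f, quiet = TRUE), "g_wrong")
  # structured config with protocol yields a program
  yaml::write_yaml(list(params = list(g_CAN = 0.5),
                        protocol = list(type = "ramp", max_I = 3,
                                        phase_duration = 1000)), f)
  cfg <- load_config(f, quiet = TRUE)
  expect_s3_class(cfg$program, "current_program")
  expect_equal(total_duration(cfg$program), 2000)
  unlink(f)
})

test_that("fast presets reproduce their qualitative outcome tags", {
  for (nm in c("fig1a", "fig1b", "fig2_step", "fig9a", "fig9b")) {
    r <- run_preset(nm)
    expect_true(r$pass, label = sprintf("%s: got '%s', expected '%s'",
                                        nm, r$tag, r$expect))
  }
})

test_that("preset artifacts are written and byte-stable across reruns", {
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_preset("fig1a", out_dir = d1)
  r2 <- run_preset("fig1a", out_dir = d2)
  expect_true(file.exists(file.path(d1, "fig1a_trace.csv")))
  expect_true(file.exists(file.path(d1, "fig1a_result.json")))
  expect_identical(readLines(file.path(d1, "fig1a_trace.csv")),
                   readLines(file.path(d2, "fig1a_trace.csv")))
  expect_identical(readLines(file.path(d1, "fig1a_result.json")),
                   readLines(file.path(d2, "fig1a_result.json")))
  unlink(c(d1, d2), recursive = TRUE)
})
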