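# Packaged parameter sets, provenance tags, calibration harness.

test_that("default parameter sets carry complete provenance and published anchors", {
  for (nm in c("paper-qualitative-v1", "rnai-v1", "sequestration-v1")) {
    df <- as.data.frame(default_parameters(nm))
    expect_true(all(df$provenance %in%
      c("paper-printed", "literature-cited", "calibrated", "placeholder")))
    expect_false(any(df$provenance == "placeholder"),
                 info = paste("placeholders remaining in", nm))
    expect_true(all(df$value >= 0))
  }
  p <- default_parameters("paper-qualitative-v1")
  expect_equal(p$k1_Dicer$value, 10)
  expect_identical(p$k1_Dicer$units, "uM-1.s-1")
  expect_identical(p$k1_Dicer$provenance, "paper-printed")
  expect_equal(p$k1_RISC$value, 10)
  # antisense default is 1/8 of the sense rate
  expect_equal(p$Kf_Make_Orf0$value, p$Kf_Make_L1mRNA$value / 8)
  expect_error(default_parameters("no-such-set"), "unknown parameter set")
})

test_that("default sweep grids match the study design", {
  expect_equal(default_sweep_values("initial_L1mRNA"),
               c(0, 10, 100, 1000, 10000, 100000))
  expect_equal(default_sweep_values("Kf_Make_L1mRNA"),
               c(1e-4, 1e-3, 1e-2, 1e-1, 1))
  expect_equal(default_sweep_values("Kf_Make_Orf0"), c(0.001, 0.1))
  expect_error(default_sweep_values("nope"), "unknown sweep parameter")
})

test_that("calibration harness handles trivial and contradictory target sets", {
  out <- calibrate_defaults(NULL)
  expect_true(out$satisfied)
  expect_identical(param_hash(out$params), param_hash(default_parameters()))
  bad <- calibration_targets(rate_threshold = c(0.01, 0.1))
  out2 <- calibrate_defaults(bad, search_grid = list(Kf_RT = c(0.01, 0.1)))
  expect_false(out2$satisfied)
  expect_match(out2$trace$reason, "contradictory")
})

test_that("toy oracles carry their closed-form expectations", {
  # pure decay mean at t = 100 with k = 0.01: 1000 * e^-1
  net <- expand_rules(toy_model("pure_decay", k = 0.01, x0 = 1000))
  ode <- simulate_ode(net, stop_condition(t_end = 100, grid_dt = 100))
  expect_equal(species_series(ode, "X")[2], 1000 * exp(-1), tolerance = 1e-6)
  expect_error(toy_model("nonexistent"), "unknown toy model")
})
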