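# Growth classification, fate accounting, standalone sequestration.

.mk_traj <- function(time, x, status = "completed") {
  counts <- matrix(x, ncol = 1, dimnames = list(NULL, "L1DNA()@Nucleus"))
  structure(list(time = time, counts = counts,
                 tallies = matrix(0, length(time), 6,
                                  dimnames = list(NULL, c("rnase", "risc", "sg",
                                                          "mvb", "rt", "other"))),
                 rxn_count = numeric(0), status = status,
                 init_counts = x[1], species = data.frame(label = "L1DNA()@Nucleus")),
            class = "trajectory")
}

test_that("classify_growth labels synthetic trajectories per the explicit criterion", {
  tt <- seq(0, 10000, by = 10)
  expo <- .mk_traj(tt, 10 * exp(0.001 * tt))
  expect_identical(classify_growth(expo, "L1DNA")$regime, "exponential")
  const <- .mk_traj(tt, rep(100, length(tt)))
  expect_identical(classify_growth(const, "L1DNA")$regime, "static")
  # modest linear growth: above the static band, below the exponential slope
  lin <- .mk_traj(tt, 100 + tt / 200)
  expect_identical(classify_growth(lin, "L1DNA")$regime, "bounded")
  # a count-cap run is exponential regardless of slope
  capped <- .mk_traj(tt, rep(100, length(tt)), status = "count-cap")
  expect_identical(classify_growth(capped, "L1DNA")$regime, "exponential")
  expect_error(classify_growth(const, "NoSuchThing"), "unknown species")
  short <- .mk_traj(0:5, rep(1, 6))
  expect_error(classify_growth(short, "L1DNA"), "at least 10 grid points")
})

test_that("fate fractions always partition unity", {
  net <- expand_rules(build_sequestration_model(n_rna = 20000))
  tr <- simulate_ssa(net, 1, stop_condition(t_end = 10000, grid_dt = 10))
  rep1 <- fate_accounting(tr, molecule = "RNA", synthesis_rules = character())
  expect_equal(sum(rep1$fractions), 1, tolerance = 1e-9)
  expect_true(all(rep1$fractions >= 0 & rep1$fractions <= 1))
  # zero-length run: everything survives
  tr0 <- simulate_ssa(net, 1, stop_condition(t_end = 1e-6, grid_dt = 1e-6))
  rep0 <- fate_accounting(tr0, molecule = "RNA", synthesis_rules = character())
  expect_equal(unname(rep0$fractions[["surviving"]]), 1)
})

test_that("with translocation off, all degradation is cytoplasmic RNase", {
  p <- default_parameters("sequestration-v1")
  p <- set_param(p, "Kf_to_SG", 0)
  p <- set_param(p, "Kf_to_MVB", 0)
  res <- run_standalone_sequestration(20000, seeds = 1, parameters = p)
  fr <- res$mean_fractions
  expect_equal(unname(fr[["sg"]] + fr[["mvb"]]), 0)
  expect_equal(unname(fr[["rnase"]] + fr[["surviving"]]), 1, tolerance = 1e-9)
})

test_that("standalone sequestration: sequestered fraction is small at both loads", {
  for (n in c(20000, 60000)) {  # scaled-down versions of the published loads
    res <- run_standalone_sequestration(n, seeds = 1)
    fr <- res$mean_fractions
    seq_frac <- fr[["sg"]] + fr[["mvb"]]
    expect_lt(seq_frac, 0.1 * fr[["rnase"]])
    expect_gt(fr[["rnase"]], 0.9)
    expect_gt(seq_frac, 0)
  }
})

test_that("sweep variant machinery rewires rates and initial counts correctly", {
  v1 <- line1sim:::.sweep_variant(merged_net, "initial_L1mRNA", 500)
  expect_equal(v1$overrides$count, 500)
  v2 <- line1sim:::.sweep_variant(merged_net, "Kf_Make_L1mRNA", 0.08)
  pp <- v2$net$model$parameters
  expect_equal(pp$Kf_Make_L1mRNA$value, 0.08)
  expect_equal(pp$Kf_Make_Orf0$value, 0.01)  # antisense tracks sense at 1/8
  v3 <- line1sim:::.sweep_variant(merged_net, "Kf_Make_Orf0", 0.1)
  pp3 <- v3$net$model$parameters
  expect_equal(pp3$Kf_Make_Orf0$value, 0.1)
  expect_equal(pp3$Kf_Make_L1mRNA$value, 1)
})

test_that("majority vote resolves ties towards higher severity", {
  expect_identical(line1sim:::.majority_regime(c("static", "bounded")), "bounded")
  expect_identical(line1sim:::.majority_regime(c("static", "static", "bounded")),
                   "static")
  expect_identical(line1sim:::.majority_regime(rep("exponential", 3)), "exponential")
})

test_that("a reduced sweep produces coherent labels, threshold and tallies", {
  sp <- sweep_spec("Kf_Make_L1mRNA", values = c(1e-3, 1), seeds = 1:2,
                   stop = stop_condition(t_end = 1500, grid_dt = 10,
                                         total_cap = 2e5))
  res <- sweep_experiment(merged_net, sp)
  expect_equal(nrow(res$runs), 4)
  expect_identical(res$summary$regime[res$summary$value == 1e-3], "static")
  expect_identical(res$summary$regime[res$summary$value == 1], "exponential")
  expect_equal(res$threshold, 1)
  expect_true(all(res$runs$risc_events == 0))
  # severity is non-decreasing along the sweep values
  sev <- line1sim:::.SEVERITY[res$summary$regime]
  expect_true(all(diff(sev) >= 0))
})
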