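# Stochastic engine (next-reaction method), ODE integration, clamps,
# replicates.

test_that("birth-death stationary mean a/k is recovered over 20 seeds", {
  net <- expand_rules(toy_model("birth_death", a = 10, k = 0.1))
  means <- vapply(1:20, function(s) {
    tr <- simulate_ssa(net, s, stop_condition(t_end = 600, grid_dt = 1))
    mean(species_series(tr, "X")[tr$time > 200])
  }, numeric(1))
  # stationary law is Poisson(100); the CLT band on the seed-mean is wide
  # because time averages are autocorrelated (relaxation time 1/k = 10 s)
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 100), 3 * se + 1)
  # stationary variance ~ mean (Poisson): pooled sample check, loose band
  tr <- simulate_ssa(net, 99, stop_condition(t_end = 5000, grid_dt = 1))
  x <- species_series(tr, "X")[tr$time > 500]
  expect_gt(stats::var(x) / mean(x), 0.7)
  expect_lt(stats::var(x) / mean(x), 1.4)
})

test_that("pure decay matches the exponential mean", {
  net <- expand_rules(toy_model("pure_decay", k = 0.01, x0 = 1000))
  finals <- vapply(1:30, function(s) {
    tr <- simulate_ssa(net, s, stop_condition(t_end = 100, grid_dt = 10))
    species_series(tr, "X")[tr$time == 100]
  }, numeric(1))
  # X(100) ~ Binomial(1000, e^-1): mean 367.9, sd 15.3
  se <- sqrt(1000 * exp(-1) * (1 - exp(-1)) / 30)
  expect_lt(abs(mean(finals) - 1000 * exp(-1)), 3 * se)
})

test_that("zero-reaction network stays constant and completes", {
  m <- toy_model("pure_decay", x0 = 42)
  m$rules <- list()
  net <- expand_rules(m)
  tr <- simulate_ssa(net, 1, stop_condition(t_end = 100, grid_dt = 1))
  expect_identical(tr$status, "completed")
  expect_true(all(species_series(tr, "X") == 42))
  expect_equal(tr$n_events, 0)
})

test_that("identical (net, stop, seed) give identical trajectories", {
  net <- expand_rules(toy_model("birth_death"))
  st <- stop_condition(t_end = 300, grid_dt = 1)
  t1 <- simulate_ssa(net, 11, st)
  t2 <- simulate_ssa(net, 11, st)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$n_events, t2$n_events)
  t3 <- simulate_ssa(net, 12, st)
  expect_false(identical(t1$counts, t3$counts))
})

test_that("next-reaction and direct-method event distributions agree", {
  # 3-reaction network: birth, death, and binding (competing channels)
  m <- toy_model("two_site_binder", kon = 5e-4, koff = 0.05, nA = 40, nB = 60)
  net <- expand_rules(m)
  n <- 4000
  set.seed(4242)
  direct <- replicate(n, {
    ev <- direct_ssa_events(net, max_events = 1)
    c(ev$times[1], ev$types[1])
  })
  nrm <- vapply(seq_len(n), function(s) {
    ev <- nrm_first_event(net, seed = 100000 + s)
    c(ev$time, ev$type)
  }, numeric(2))
  ks <- suppressWarnings(stats::ks.test(direct[1, ], nrm[1, ]))
  expect_gt(ks$p.value, 0.01)
  # event-type distribution
  tab <- rbind(table(factor(direct[2, ], levels = seq_along(net$reactions))),
               table(factor(nrm[2, ], levels = seq_along(net$reactions))))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("ODE integration matches closed forms and zeroes clamped derivatives", {
  net <- expand_rules(toy_model("birth_death", a = 10, k = 0.1))
  tr <- simulate_ode(net, stop_condition(t_end = 100, grid_dt = 1))
  x <- species_series(tr, "X")
  expect_equal(x, 100 * (1 - exp(-0.1 * tr$time)), tolerance = 1e-6)
  # clamped species' derivative is identically zero
  netc <- clamp_species(net, "X", "Cell")
  netc <- set_initial(netc, initial_conditions(ic("X", "Cell", 5, clamped = TRUE)))
  trc <- simulate_ode(netc, stop_condition(t_end = 50, grid_dt = 1))
  expect_true(all(species_series(trc, "X") == 5))
})

test_that("SSA ensemble mean matches the ODE for a linear network", {
  net <- expand_rules(toy_model("birth_death", a = 20, k = 0.1))
  st <- stop_condition(t_end = 80, grid_dt = 2)
  reps <- run_replicates(net, 1:50, st)
  ode <- simulate_ode(net, st)
  xo <- species_series(ode, "X")
  m <- reps$summary$mean[, "X()@Cell"]
  se <- reps$summary$sd[, "X()@Cell"] / sqrt(50)
  sel <- reps$summary$time > 0
  expect_true(all(abs(m[sel] - xo[sel]) <= 3 * se[sel] + 1e-9))
})

test_that("run_replicates summarises correctly and is deterministic", {
  net <- expand_rules(toy_model("pure_decay", x0 = 200))
  st <- stop_condition(t_end = 50, grid_dt = 5)
  one <- run_replicates(net, 3, st)
  expect_equal(one$summary$mean[, 1], unname(one$trajectories[[1]]$counts[, 1]))
  r1 <- run_replicates(net, c(1, 2, 3), st)
  r2 <- run_replicates(net, c(1, 2, 3), st)
  expect_identical(r1$summary, r2$summary)
})

test_that("clamped species stay constant while their reactions keep firing", {
  net <- expand_rules(build_sequestration_model(n_rna = 5000))
  tr <- simulate_ssa(net, 3, stop_condition(t_end = 10000, grid_dt = 10))
  mov_free <- species_series(tr, "MOV10_ZAP", compartment = "Cytoplasm",
                             free_only = TRUE)
  expect_true(all(mov_free == 1000))
  # consumption from the clamped pool exceeds what 1000 copies would allow
  # if clamping a species with a consuming reaction did not replenish
  expect_gt(sum(tr$rxn_count[names(tr$rxn_count) == "mov10_bind"]), 0)
  # no clamps: state evolves freely (contract: apply_clamp of nothing)
  expect_identical(apply_clamp(net, list()), net)
})

test_that("early termination on count cap is graceful and recorded", {
  net <- expand_rules(toy_model("birth_death", a = 50, k = 1e-4))
  tr <- simulate_ssa(net, 1, stop_condition(t_end = 1e4, grid_dt = 10,
                                            total_cap = 2000))
  expect_identical(tr$status, "count-cap")
  expect_lt(tr$t_final, 1e4)
  # series is held at the last state after the cap
  x <- species_series(tr, "X")
  expect_equal(x[length(x)], x[sum(tr$time <= tr$t_final) + 1])
})

test_that("no species count ever goes negative in the merged model", {
  tr <- simulate_ssa(merged_net, 5,
                     stop_condition(t_end = 2000, grid_dt = 10),
                     overrides = initial_conditions(ic("L1mRNA", "Nucleus", 5000)))
  expect_true(all(tr$counts >= 0))
})

test_that("machinery totals are conserved along unclamped merged trajectories", {
  net <- set_initial(merged_net,
                     initial_conditions(ic("MOV10_Zap", "Cytoplasm", 1000,
                                           clamped = FALSE)))
  p <- set_param(net$model$parameters, "Kf_Make_L1mRNA", 0.05)
  net <- update_rates(net, p)
  tr <- simulate_ssa(net, 2, stop_condition(t_end = 1500, grid_dt = 10))
  for (mol in c("Exportin", "Dicer", "RISC", "MOV10_Zap")) {
    tot <- species_series(tr, mol)
    expect_true(all(tot == 1000), info = mol)
  }
})
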