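# Michaelis-Menten <-> elementary mass-action machinery.

test_that("mm_velocity has the hyperbolic closed-form identities", {
  s <- mm_spec(Vmax = 2, Km = 1, Et = 1)
  expect_equal(mm_velocity(s, 0), 0)
  expect_equal(mm_velocity(s, s$Km), s$Vmax / 2)
  # monotone approach to Vmax
  grid <- 10^seq(-2, 4, by = 0.5)
  v <- mm_velocity(s, grid)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < s$Vmax))
  expect_lt(s$Vmax - mm_velocity(s, 1e6), 1e-5)
  expect_error(mm_velocity(s, -1), "must be >= 0")
})

test_that("equilibrium conversion substitutes k2 = Vmax/Et and k-1 = k1*Km", {
  tr <- mm_to_mass_action(mm_spec(Vmax = 1, Km = 0.5, Et = 1), k1 = 10)
  expect_equal(tr$k1, 10)
  expect_equal(tr$k_minus1, 5)
  expect_equal(tr$k2, 1)
  tr2 <- mm_to_mass_action(mm_spec(Vmax = 2, Km = 3, Et = 4), k1 = 1)
  expect_equal(tr2$k2, 0.5)
  expect_equal(tr2$k_minus1, 3)
  expect_error(mm_to_mass_action(mm_spec(1, 1, 1), k1 = 0), "positive")
})

test_that("conversion round-trips exactly through the inverse relations", {
  for (vals in list(c(1.7, 0.8, 2.2, 10), c(0.03, 12, 0.5, 100),
                    c(5, 0.01, 1, 1))) {
    s <- mm_spec(Vmax = vals[1], Km = vals[2], Et = vals[3])
    tr <- mm_to_mass_action(s, k1 = vals[4])
    s2 <- mass_action_to_mm(tr, Et = vals[3])
    expect_identical(s2$Vmax, s$Vmax)
    expect_identical(s2$Km, s$Km)
  }
})

test_that("equilibrium validity flag uses the documented 0.1 ratio threshold", {
  expect_equal(equilibrium_validity(ma_triplet(10, 5, 1)),
               list(ratio = 0.2, flag = "warn"))
  expect_equal(equilibrium_validity(ma_triplet(10, 100, 1)),
               list(ratio = 0.01, flag = "valid"))
  tr <- ma_triplet(10, 5, 1); tr$k_minus1 <- 0
  expect_error(equilibrium_validity(tr), "undefined")
})

test_that("propensity conversion follows the volume scaling laws", {
  expect_equal(macroscopic_to_propensity(0.1, 1, 2e-12), 0.1)
  expect_equal(macroscopic_to_propensity(0.1, 1, 1e-15), 0.1)
  v <- 2e-12
  expect_equal(macroscopic_to_propensity(10, 2, v),
               10 / (6.02214076e23 * v * 1e-6))
  # doubling the volume halves a bimolecular propensity, doubles a source
  expect_equal(macroscopic_to_propensity(10, 2, 2 * v),
               macroscopic_to_propensity(10, 2, v) / 2)
  expect_equal(macroscopic_to_propensity(3, 0, 2 * v),
               macroscopic_to_propensity(3, 0, v) * 2)
  # round trip
  for (ord in 0:2) {
    c0 <- macroscopic_to_propensity(7.3, ord, v)
    expect_equal(propensity_to_macroscopic(c0, ord, v), 7.3)
  }
  expect_error(macroscopic_to_propensity(1, 3, v), "order")
  expect_error(macroscopic_to_propensity(1, 1, -1), "volume")
})

test_that("mass-action triplet reproduces the MM velocity within 5% in the validity regime", {
  vol <- 1e-15
  sc <- uM_scale(vol)
  Km <- 1            # uM
  Et_uM <- 50 / sc   # 50 molecules
  k2 <- 0.1
  tr <- mm_to_mass_action(mm_spec(Vmax = k2 * Et_uM, Km = Km, Et = Et_uM), k1 = 10)
  expect_equal(equilibrium_validity(tr)$flag, "valid")
  for (mult in c(0.01, 0.1, 1, 10, 100)) {
    S0 <- round(mult * Km * sc)
    net <- expand_rules(toy_model("mm_enzyme", triplet = tr, Et = 50, S0 = S0,
                                  volume = vol))
    # clamp the substrate so the measured velocity is the initial velocity
    # the hyperbolic law describes (no depletion at low S)
    net <- set_initial(net, initial_conditions(ic("S", "Cell", S0,
                                                  clamped = TRUE)))
    tro <- simulate_ode(net, stop_condition(t_end = 4, grid_dt = 0.5),
                        rel_tol = 1e-10, abs_tol = 1e-12)
    p <- species_series(tro, "P", free_only = TRUE)
    # velocity after the fast binding transient has relaxed
    v_sim <- (p[which(tro$time == 4)] - p[which(tro$time == 2)]) / 2
    v_mm <- S0 * (k2 * 50) / (S0 + Km * sc)  # molecule-unit closed form
    expect_lt(abs(v_sim - v_mm) / v_mm, 0.05)
  }
})

test_that("velocity curves are invariant under k1 scaling with k-1 scaled by Km", {
  # deep inside the validity regime the quasi-equilibrium kinetics depend
  # only on the ratio k-1/k1, so scaling both leaves the product curve
  # unchanged to solver precision
  vol <- 1e-15
  sc <- uM_scale(vol)
  Km <- 1
  k2 <- 1e-5
  velocity <- function(k1, mult) {
    tr <- ma_triplet(k1 = k1, k_minus1 = k1 * Km, k2 = k2)
    S0 <- round(mult * Km * sc)
    net <- expand_rules(toy_model("mm_enzyme", triplet = tr, Et = 50,
                                  S0 = S0, volume = vol))
    tro <- simulate_ode(net, stop_condition(t_end = 50, grid_dt = 10),
                        rel_tol = 1e-10, abs_tol = 1e-14)
    p <- species_series(tro, "P", free_only = TRUE)
    # post-transient velocity (the binding transient lasts well under 1 s)
    (p[which(tro$time == 50)] - p[which(tro$time == 10)]) / 40
  }
  for (mult in c(0.5, 2)) {
    v10 <- velocity(10, mult)
    v100 <- velocity(100, mult)
    expect_lt(abs(v100 - v10) / v10, 1e-5)
  }
})
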