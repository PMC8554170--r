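# Model builders and structural validation.

test_that("all four builders produce models that validate cleanly", {
  for (m in list(build_rnai_model(), build_sequestration_model(),
                 build_lifecycle_model(), merged_model)) {
    expect_length(validate_model(m), 0)
  }
})

test_that("merged model declares exactly 13 molecule types and 36 rules", {
  expect_length(merged_model$molecule_types, 13)
  expect_length(merged_model$rules, 36)
  expect_setequal(vapply(merged_model$compartments, `[[`, character(1), "name"),
                  c("Nucleus", "Cytoplasm", "Stress_Granule",
                    "MultiVesicularBodies"))
  # every rule documented in the provenance table
  expect_identical(merged_model$rule_provenance$rule,
                   vapply(merged_model$rules, `[[`, character(1), "name"))
})

test_that("LINE-1 mRNA carries the 4-site structure with equivalent ORF1p sites", {
  ty <- merged_model$molecule_types[[
    match("L1mRNA", vapply(merged_model$molecule_types, `[[`, character(1), "name"))]]
  expect_setequal(names(ty$sites), c("orf1_a", "orf1_b", "orf2", "orf0"))
  expect_identical(ty$equivalent, list(c("orf1_a", "orf1_b")))
  expect_identical(ty$sites$orf1_a, "ORF1p")
  expect_identical(ty$sites$orf1_b, "ORF1p")
  expect_identical(ty$sites$orf2, "ORF2p")
})

test_that("merged default initial conditions match the published table", {
  init <- merged_model$initial
  get <- function(mol) init[init$molecule == mol, ]
  expect_equal(get("RISC")$count, 1000)
  expect_false(get("RISC")$clamped)
  expect_equal(get("MOV10_Zap")$count, 1000)
  expect_true(get("MOV10_Zap")$clamped)
  expect_equal(get("L1mRNA")$count, 0)
  expect_equal(get("L1DNA")$count, 100)
  expect_identical(get("L1DNA")$compartment, "Nucleus")
  expect_equal(get("Exportin")$count, 1000)
  expect_identical(get("Exportin")$compartment, "Nucleus")
  expect_equal(get("Dicer")$count, 1000)
  # all species not listed start at zero
  expect_true(all(init$count[!init$molecule %in%
    c("RISC", "MOV10_Zap", "L1DNA", "Exportin", "Dicer")] == 0))
})

test_that("Dicer and RISC enzymatic steps are 3-reaction mass-action triplets", {
  rules <- vapply(merged_model$rules, `[[`, character(1), "name")
  expect_true(all(c("dicer_bind", "dicer_unbind", "dicer_cleave") %in% rules))
  expect_true(all(c("risc_target_bind", "risc_target_unbind", "risc_cleave") %in% rules))
  # bind steps are bimolecular, unbind/catalyze unimolecular
  get_rule <- function(n) merged_model$rules[[match(n, rules)]]
  expect_length(get_rule("dicer_bind")$reactants, 2)
  expect_length(get_rule("dicer_unbind")$reactants, 1)
  expect_length(get_rule("dicer_cleave")$reactants, 1)
  expect_length(get_rule("risc_target_bind")$reactants, 2)
})

test_that("every rule is elementary mass action with at most 2 reactant patterns", {
  for (m in list(build_rnai_model(), build_sequestration_model(),
                 build_lifecycle_model(), merged_model)) {
    expect_true(all(vapply(m$rules, function(r) length(r$reactants) <= 2,
                           logical(1))))
  }
})

test_that("validation reports dangling constants and negative counts as data", {
  m <- build_sequestration_model(n_rna = 100)
  m$rules[[1]]$rate <- "no_such_constant"
  errs <- validate_model(m)
  expect_length(grep("no_such_constant", errs), 1)

  m2 <- build_sequestration_model(n_rna = 100)
  m2$initial$count[1] <- -5
  errs2 <- validate_model(m2)
  expect_length(grep("not a non-negative integer", errs2), 1)

  # unit/order mismatch: bimolecular rule pointed at a s-1 constant
  m3 <- build_sequestration_model(n_rna = 100)
  m3$rules[[1]]$rate <- "Kf_to_SG"  # s-1 constant on a 2-reactant rule
  expect_length(grep("order 2 but constant", validate_model(m3)), 1)
})

test_that("pattern bond endpoints must be mutually consistent", {
  m <- build_sequestration_model(n_rna = 100)
  # break one endpoint of the translocation pattern's bond
  m$rules[[2]]$reactants[[1]]$molecules[[2]]$sites$mov <- 2
  errs <- validate_model(m)
  expect_true(any(grepl("endpoints", errs)))
})

test_that("reverse transcription conserves ORF proteins and adds exactly one DNA", {
  net <- merged_net
  rt_idx <- which(vapply(net$reactions, `[[`, character(1), "rule") ==
                    "reverse_transcription")
  expect_gt(length(rt_idx), 0)
  occ_dna <- line1sim:::.mol_occurrence(net$species$label, "L1DNA")
  for (mol in c("ORF1p", "ORF2p", "L1mRNA")) {
    occ <- line1sim:::.mol_occurrence(net$species$label, mol)
    for (i in rt_idx) {
      rx <- net$reactions[[i]]
      expect_equal(sum(occ[rx$products]), sum(occ[rx$reactants]),
                   info = paste("conservation of", mol))
    }
  }
  for (i in rt_idx) {
    rx <- net$reactions[[i]]
    expect_equal(sum(occ_dna[rx$products]) - sum(occ_dna[rx$reactants]), 1)
  }
})

test_that("no rule creates or destroys the finite machinery pools", {
  # Exportin, Dicer, RISC, MOV10_Zap take part in binding and transport only
  for (mol in c("Exportin", "Dicer", "RISC", "MOV10_Zap")) {
    occ <- line1sim:::.mol_occurrence(merged_net$species$label, mol)
    for (rx in merged_net$reactions) {
      expect_equal(sum(occ[rx$products]), sum(occ[rx$reactants]),
                   info = paste(rx$rule, mol))
    }
  }
})

test_that("lifecycle model has no DNA source when transcription is silenced", {
  p <- set_param(build_lifecycle_model()$parameters, "Kf_Make_L1mRNA", 0)
  p <- set_param(p, "Kf_Make_Orf0", 0)
  m <- build_lifecycle_model(parameters = p)
  net <- expand_rules(m)
  tr <- simulate_ssa(net, 7, stop_condition(t_end = 2000, grid_dt = 10))
  expect_true(all(species_series(tr, "L1DNA") == 100))
  expect_equal(tr$n_events, 0)
})

test_that("an mRNA with ORF2p but no ORF1p has no enabled nuclear-import reaction", {
  labs <- merged_net$species$label
  # cytoplasmic species: transcript + ORF2p only
  sidx <- match("L1mRNA(orf1_a,orf1_b,orf2!1,orf0).ORF2p(rna!1)@Cytoplasm", labs)
  expect_false(is.na(sidx))
  imp <- vapply(merged_net$reactions, function(rx)
    rx$rule == "rnp_import" && sidx %in% rx$reactants, logical(1))
  expect_false(any(imp))
  # but a transcript with one ORF1p and one ORF2p is importable
  sidx2 <- match("L1mRNA(orf1_a!1,orf1_b,orf2!2,orf0).ORF1p(rna!1).ORF2p(rna!2)@Cytoplasm",
                 labs)
  expect_false(is.na(sidx2))
  imp2 <- vapply(merged_net$reactions, function(rx)
    rx$rule == "rnp_import" && sidx2 %in% rx$reactants, logical(1))
  expect_true(any(imp2))
})
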