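# Pattern matching, canonicalisation and network expansion.

test_that("two-site binder expands to the hand-enumerated network", {
  net <- expand_rules(toy_model("two_site_binder", kon = 1e-3, koff = 0.1))
  expect_setequal(net$species$label,
                  c("A(s1,s2)@Cell", "B(a)@Cell", "A(s1!1,s2).B(a!1)@Cell",
                    "A(s1!1,s2!2).B(a!1).B(a!2)@Cell"))
  tab <- network_comparable(net)$reactions
  expect_equal(nrow(tab), 4)  # 2 binding + 2 unbinding
  # statistical factors: 2 for binding to the doubly-free pair, 1 for the
  # second binding; 1 for unbinding the single occupant, 2 for the pair
  bind <- tab[tab$rule == "bind", ]
  unbind <- tab[tab$rule == "unbind", ]
  expect_setequal(bind$factor, c(2, 1))
  expect_setequal(unbind$factor, c(1, 2))
  b2 <- bind[grepl("^A\\(s1,s2\\)", bind$reactants), ]
  expect_equal(b2$factor, 2)
})

test_that("structurally identical complexes canonicalise to the same label", {
  m <- toy_model("two_site_binder")
  # build A bound through s1 vs through s2: same canonical label
  a <- free_species("A", "Cell", m)
  b <- free_species("B", "Cell", m)
  v1 <- list(molecules = list(
    list(type = "A", sites = c(s1 = 1L, s2 = 0L)),
    list(type = "B", sites = c(a = 1L))), compartment = "Cell")
  v2 <- list(molecules = list(
    list(type = "B", sites = c(a = 9L)),
    list(type = "A", sites = c(s1 = 0L, s2 = 9L))), compartment = "Cell")
  expect_identical(canonical_label(v1, m), canonical_label(v2, m))
  expect_false(canonical_label(v1, m) == canonical_label(a, m))
  expect_identical(canonical_label(b, m), "B(a)@Cell")
})

test_that("match_pattern collapses symmetric embeddings into the statistical factor", {
  m <- build_merged_model()
  sp <- free_species("L1mRNA", "Cytoplasm", m)
  # >=1 ORF1p site free on a doubly-free transcript: one embedding, factor 2
  pat <- complex_pattern(pmol("L1mRNA", orf1_a = 0), compartment = "Cytoplasm")
  em <- match_pattern(pat, sp, m)
  expect_length(em, 1)
  expect_equal(em[[1]]$factor, 2)
  # compartment-constrained pattern does not match elsewhere
  pat_nuc <- complex_pattern(pmol("L1mRNA", orf1_a = 0), compartment = "Nucleus")
  expect_length(match_pattern(pat_nuc, sp, m), 0)
  # fully specified pattern against the identical species: exactly 1 embedding
  pat_full <- complex_pattern(
    pmol("L1mRNA", orf1_a = 0, orf1_b = 0, orf2 = 0, orf0 = 0),
    compartment = "Cytoplasm")
  em_full <- match_pattern(pat_full, sp, m)
  expect_length(em_full, 1)
  expect_equal(em_full[[1]]$factor, 1)
})

test_that("model with no rules expands to the seed species and zero reactions", {
  m <- toy_model("birth_death")
  m$rules <- list()
  net <- expand_rules(m)
  expect_equal(nrow(net$species), 1)
  expect_length(net$reactions, 0)
  s <- network_summary(net)
  expect_equal(s$n_reactions, 0)
})

test_that("expansion equals the brute-force oracle on toy models", {
  toys <- list(
    toy_model("birth_death"),
    toy_model("pure_decay"),
    toy_model("two_site_binder"),
    toy_model("mm_enzyme"))
  for (m in toys) {
    got <- network_comparable(expand_rules(m))
    want <- brute_force_expand(m)
    expect_identical(got$species, want$species, info = m$name)
    expect_equal(got$reactions, want$reactions, info = m$name)
  }
})

test_that("expansion equals the brute-force oracle on the sequestration model", {
  m <- build_sequestration_model(n_rna = 10)
  got <- network_comparable(expand_rules(m))
  want <- brute_force_expand(m)
  expect_identical(got$species, want$species)
  expect_equal(got$reactions, want$reactions)
})

test_that("expansion is deterministic", {
  n1 <- expand_rules(build_rnai_model())
  n2 <- expand_rules(build_rnai_model())
  expect_identical(n1$species, n2$species)
  expect_identical(reaction_table(n1), reaction_table(n2))
})

test_that("LINE-1 mRNA internal states stay within the 2^4 site bound per compartment", {
  labs <- merged_net$species$label
  occ <- line1sim:::.mol_occurrence(labs, "L1mRNA")
  # internal state = bound/unbound pattern over the 4 sites, read off the
  # canonical label of the transcript molecule
  state_of <- function(lab) {
    body <- regmatches(lab, regexpr("L1mRNA\\([^)]*\\)", lab))
    sites <- strsplit(sub("^L1mRNA\\(", "", sub("\\)$", "", body)), ",")[[1]]
    paste(grepl("!", sites) + 0, collapse = "")
  }
  for (comp in c("Nucleus", "Cytoplasm", "Stress_Granule", "MultiVesicularBodies")) {
    sel <- occ > 0 & grepl(paste0("@", comp, "$"), labs)
    n_states <- length(unique(vapply(labs[sel], state_of, character(1))))
    expect_lte(n_states, 16)
  }
  # constraint pruning: Dicer never loads an ORF-protein-decorated duplex
  # (proteins may bind after loading, but every dicer_bind reactant duplex
  # has all ORF sites free)
  for (rx in merged_net$reactions) {
    if (rx$rule != "dicer_bind") next
    duplex <- labs[rx$reactants[grepl("L1mRNA", labs[rx$reactants])]]
    expect_false(grepl("ORF1p|ORF2p", duplex), info = duplex)
  }
})

test_that("runaway rule sets hit the species cap with the offending rule named", {
  m <- toy_model("birth_death")
  # polymer-like growth: every X spawns a distinguishable chain via bonds
  m$molecule_types <- list(molecule_type("X", sites = list(s = "X", t = "X"),
                                         compartments = "Cell"))
  m$rules <- list(reaction_rule("chain",
    list(complex_pattern(pmol("X", s = 0), compartment = "Cell"),
         complex_pattern(pmol("X", t = 0), compartment = "Cell")),
    "k", ops = list(list(op = "bind", a = c(1, 1, "s"), b = c(2, 1, "t")))))
  m$parameters <- parameter_set(k = param(1, "molec-1.s-1", "calibrated"))
  expect_error(expand_rules(m, max_species = 20), "species cap.*chain")
})

test_that("mass audit: only declared synthesis/degradation rules change molecule totals", {
  synth <- c("make_l1_mrna", "make_orf0", "translate_orf1", "translate_orf2",
             "reverse_transcription", "dicer_cleave", "sirna_separation",
             "exosome_packaging")
  degr <- c("rnase_l1_mrna", "orf0_decay", "orf1_degradation",
            "orf2_degradation", "risc_cleave", "passenger_decay",
            "sg_degradation", "dicer_cleave", "sirna_separation")
  mols <- vapply(merged_model$molecule_types, `[[`, character(1), "name")
  occ <- sapply(mols, function(mm)
    line1sim:::.mol_occurrence(merged_net$species$label, mm))
  for (rx in merged_net$reactions) {
    delta <- colSums(occ[rx$products, , drop = FALSE]) -
      colSums(occ[rx$reactants, , drop = FALSE])
    if (!rx$rule %in% c(synth, degr)) {
      expect_true(all(delta == 0), info = rx$rule)
    }
  }
})
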