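# Builders for the three sub-models (RNA interference, stress-granule /
# multivesicular-body sequestration, LINE-1 life cycle) and the merged
# 13-molecule-type / 36-rule model. The supplementary rule inventory of the
# original study is not public; this reconstruction follows the published
# reaction diagrams and prose, and every rule carries a provenance note in
# the merged model's `rule_provenance` table.

.comp_list <- function(names) {
  vols <- default_volumes()
  lapply(names, function(n) compartment(n, vols[[n]]))
}

#' Build the standalone RNA-interference model
#'
#' Nucleus + cytoplasm. Messenger RNA is exported by mass action; double
#' stranded RNA (the sense/antisense duplex) is ferried out by Exportin,
#' released in the cytoplasm, and diced into single-stranded siRNA that loads
#' RISC; loaded RISC binds and cleaves complementary mRNA catalytically
#' (the guide strand is retained). Free cytoplasmic mRNA is also degraded by
#' background RNase. The Dicer and RISC enzymatic steps are each elementary
#' bind / unbind / catalyze mass-action triplets obtained from
#' Michaelis-Menten constants via [mm_to_mass_action()].
#'
#' @param parameters A [parameter_set()] (default
#'   `default_parameters("rnai-v1")`).
#' @param initial Optional [initial_conditions()] replacing the defaults
#'   (Exportin 1000 nuclear, Dicer 1000, RISC 1000 cytoplasmic, mRNA and
#'   dsRNA 1000 nuclear).
#' @return A validated [model_definition()].
#' @export
build_rnai_model <- function(parameters = default_parameters("rnai-v1"),
                             initial = NULL) {
  Nuc <- "Nucleus"; Cyt <- "Cytoplasm"
  types <- list(
    molecule_type("mRNA", sites = list(risc = "RISC"), compartments = c(Nuc, Cyt)),
    molecule_type("dsRNA", sites = list(carrier = c("Exportin", "Dicer")),
                  compartments = c(Nuc, Cyt)),
    molecule_type("Exportin", sites = list(cargo = "dsRNA"), compartments = c(Nuc, Cyt)),
    molecule_type("Dicer", sites = list(sub = "dsRNA"), compartments = Cyt),
    molecule_type("ssRNA", sites = list(risc = "RISC"), compartments = Cyt),
    molecule_type("RISC", sites = list(guide = "ssRNA", target = "mRNA"),
                  compartments = Cyt))
  rules <- list(
    reaction_rule("mrna_export",
      list(complex_pattern(pmol("mRNA", risc = 0), compartment = Nuc)),
      "Kf_mRNA_export", ops = list(list(op = "transport", to = Cyt))),
    reaction_rule("exportin_binds_dsrna",
      list(complex_pattern(pmol("dsRNA", carrier = 0), compartment = Nuc),
           complex_pattern(pmol("Exportin", cargo = 0), compartment = Nuc)),
      "Kf_Exp_bind",
      ops = list(list(op = "bind", a = c(1, 1, "carrier"), b = c(2, 1, "cargo")))),
    reaction_rule("dsrna_complex_export",
      list(complex_pattern(pmol("dsRNA", carrier = 1), pmol("Exportin", cargo = 1),
                           compartment = Nuc)),
      "Kf_dsRNA_export", ops = list(list(op = "transport", to = Cyt))),
    reaction_rule("exportin_release",
      list(complex_pattern(pmol("dsRNA", carrier = 1), pmol("Exportin", cargo = 1),
                           compartment = Cyt)),
      "Kr_Exp", ops = list(list(op = "unbind", a = c(1, 1, "carrier")))),
    reaction_rule("exportin_import",
      list(complex_pattern(pmol("Exportin", cargo = 0), compartment = Cyt)),
      "Kf_Exp_import", ops = list(list(op = "transport", to = Nuc))),
    reaction_rule("dicer_bind",
      list(complex_pattern(pmol("Dicer", sub = 0), compartment = Cyt),
           complex_pattern(pmol("dsRNA", carrier = 0), compartment = Cyt)),
      "k1_Dicer",
      ops = list(list(op = "bind", a = c(1, 1, "sub"), b = c(2, 1, "carrier")))),
    reaction_rule("dicer_unbind",
      list(complex_pattern(pmol("Dicer", sub = 1), pmol("dsRNA", carrier = 1),
                           compartment = Cyt)),
      "km1_Dicer", ops = list(list(op = "unbind", a = c(1, 1, "sub")))),
    reaction_rule("dicer_cleave",
      list(complex_pattern(pmol("Dicer", sub = 1), pmol("dsRNA", carrier = 1),
                           compartment = Cyt)),
      "k2_Dicer",
      ops = list(list(op = "destroy", target = c(1, 2)),
                 list(op = "create", type = "ssRNA"))),
    reaction_rule("risc_load",
      list(complex_pattern(pmol("RISC", guide = 0), compartment = Cyt),
           complex_pattern(pmol("ssRNA", risc = 0), compartment = Cyt)),
      "Kf_RISC_load",
      ops = list(list(op = "bind", a = c(1, 1, "guide"), b = c(2, 1, "risc")))),
    reaction_rule("risc_target_bind",
      list(complex_pattern(pmol("RISC", guide = "+", target = 0), compartment = Cyt),
           complex_pattern(pmol("mRNA", risc = 0), compartment = Cyt)),
      "k1_RISC",
      ops = list(list(op = "bind", a = c(1, 1, "target"), b = c(2, 1, "risc")))),
    reaction_rule("risc_target_unbind",
      list(complex_pattern(pmol("RISC", target = 1), pmol("mRNA", risc = 1),
                           compartment = Cyt)),
      "km1_RISC", ops = list(list(op = "unbind", a = c(1, 1, "target")))),
    reaction_rule("risc_cleave",
      list(complex_pattern(pmol("RISC", guide = "+", target = 1),
                           pmol("mRNA", risc = 1), compartment = Cyt)),
      "k2_RISC", ops = list(list(op = "destroy", target = c(1, 2))),
      pathway = "risc"),
    reaction_rule("rnase_mrna",
      list(complex_pattern(pmol("mRNA", risc = 0), compartment = Cyt)),
      "Kf_RNase", ops = list(list(op = "destroy", target = c(1, 1))),
      pathway = "rnase"))
  if (is.null(initial)) {
    initial <- initial_conditions(
      ic("mRNA", Nuc, 1000), ic("dsRNA", Nuc, 1000),
      ic("Exportin", Nuc, 1000), ic("Dicer", Cyt, 1000), ic("RISC", Cyt, 1000))
  }
  model_definition("rnai", .comp_list(c(Nuc, Cyt)), types, rules,
                   parameters, initial)
}

#' Build the standalone sequestration model
#'
#' Cytoplasm, multivesicular bodies and stress granules; two molecules only.
#' MOV10_ZAP (a lumped placeholder for the MOV10 / ZAP / SAMHD1 localisation
#' machinery) binds cytoplasmic RNA; the bound complex translocates to either
#' compartment; RNA is degraded inside stress granules; free cytoplasmic RNA
#' is degraded by background RNase. MOV10_ZAP is clamped by default.
#'
#' @param parameters A [parameter_set()] (default
#'   `default_parameters("sequestration-v1")`).
#' @param n_rna Initial cytoplasmic RNA count (default 100000).
#' @param clamp_mov10 Clamp the free MOV10_ZAP pool (default TRUE).
#' @return A validated [model_definition()].
#' @export
build_sequestration_model <- function(parameters = default_parameters("sequestration-v1"),
                                      n_rna = 100000, clamp_mov10 = TRUE) {
  Cyt <- "Cytoplasm"; MVB <- "MultiVesicularBodies"; SG <- "Stress_Granule"
  types <- list(
    molecule_type("RNA", sites = list(mov = "MOV10_ZAP"),
                  compartments = c(Cyt, MVB, SG)),
    molecule_type("MOV10_ZAP", sites = list(rna = "RNA"),
                  compartments = c(Cyt, MVB, SG)))
  rules <- list(
    reaction_rule("mov10_bind",
      list(complex_pattern(pmol("MOV10_ZAP", rna = 0), compartment = Cyt),
           complex_pattern(pmol("RNA", mov = 0), compartment = Cyt)),
      "Kf_Mov10_RNA_bind",
      ops = list(list(op = "bind", a = c(1, 1, "rna"), b = c(2, 1, "mov")))),
    reaction_rule("rnp_to_sg",
      list(complex_pattern(pmol("MOV10_ZAP", rna = 1), pmol("RNA", mov = 1),
                           compartment = Cyt)),
      "Kf_to_SG", ops = list(list(op = "transport", to = SG)), pathway = "sg"),
    reaction_rule("rnp_to_mvb",
      list(complex_pattern(pmol("MOV10_ZAP", rna = 1), pmol("RNA", mov = 1),
                           compartment = Cyt)),
      "Kf_to_MVB", ops = list(list(op = "transport", to = MVB)), pathway = "mvb"),
    reaction_rule("sg_degradation",
      list(complex_pattern(pmol("MOV10_ZAP", rna = 1), pmol("RNA", mov = 1),
                           compartment = SG)),
      "Kf_SG_deg", ops = list(list(op = "destroy", target = c(1, 2)))),
    reaction_rule("rnase_rna",
      list(complex_pattern(pmol("RNA", mov = 0), compartment = Cyt)),
      "Kf_RNase_RNA", ops = list(list(op = "destroy", target = c(1, 1))),
      pathway = "rnase"))
  initial <- initial_conditions(
    ic("RNA", Cyt, n_rna),
    ic("MOV10_ZAP", Cyt, 1000, clamped = clamp_mov10))
  model_definition("sequestration", .comp_list(c(Cyt, MVB, SG)), types, rules,
                   parameters, initial)
}

# site-graph L1mRNA type shared by the life-cycle and merged builders
.l1mrna_type <- function(orf0_partners, compartments) {
  molecule_type("L1mRNA",
                sites = list(orf1_a = "ORF1p", orf1_b = "ORF1p",
                             orf2 = "ORF2p", orf0 = orf0_partners),
                equivalent = list(c("orf1_a", "orf1_b")),
                compartments = compartments)
}

# the life-cycle rules shared verbatim by the merged model. `Nuc`/`Cyt`
# literals kept local for readability.
.lifecycle_core_rules <- function() {
  Nuc <- "Nucleus"; Cyt <- "Cytoplasm"
  naked <- function(comp) complex_pattern(
    pmol("L1mRNA", orf1_a = 0, orf1_b = 0, orf2 = 0, orf0 = 0),
    compartment = comp)
  list(
    reaction_rule("make_l1_mrna",
      list(complex_pattern(pmol("L1DNA"), compartment = Nuc)),
      "Kf_Make_L1mRNA", ops = list(list(op = "create", type = "L1mRNA"))),
    reaction_rule("make_orf0",
      list(complex_pattern(pmol("L1DNA"), compartment = Nuc)),
      "Kf_Make_Orf0", ops = list(list(op = "create", type = "Orf0_mRNA"))),
    reaction_rule("duplex_formation",
      list(naked(Nuc),
           complex_pattern(pmol("Orf0_mRNA", sense = 0), compartment = Nuc)),
      "Kf_duplex",
      ops = list(list(op = "bind", a = c(1, 1, "orf0"), b = c(2, 1, "sense")))),
    reaction_rule("l1_mrna_export",
      list(naked(Nuc)),
      "Kf_L1mRNA_export", ops = list(list(op = "transport", to = Cyt))),
    reaction_rule("translate_orf1",
      list(naked(Cyt)),
      "Kf_translate_Orf1", ops = list(list(op = "create", type = "ORF1p"))),
    reaction_rule("translate_orf2",
      list(naked(Cyt)),
      "Kf_translate_Orf2", ops = list(list(op = "create", type = "ORF2p"))),
    reaction_rule("orf1_bind",
      list(complex_pattern(pmol("ORF1p", rna = 0), compartment = Cyt),
           complex_pattern(pmol("L1mRNA", orf1_a = 0), compartment = Cyt)),
      "Kf_Orf1_bind",
      ops = list(list(op = "bind", a = c(1, 1, "rna"), b = c(2, 1, "orf1_a")))),
    reaction_rule("orf1_unbind",
      list(complex_pattern(pmol("L1mRNA", orf1_a = 1), pmol("ORF1p", rna = 1),
                           compartment = Cyt)),
      "Kr_Orf1", ops = list(list(op = "unbind", a = c(1, 2, "rna")))),
    reaction_rule("orf2_bind",
      list(complex_pattern(pmol("ORF2p", rna = 0), compartment = Cyt),
           complex_pattern(pmol("L1mRNA", orf2 = 0), compartment = Cyt)),
      "Kf_Orf2_bind",
      ops = list(list(op = "bind", a = c(1, 1, "rna"), b = c(2, 1, "orf2")))),
    reaction_rule("orf2_unbind",
      list(complex_pattern(pmol("L1mRNA", orf2 = 1), pmol("ORF2p", rna = 1),
                           compartment = Cyt)),
      "Kr_Orf2", ops = list(list(op = "unbind", a = c(1, 2, "rna")))),
    # import is gated: at least one ORF1p and the ORF2p site occupied
    reaction_rule("rnp_import",
      list(complex_pattern(pmol("L1mRNA", orf1_a = "+", orf2 = "+", orf0 = 0),
                           compartment = Cyt)),
      "Kf_RNP_import", ops = list(list(op = "transport", to = Nuc))),
    # reverse transcription: one new genomic copy, complete dissociation
    reaction_rule("reverse_transcription",
      list(complex_pattern(pmol("L1mRNA", orf1_a = "+", orf2 = "+", orf0 = 0),
                           compartment = Nuc)),
      "Kf_RT",
      ops = list(list(op = "dissolve"),
                 list(op = "create", type = "L1DNA")),
      pathway = "rt"),
    reaction_rule("orf1_export",
      list(complex_pattern(pmol("ORF1p", rna = 0), compartment = Nuc)),
      "Kf_Orf1_export", ops = list(list(op = "transport", to = Cyt))),
    reaction_rule("orf2_export",
      list(complex_pattern(pmol("ORF2p", rna = 0), compartment = Nuc)),
      "Kf_Orf2_export", ops = list(list(op = "transport", to = Cyt))),
    reaction_rule("orf1_degradation",
      list(complex_pattern(pmol("ORF1p", rna = 0), compartment = Cyt)),
      "Kf_Orf1_deg", ops = list(list(op = "destroy", target = c(1, 1)))),
    reaction_rule("orf2_degradation",
      list(complex_pattern(pmol("ORF2p", rna = 0), compartment = Cyt)),
      "Kf_Orf2_deg", ops = list(list(op = "destroy", target = c(1, 1)))),
    reaction_rule("rnase_l1_mrna",
      list(naked(Cyt)),
      "Kf_RNase_L1", ops = list(list(op = "destroy", target = c(1, 1))),
      pathway = "rnase"),
    reaction_rule("orf0_decay",
      list(complex_pattern(pmol("Orf0_mRNA", sense = 0), compartment = Nuc)),
      "Kf_Orf0_decay", ops = list(list(op = "destroy", target = c(1, 1))))
  )
}

#' Build the standalone LINE-1 life-cycle model
#'
#' Nucleus + cytoplasm. Genomic LINE-1 DNA transcribes both the sense
#' transcript and the antisense ORF0 transcript; the two can anneal into a
#' duplex in the nucleus (here simply exported and degraded, standing in for
#' the RNA-interference path of the merged model). Free cytoplasmic
#' transcript is translated into ORF1p and ORF2p, which bind the
#' transcript's sites in the cytoplasm only; a ribonucleoprotein carrying at
#' least one ORF1p and one ORF2p may be imported into the nucleus, where
#' reverse transcription creates one new genomic copy and the particle
#' completely dissociates. The preserved transcript is re-exported; free ORF
#' proteins are exported and degraded in the cytoplasm.
#'
#' @param parameters A [parameter_set()]; defaults to the merged-model
#'   constants plus duplex-stub rates.
#' @param initial Optional [initial_conditions()] (default: 100 genomic
#'   copies, no transcript).
#' @return A validated [model_definition()].
#' @export
build_lifecycle_model <- function(parameters = NULL, initial = NULL) {
  Nuc <- "Nucleus"; Cyt <- "Cytoplasm"
  if (is.null(parameters)) {
    parameters <- default_parameters("paper-qualitative-v1")
    parameters$Kf_duplex_export <- param(0.05, "s-1", "calibrated")
    parameters$Kf_duplex_deg <- param(0.01, "s-1", "calibrated")
  }
  types <- list(
    molecule_type("L1DNA", compartments = Nuc),
    .l1mrna_type(orf0_partners = "Orf0_mRNA", compartments = c(Nuc, Cyt)),
    molecule_type("Orf0_mRNA", sites = list(sense = "L1mRNA"),
                  compartments = c(Nuc, Cyt)),
    molecule_type("ORF1p", sites = list(rna = "L1mRNA"), compartments = c(Nuc, Cyt)),
    molecule_type("ORF2p", sites = list(rna = "L1mRNA"), compartments = c(Nuc, Cyt)))
  rules <- c(.lifecycle_core_rules(), list(
    reaction_rule("duplex_export",
      list(complex_pattern(pmol("L1mRNA", orf0 = 1), pmol("Orf0_mRNA", sense = 1),
                           compartment = Nuc)),
      "Kf_duplex_export", ops = list(list(op = "transport", to = Cyt))),
    reaction_rule("duplex_degradation",
      list(complex_pattern(pmol("L1mRNA", orf0 = 1), pmol("Orf0_mRNA", sense = 1),
                           compartment = Cyt)),
      "Kf_duplex_deg",
      ops = list(list(op = "destroy", target = c(1, 1)),
                 list(op = "destroy", target = c(1, 2))))))
  if (is.null(initial)) {
    initial <- initial_conditions(ic("L1DNA", Nuc, 100), ic("L1mRNA", Nuc, 0))
  }
  model_definition("lifecycle", .comp_list(c(Nuc, Cyt)), types, rules,
                   parameters, initial)
}

#' Build the merged LINE-1 model (13 molecule types, 36 reaction rules)
#'
#' The union of the life-cycle, RNA-interference and sequestration
#' sub-models with shared species identities. The LINE-1 transcript carries
#' the four-site structure (two equivalent ORF1p sites, one ORF2p site, one
#' ORF0-RNA site); the sense/antisense duplex occupies the ORF0 site; Dicer
#' loading of the duplex is blocked when ORF protein sites are occupied;
#' MOV10_Zap binds ORF1p-loaded particles via the free ORF0 site and routes
#' them to stress granules (degradative) or multivesicular bodies (exosome
#' packaging). Default initial conditions: 100 genomic copies, 1000 each of
#' Exportin (nuclear), Dicer, RISC and clamped MOV10_Zap, no transcript; all
#' other species zero.
#'
#' @param parameters A [parameter_set()] (default
#'   `default_parameters("paper-qualitative-v1")`).
#' @param initial Optional [initial_conditions()] overriding the defaults.
#' @return A validated [model_definition()] with a `rule_provenance` table.
#'   Errors if the structural counts (13 molecule types / 36 rules) are
#'   violated, signalling a model-definition regression.
#' @export
build_merged_model <- function(parameters = default_parameters("paper-qualitative-v1"),
                               initial = NULL) {
  Nuc <- "Nucleus"; Cyt <- "Cytoplasm"
  MVB <- "MultiVesicularBodies"; SG <- "Stress_Granule"
  all4 <- c(Nuc, Cyt, SG, MVB)
  types <- list(
    molecule_type("L1DNA", compartments = Nuc),
    .l1mrna_type(orf0_partners = c("Orf0_mRNA", "MOV10_Zap", "RISC"),
                 compartments = all4),
    molecule_type("Orf0_mRNA",
                  sites = list(sense = "L1mRNA", carrier = c("Exportin", "Dicer")),
                  compartments = c(Nuc, Cyt)),
    molecule_type("ORF1p", sites = list(rna = "L1mRNA"), compartments = all4),
    molecule_type("ORF2p", sites = list(rna = "L1mRNA"), compartments = all4),
    molecule_type("Exportin", sites = list(cargo = "Orf0_mRNA"),
                  compartments = c(Nuc, Cyt)),
    molecule_type("Dicer", sites = list(sub = "Orf0_mRNA"), compartments = Cyt),
    molecule_type("RISC", sites = list(guide = "siRNA", target = "L1mRNA"),
                  compartments = Cyt),
    molecule_type("siRNA_duplex", compartments = Cyt),
    molecule_type("siRNA", sites = list(risc = "RISC"), compartments = Cyt),
    molecule_type("siRNA_passenger", compartments = Cyt),
    molecule_type("MOV10_Zap", sites = list(rna = "L1mRNA"),
                  compartments = c(Cyt, SG, MVB)),
    molecule_type("Exosome", compartments = MVB))

  rnai_rules <- list(
    reaction_rule("exportin_binds_duplex",
      list(complex_pattern(pmol("Orf0_mRNA", sense = "+", carrier = 0),
                           compartment = Nuc),
           complex_pattern(pmol("Exportin", cargo = 0), compartment = Nuc)),
      "Kf_Exp_bind",
      ops = list(list(op = "bind", a = c(1, 1, "carrier"), b = c(2, 1, "cargo")))),
    reaction_rule("duplex_complex_export",
      list(complex_pattern(pmol("Orf0_mRNA", carrier = 1), pmol("Exportin", cargo = 1),
                           compartment = Nuc)),
      "Kf_dsRNA_export", ops = list(list(op = "transport", to = Cyt))),
    reaction_rule("exportin_release",
      list(complex_pattern(pmol("Orf0_mRNA", carrier = 1), pmol("Exportin", cargo = 1),
                           compartment = Cyt)),
      "Kr_Exp", ops = list(list(op = "unbind", a = c(1, 1, "carrier")))),
    reaction_rule("exportin_import",
      list(complex_pattern(pmol("Exportin", cargo = 0), compartment = Cyt)),
      "Kf_Exp_import", ops = list(list(op = "transport", to = Nuc))),
    # Dicer loading is blocked when any ORF protein site is occupied
    reaction_rule("dicer_bind",
      list(complex_pattern(pmol("Dicer", sub = 0), compartment = Cyt),
           complex_pattern(pmol("L1mRNA", orf1_a = 0, orf1_b = 0, orf2 = 0, orf0 = 1),
                           pmol("Orf0_mRNA", sense = 1, carrier = 0),
                           compartment = Cyt)),
      "k1_Dicer",
      ops = list(list(op = "bind", a = c(1, 1, "sub"), b = c(2, 2, "carrier")))),
    reaction_rule("dicer_unbind",
      list(complex_pattern(pmol("Dicer", sub = 1), pmol("Orf0_mRNA", carrier = 1),
                           compartment = Cyt)),
      "km1_Dicer", ops = list(list(op = "unbind", a = c(1, 1, "sub")))),
    reaction_rule("dicer_cleave",
      list(complex_pattern(pmol("L1mRNA", orf0 = 1),
                           pmol("Orf0_mRNA", sense = 1, carrier = 2),
                           pmol("Dicer", sub = 2), compartment = Cyt)),
      "k2_Dicer",
      ops = list(list(op = "destroy", target = c(1, 1)),
                 list(op = "destroy", target = c(1, 2)),
                 list(op = "create", type = "siRNA_duplex"))),
    reaction_rule("sirna_separation",
      list(complex_pattern(pmol("siRNA_duplex"), compartment = Cyt)),
      "Kf_helicase",
      ops = list(list(op = "destroy", target = c(1, 1)),
                 list(op = "create", type = "siRNA"),
                 list(op = "create", type = "siRNA_passenger"))),
    reaction_rule("passenger_decay",
      list(complex_pattern(pmol("siRNA_passenger"), compartment = Cyt)),
      "Kf_passenger_decay", ops = list(list(op = "destroy", target = c(1, 1)))),
    reaction_rule("risc_load",
      list(complex_pattern(pmol("RISC", guide = 0), compartment = Cyt),
           complex_pattern(pmol("siRNA", risc = 0), compartment = Cyt)),
      "Kf_RISC_load",
      ops = list(list(op = "bind", a = c(1, 1, "guide"), b = c(2, 1, "risc")))),
    reaction_rule("risc_target_bind",
      list(complex_pattern(pmol("RISC", guide = "+", target = 0), compartment = Cyt),
           complex_pattern(pmol("L1mRNA", orf1_a = 0, orf1_b = 0, orf2 = 0, orf0 = 0),
                           compartment = Cyt)),
      "k1_RISC",
      ops = list(list(op = "bind", a = c(1, 1, "target"), b = c(2, 1, "orf0")))),
    reaction_rule("risc_target_unbind",
      list(complex_pattern(pmol("RISC", target = 1), pmol("L1mRNA", orf0 = 1),
                           compartment = Cyt)),
      "km1_RISC", ops = list(list(op = "unbind", a = c(1, 1, "target")))),
    reaction_rule("risc_cleave",
      list(complex_pattern(pmol("RISC", guide = "+", target = 1),
                           pmol("L1mRNA", orf0 = 1), compartment = Cyt)),
      "k2_RISC", ops = list(list(op = "destroy", target = c(1, 2))),
      pathway = "risc"))

  seq_rules <- list(
    # MOV10_Zap binds ORF1p-loaded particles via the free ORF0 site
    reaction_rule("mov10_bind",
      list(complex_pattern(pmol("MOV10_Zap", rna = 0), compartment = Cyt),
           complex_pattern(pmol("L1mRNA", orf1_a = "+", orf0 = 0), compartment = Cyt)),
      "Kf_Mov10_bind",
      ops = list(list(op = "bind", a = c(1, 1, "rna"), b = c(2, 1, "orf0")))),
    reaction_rule("rnp_to_sg",
      list(complex_pattern(pmol("MOV10_Zap", rna = 1), pmol("L1mRNA", orf0 = 1),
                           compartment = Cyt)),
      "Kf_to_SG", ops = list(list(op = "transport", to = SG)), pathway = "sg"),
    reaction_rule("rnp_to_mvb",
      list(complex_pattern(pmol("MOV10_Zap", rna = 1), pmol("L1mRNA", orf0 = 1),
                           compartment = Cyt)),
      "Kf_to_MVB", ops = list(list(op = "transport", to = MVB)), pathway = "mvb"),
    # granule-internal degradation of the particle; MOV10_Zap survives
    reaction_rule("sg_degradation",
      list(complex_pattern(pmol("MOV10_Zap", rna = 1), pmol("L1mRNA", orf0 = 1),
                           compartment = SG)),
      "Kf_SG_deg", ops = list(list(op = "destroy_others", keep = list(c(1, 1))))),
    reaction_rule("exosome_packaging",
      list(complex_pattern(pmol("MOV10_Zap", rna = 1), pmol("L1mRNA", orf0 = 1),
                           compartment = MVB)),
      "Kf_exosome",
      ops = list(list(op = "destroy_others", keep = list(c(1, 1))),
                 list(op = "create", type = "Exosome"))))

  rules <- c(.lifecycle_core_rules(), rnai_rules, seq_rules)

  if (is.null(initial)) {
    initial <- initial_conditions(
      ic("RISC", Cyt, 1000),
      ic("MOV10_Zap", Cyt, 1000, clamped = TRUE),
      ic("L1mRNA", Nuc, 0),
      ic("L1DNA", Nuc, 100),
      ic("Exportin", Nuc, 1000),
      ic("Dicer", Cyt, 1000))
  }

  prov <- data.frame(
    rule = vapply(rules, `[[`, character(1), "name"),
    origin = c(
      # life-cycle core
      "life-cycle diagram: sense transcription",
      "life-cycle diagram: antisense (ORF0) transcription",
      "life-cycle diagram: sense/antisense duplex formation (irreversible annealing)",
      "life-cycle diagram: nuclear export of the free transcript (also re-export after reverse transcription)",
      "life-cycle diagram: translation of ORF1p from the free cytoplasmic transcript",
      "life-cycle diagram: translation of ORF2p from the free cytoplasmic transcript",
      "life-cycle diagram: ORF1p binding (cytoplasm only; two equivalent sites)",
      "bookkeeping: ORF1p unbinding (reverse of binding)",
      "life-cycle diagram: ORF2p binding (cytoplasm only)",
      "bookkeeping: ORF2p unbinding (reverse of binding)",
      "life-cycle prose: nuclear import gated on >=1 ORF1p and one ORF2p",
      "reverse-transcription rule figure: one new genomic copy, complete dissociation",
      "life-cycle prose: ORF proteins exported back to the cytoplasm",
      "life-cycle prose: ORF proteins exported back to the cytoplasm",
      "full-model prose: ORF protein degradation in the cytoplasm",
      "full-model prose: ORF protein degradation in the cytoplasm",
      "life-cycle diagram: background cytoplasmic RNase degradation",
      "bookkeeping: nuclear antisense-RNA turnover (nuclear RNase H2 activity)",
      # RNAi
      "RNAi diagram: Exportin binds the duplex in the nucleus",
      "RNAi diagram: duplex-Exportin complex export",
      "RNAi diagram: duplex release in the cytoplasm",
      "RNAi diagram: Exportin re-import",
      "full-model prose: Dicer loading blocked when ORF protein sites are occupied",
      "RNAi equilibrium triplet: Dicer complex dissociation",
      "RNAi diagram: Dicer catalysis producing siRNA duplex",
      "RNAi prose: helicase separation of the siRNA strands",
      "bookkeeping: passenger-strand decay",
      "RNAi diagram: RISC loading with the guide strand",
      "RNAi equilibrium triplet: loaded RISC binds the free transcript",
      "RNAi equilibrium triplet: target dissociation",
      "RNAi diagram: catalytic target cleavage, guide retained",
      # sequestration
      "full-model prose: MOV10_Zap binds the loaded particle via the ORF0 site",
      "sequestration diagram: translocation to stress granules",
      "sequestration diagram: translocation to multivesicular bodies",
      "sequestration diagram: degradation inside stress granules",
      "bookkeeping: exosome packaging in multivesicular bodies"),
    stringsAsFactors = FALSE)

  model <- model_definition("merged", .comp_list(c(Nuc, Cyt, SG, MVB)), types,
                            rules, parameters, initial,
                            rule_provenance = prov)
  if (length(model$molecule_types) != 13L || length(model$rules) != 36L)
    stop("build_merged_model: structural regression - expected 13 molecule types ",
         "and 36 rules, got ", length(model$molecule_types), "/",
         length(model$rules), call. = FALSE)
  model
}
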