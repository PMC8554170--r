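Package: line1sim
Title: Stochastic Rule-Based Simulation of the LINE-1 Retrotransposon Life Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and simulates compartmental, rule-based stochastic models of
    the human LINE-1 retrotransposon life cycle: transcription of sense and
    antisense (ORF0) RNA, RNA interference through Exportin, Dicer and RISC,
    sequestration of ribonucleoprotein particles into stress granules and
    multivesicular bodies, and the reverse-transcription positive feedback loop
    that copies LINE-1 back into the genome. Reaction rules over site-graph
    molecules are expanded into a finite mass-action network and simulated
    exactly with the Gibson-Bruck next-reaction method (or deterministically as
    ODEs), with clamped species, per-pathway event tallies, growth-regime
    classification and parameter-sweep experiments. Includes Michaelis-Menten
    to elementary mass-action conversion under the equilibrium approximation,
    YAML model configuration, and SBML Level 3 export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
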