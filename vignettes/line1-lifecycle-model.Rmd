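---
title: "Modelling the LINE-1 retrotransposon life cycle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the LINE-1 retrotransposon life cycle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(line1sim)
```

## The biological problem

LINE-1 (Long INterspersed Element-1) is the only autonomous human
retrotransposon: its ~6 kb transcript encodes an RNA-binding chaperone
(ORF1p) and a protein with endonuclease and reverse-transcriptase activity
(ORF2p). When epigenetic silencing fails — for instance after carcinogen
exposure — the transcript is exported, translated, packaged into a
ribonucleoprotein particle (RNP), re-imported into the nucleus, and reverse
transcribed into a new genomic copy. Because every new copy can itself be
transcribed, the life cycle is a positive feedback loop.

`line1sim` models this loop together with three post-transcriptional
defences, as a compartmental, well-mixed, rule-based stochastic
reaction network:

* **background RNase** — first-order degradation of the free cytoplasmic
  transcript;
* **RNA interference** — the antisense ORF0 promoter in the LINE-1 5' UTR
  produces a complementary transcript; the sense/antisense duplex is
  ferried out of the nucleus by Exportin, diced into siRNA, and loaded into
  RISC, which cleaves the free transcript catalytically;
* **sequestration** — a lumped MOV10/ZAP/SAMHD1 species binds
  ORF1p-bearing particles and routes them to stress granules (degradative)
  or multivesicular bodies (exosome precursors).

The central question the simulations ask: when carcinogen exposure is
represented either as a one-time bolus of nuclear transcript or as an
increase of the transcription rate, at what point does the genomic copy
number switch from static, through bounded growth, to runaway exponential
amplification — and which defence pathway absorbs the load?

## Model structure

Molecules are site graphs. The LINE-1 transcript deliberately carries only
four binding sites — two *equivalent* ORF1p sites, one ORF2p site, and one
ORF0 site — a published simplification of the real biology, in which ORF1p
trimerises and coats the transcript in many copies. The ORF0 site is
over-loaded: it can hold the antisense transcript (forming the duplex), the
loaded RISC complex (target engagement), or MOV10_Zap (sequestration), so
the three defences compete structurally for the same molecular real estate.
Two consequences of this encoding are worth spelling out:

* Dicer can only load a duplex whose ORF protein sites are all free, so ORF
  proteins shield the transcript from RNA interference;
* translation fires only on the fully naked cytoplasmic transcript, so a
  partially assembled particle no longer produces protein (a ribosome can
  no longer scan it).

The merged model declares exactly 13 molecule types and 36 reaction rules
in 4 compartments (`Nucleus`, `Cytoplasm`, `Stress_Granule`,
`MultiVesicularBodies`). The original supplementary rule inventory is not
public, so the rule set here is a reconstruction from the published
reaction diagrams and prose; `build_merged_model()$rule_provenance` records
the origin of every rule, and bookkeeping additions (siRNA strand
separation and passenger decay, nuclear antisense turnover, exosome
packaging from multivesicular bodies) are flagged as such there. Reverse
transcription consumes an imported RNP carrying at least one ORF1p and one
ORF2p, emits exactly one new genomic copy, and completely dissociates the
particle; the preserved transcript is re-exported, because ORF2p lacks
RNase H activity. ORF proteins bind the transcript only in the cytoplasm
and are degraded only in the cytoplasm or stress granules, reflecting their
experimentally observed absence from the nucleus.

```{r structure}
model <- build_merged_model()
model
head(model$rule_provenance, 4)
```

## From rules to a concrete network

`expand_rules()` saturates the rule set over the seed species
(BioNetGen-style generate-network semantics): every rule is applied to
every matching species tuple until no new species appear. Matching
collapses embeddings that differ only by a permutation of the declared
equivalent ORF1p sites; the surviving multiplicity becomes the statistical
factor of the concrete reaction, so binding to a doubly-free ORF1p pair is
twice as fast as binding to a half-occupied one, and unbinding from a
doubly-occupied pair is twice as fast as from a single occupant.
Species are identified by a canonical label (brute-force minimisation over
molecule orderings within equal-signature groups and equivalent-site
permutations, using byte ordering so labels are locale-independent). This
is exact for the complex sizes this model can form (at most five
molecules); complexes of many identical molecules would exceed a documented
candidate cap and fall back to a deterministic non-minimised ordering — a
deliberate limit, since no packaged rule set can polymerise.

```{r network}
net <- expand_rules(model)
net
```

## Simulation

The stochastic engine is an exact next-reaction implementation: tentative
absolute firing times in an indexed binary min-heap, time rescaling
`t_new = t + (a_old/a_new)(t_old - t)` for dependent reactions, a fresh
exponential draw for the fired reaction (and whenever the old propensity
was zero), ties broken by reaction index, and rate-zero reactions parked at
`+Inf`. Output is sampled on a fixed time grid (default 1 s) rather than
per event, which bounds memory in exponential regimes. Runs stop at
`t_end` (default 10,000 s, i.e. 2.7 h), or gracefully at a configurable
total-molecule cap (default 1e7) standing in for the original simulation
platform's overflow fault; the termination status is recorded on the
trajectory. Randomness comes from R's Mersenne-Twister via `set.seed()`,
so a `(network, stop condition, seed)` triple reproduces a trajectory
bit-identically; the generator identity is stored in the run metadata.

Clamped species (MOV10_Zap by default, per the published initial-condition
table) keep a constant count: they enter propensities normally but every
consumed copy is replenished, which is how the published
constant-copy-number variant is expressed. The same network can be
integrated deterministically (`simulate_ode()`, stiff-capable `lsoda`,
clamped species with zeroed derivatives) — used here both for the enzyme
kinetics validation and as a mean-field cross-check of the stochastic
engine.

Every reaction carries a pathway tag (`rnase`, `risc`, `sg`, `mvb`, `rt`,
`other`); cumulative per-pathway event tallies ride along the trajectory
and power the degradation-fate accounting: each transcript ever present is
attributed to exactly one of RNase degradation, RISC cleavage,
stress-granule or multivesicular-body sequestration (counted at
translocation), or survival, so the fractions partition unity exactly.

## Enzyme kinetics: Michaelis–Menten to elementary steps

Stochastic simulation requires elementary mass action, so the Dicer and
RISC enzymatic steps are rapid-equilibrium decompositions of their
saturating forms: for E + S ⇌ ES → E + P, `k2 = Vmax/Et` and
`k_minus1 = k1·Km`, with `k1` chosen arbitrarily at 10 (µM·s)⁻¹ for both
enzymes (the one pair of binding constants fixed by the source study).
Only the ratio `k_minus1/k1` matters in the quasi-equilibrium limit;
the test suite verifies both that the converted triplet reproduces the
hyperbolic velocity within 5% across substrate concentrations spanning
`[0.01·Km, 100·Km]`, and that scaling `k1 → 10·k1` with `k_minus1` scaled
by `Km` leaves the steady-state velocity unchanged to better than one part
in 1e5. The decomposition is flagged self-consistent only while
`k2/k_minus1 < 0.1` — the package's explicit reading of "catalysis much
slower than dissociation". Bimolecular constants in (µM·s)⁻¹ are converted
to per-pair propensities with the source compartment volume
(`c = k/(N_A·V·1e-6)`); the default volumes (cytoplasm 2.0e-12 L, nucleus
4.0e-13 L, granules 1.0e-15 L) are ordinary mammalian-cell magnitudes and
matter *only* for those conversions, since the model is non-spatial.

## The default parameter set and its calibration

The source study's full rate-constant table is confined to a supplementary
spreadsheet that is not publicly archived. The shipped default set
`"paper-qualitative-v1"` therefore distinguishes provenance explicitly:
`paper-printed` entries are exactly the Dicer/RISC `k1` values, the sweep
grids and the initial counts; everything else is tagged `calibrated`. The
calibrated values were fixed once, before the acceptance suite was frozen,
by a coarse scaling analysis followed by a grid refinement
(`calibrate_defaults()` reproduces the procedure), against the study's
*qualitative* targets:

* transcription-rate sweep threshold at 0.1 s⁻¹ (static/bounded below
  0.1, exponential at 0.1 and 1.0);
* initial-transcript sweep static at 100 copies (net genomic gain of about
  one copy), bounded at 10,000, exponential with early count-cap
  termination at 100,000;
* zero RISC-mediated cleavage events in all rate-sweep and antisense-rate
  runs;
* stress-granule/multivesicular-body events only at the three highest
  transcription rates;
* identical threshold with the finite pools (Exportin, Dicer, RISC,
  MOV10_Zap) clamped.

The single-trajectory copy numbers printed in the source figures (a rise
to ~39 transcripts, stabilisation at 135 genomic copies) are individual
stochastic realisations under unpublished constants; they are treated as
order-of-magnitude context, not calibration targets, and the packaged
defaults make no attempt to match them. In particular, the "about one"
genomic gain at 100 initial transcripts is a Poisson-level event count:
under the defaults the median gain across seeds is 0–1 copies, comfortably
inside the static band (a net change of at most 2 counts).

The threshold mechanics under the defaults are worth recording. Protein
supply scales with transcript abundance, and particle assembly is
bimolecular in both, so the per-transcript probability of completing a
retrotransposition cycle grows roughly quadratically with activity. That
gives the copy-number dynamics a finite-time-blow-up character
(dD/dt ∝ D³ along the self-reinforcing branch): below threshold the blow-up
time sits far beyond the 10,000 s horizon and the trajectory looks static
or bounded; above it the runaway arrives early and the run terminates at
the count cap. The antisense/RNAi arm is parameterised with a very slow
duplex-annealing constant (two long single-molecule RNAs finding each other
in the nucleus), which is why RNAi contributes no cleavage under any
default condition — matching the source study's own conclusion that RNase,
not RNAi or sequestration, dominates transcript turnover.

The sequestration sub-model's defaults are derived in closed form: with
1000 clamped MOV10_ZAP copies, binding at `k_b` and background RNase at
`k_d`, the sequestered fraction of a decaying RNA pool is
`k_b·M/(k_b·M + k_d)` and the surviving fraction `exp(-(k_b·M + k_d)·t)`.
The shipped values put those at ≈2.4% sequestered / ≈95.3% degraded /
≈2.3% surviving after 10,000 s. The quantitative split from the source
supplement is *not* treated as reproducible (its constants are
unpublished); the default test suite asserts the property that fractions
partition unity and sequestration is far smaller than RNase degradation,
and reports the simulated percentages.

```{r fates}
res <- run_standalone_sequestration(20000, seeds = 1)
round(100 * res$mean_fractions, 2)
```

## Regime classification

The source figures distinguish regimes by eye; the package makes the
criterion explicit and configurable (`classify_growth()`):

* **exponential** — the run hit a count cap, or the least-squares slope of
  `log(count + 1)` over the final third exceeds 2e-4 s⁻¹ *and* the count at
  least doubled over that window;
* **static** — net change of at most 2 counts over the run;
* **bounded** — everything else.

Sweeps run 10 seeds per value by default and aggregate regimes by majority
vote (ties resolved towards higher severity); the reported threshold is the
smallest value labelled exponential. Sweep stop conditions default to a
10 s output grid and a 5e5 total-molecule cap — small enough to keep an
exponential run's event count modest, large enough that the 100,000
initial-transcript bolus (peak occupancy well under 2e5 molecules) cannot
trip the cap without genuine growth.

When the transcription rate is swept, the antisense rate follows at 1/8 of
each value. The source text gives both "about 1/8" and "approximately
1/10" for that ratio in different places; the package defaults to 1/8 and
leaves `Kf_Make_Orf0` independently settable. The dedicated antisense-rate
runs use the study's absolute pairs (antisense 0.001 s⁻¹ with sense
0.01 s⁻¹; antisense 0.1 s⁻¹ with sense 1.0 s⁻¹) and are evaluated solely
on the RISC event count, the only outcome reported for them.

## What the synthetic conditions do and do not show

The simulations emulate an acute activation of LINE-1 in a single
well-mixed cell over 2.7 h: no spatial structure, no diffusion limits, no
cell cycle or nuclear-envelope breakdown, no epigenetic silencing dynamics,
no APOBEC or piRNA pathways, no ORF0 protein function, no SINE competition
for the retrotransposition machinery, and no resource limits (nucleotides,
ribosomes) — so the "exponential" regime is a mathematical statement about
the unchecked feedback loop, not a physiological trajectory. Passing the
regime-structure tests shows that the reconstructed network with the
calibrated defaults reproduces the published threshold *topology*; it does
not validate any individual rate constant against measurement, and the
clock of the model (transcript half-lives of ~30 s, for example) is faster
than the cell-culture time courses it is inspired by.

## Numerical choices and degenerate inputs

* Firing-time ties break by reaction index; zero-propensity reactions sit
  at `+Inf`; a fresh exponential is drawn whenever the previous propensity
  was zero.
* Species counts can never go negative (a consuming reaction's propensity
  vanishes at zero count); the engine also guards against it explicitly.
* Networks with zero reactions or zero-length horizons are valid inputs
  (constant trajectories, surviving fraction 1).
* Expansion is guarded by a species cap (default 10,000) that names the
  runaway rule — relevant only for user-supplied polymerising rule sets,
  which the packaged models exclude.
* Fate fractions are computed from integer event tallies, so they
  partition unity to floating-point exactness, not approximately.

## Reproducibility surface

Every trajectory CSV is accompanied by metadata (seed, RNG identity,
termination status, parameter-set hash), and sweeps embed the same hash, so
any figure can be regenerated bit-identically. Models serialise to YAML
configs (`load_config()` / `compile_config()`) with unknown keys and
malformed values rejected; expanded networks export to SBML Level 3
(`export_sbml()`), with compartment volumes, initial amounts, clamp flags
as boundary conditions, and one elementary mass-action kinetic law per
concrete reaction, round-tripping exactly through `import_sbml()`.

## Problem sizes used by the test and acceptance suites

The packaged checks run the full 10,000 s horizon with 10 seeds per sweep
condition and a 10 s output grid; the standalone sequestration scenario
runs at the study's full loads (100,000 and 300,000 RNA copies, a few
seeds), while unit tests use scaled-down loads (tens of thousands) where
only a fraction or a property is being asserted. Engine-equivalence checks
use 5,000 first-event replicates per method. These sizes were chosen so
the whole suite exercises every published condition while remaining a
matter of minutes on a single core.
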