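---
title: "A ligand-based virtual screening workflow for PPI inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A ligand-based virtual screening workflow for PPI inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Protein–protein interactions (PPIs) such as the Keap1 Kelch domain binding
the Nrf2 Neh2 peptide are hard screening targets: conventional
small-molecule libraries built around the rule of five rarely contain
matter that can cover a large, shallow interaction surface, and hit rates
in unfocused high-throughput screens are measured in hundredths of a
percent. Two ideas improve the odds. First, screen a *PPI-oriented*
library of small-to-medium molecules (molecular weight mainly 450–650).
Second, spend the assay budget on compounds prioritised by *ligand-based
virtual screening* (LBVS): classifiers trained on known actives rank the
library, and only the high-ranked (plus a random comparator arm) go into
the assay. This package implements that workflow end to end, in a form
where every stage is testable without any external database: curation,
featurization, model training and evaluation, ranking and selection, assay
triage, and hit-rate analysis, plus a synthetic compound universe that
emulates the statistical structure of the real inputs.

## The two negative-data strategies

The workflow trains two random-forest classifiers that differ only in
where their negative examples come from:

* **RF-TI** ("true inactive") — measured actives versus compounds measured
  inactive against the same PPI. Realistic but hard: measured inactives
  are usually close analogues of the actives (chemists test around known
  chemotypes), so the classes share scaffolds and the decision boundary
  runs through substituent-level differences.
* **RF-PI** ("putative inactive") — measured actives versus untested
  vendor compounds presumed inactive (decoys). Optimistic by
  construction: actives and random commercial matter differ broadly, so
  cross-validation is near-perfect. Its value shows up prospectively, not
  in cross-validation.

Both use 1,000 trees and mtry = floor(sqrt(p)) (the conventional default),
with probability-of-active defined as the fraction of trees voting active.
The classification threshold for confusion counts is 0.5; the evaluation
protocol is stratified five-fold cross-validation reporting accuracy,
precision, recall, specificity, MCC, AUCROC and AUCPR per fold and their
unweighted mean (folds differ by at most one compound, so weighting is
immaterial). An MCC with a zero denominator is reported as 0 with an
undefined flag — the convention that keeps fold means aggregatable. The
random-forest fitting itself is delegated to `ranger`; the contract this
package owns is the feature space, the fold construction, the metric
formulas and seeded reproducibility (`num.threads = 1`; parallel tree
growth would not change results but keeps timing machine-independent).

## Features

Each compound is reduced to its largest covalent fragment (salts and
mixtures drop counter-ions), then described by five properties —
molecular weight, an atom-contribution (Crippen-type) logP standing in
for the proprietary AlogP, and counts of H-bond acceptors, donors and
rotatable bonds — plus a functional-class circular fingerprint. The
fingerprint assigns each atom a six-role pharmacophore type (H-donor,
H-acceptor, positively ionizable, negatively ionizable, aromatic,
halogen) and hashes bonded neighbourhoods iteratively out to radius 3
(diameter 6), collecting sparse integer identifiers without folding. This
is the package's analogue of FCFP_6: the exact Pipeline Pilot bit values
are not reproducible outside that product, so all similarity values are
treated as analogous rather than bit-identical, and the package's
similarity contract (Tanimoto = |A∩B|/|A∪B| over bit sets, properties
excluded) is what the tests pin down exactly. Donor/acceptor property
counts reuse the fingerprint's atom roles, so bits and counts can never
disagree about what an acceptor is. The model feature space is frozen
from training data only — five properties plus every distinct training
bit — and unseen bits are dropped at projection time, exactly as a
deployed model would see them.

Two deliberate simplifications: formal charges are ignored by the atom
typing (ionizable roles are perceived from the neutral substructure;
generated molecules are neutral), and kekulisation ambiguity is
neutralised by treating any bond inside a perceived aromatic ring as a
single "aromatic" bond type, which keeps the fingerprint invariant to
atom reordering — a property the test suite checks over randomly permuted
atom orders.

## The synthetic universe

The real campaign drew on activity databases, a vendor catalogue and a
12,593-compound PPI-oriented library. The generator stands in for all of
these with a template grammar: 20 scaffold templates × 15 substituents at
2–3 substitution points, partitioned into active/true-inactive chemotypes
(naphthalene-sulfonamide and aryl-carboxylate cores), small plain vendor
chemotypes, and eight large library chemotypes sized into the 450–650 Da
window. Within a family similarity is high; across families it is low.
Three library families are *feature-correlated* with the actives: their
scaffolds embed an ortho-substituted aromatic amide with a carboxylated
piperidine — the common substructure seen in real hits — and they draw
from the same pharmacophoric substituent pool, while remaining distinct
scaffolds. Latent hit labels are planted at `base_hit_rate` (default 1%,
the random-arm rate of the modelled campaign), multiplied by
`enrichment_factor` (default 6, the ratio of the reported model-arm to
random-arm hit rates) in the correlated families. Tying hit probability
to feature-correlated *families* rather than raw similarity reflects the
campaign's central observation: its hits sat at Tanimoto 0.14–0.26 from
every known inhibitor — far below any similarity-search radius — yet a
model trained on functional-class features found them. Every library
compound is kept at Tanimoto ≤ 0.32 (configurable) to its nearest active,
the cap observed for the real library; violating draws are replaced, and
an exhausted template space is an explicit error naming the shortfall.

Actives must carry at least one acidic/sulfonamide substituent and true
inactives none; this is the learnable within-chemotype signal, mirroring
the acidic anchor that real Keap1/Nrf2 inhibitors use at the arginine
triad of the Kelch pocket. The availability flag marks a random 21.3% of
the library (nearest integer, ties rounded up), emulating the synthesized
subset that was actually assayable.

The simulated TR-FRET assay fixes the 0%- and 100%-inhibition anchors at
10,000 and 1,000 arbitrary units (only the converted inhibition percent is
contractually meaningful), places each compound's signal at its planted
effect, adds Gaussian noise (`assay_noise_sd`, default 5 percentage
points, expressed on the signal scale) and converts back through the
standard inhibition formula, so values can fall outside [0, 100] under
noise exactly as plate data do. Planted effects are drawn once per
universe (mean 40, sd 20, truncated to [0, 100]) — spanning the weak
15–30% hits and the few strong ones the modelled assay reported — and a
`nonspecific_fraction` (default 1/16) of hits also inhibits the counter
assay. What the generator does **not** emulate: real
structure–activity landscapes, assay artefacts other than Gaussian noise
(aggregation, interference), and correlations between availability and
chemistry. Passing tests therefore demonstrate that the machinery
recovers structure that is present by construction; they are not evidence
about any particular real target.

## Selection, triage and hit statistics

Both models score the full library before availability filtering (ranks
are over all compounds, ties broken by compound id), and the top-*n*
(default 1,000) per model intersected with the available subset forms
three arms: overlap, PI-only, TI-only. The random arm samples uniformly
from available compounds outside all model arms. A primary hit shows
inhibition strictly above 15% at the screening concentration; a specific
hit additionally stays below the counter-assay cutoff. The counter
cutoff is not stated numerically in the modelled campaign — its one
non-specific hit sat at 65.2% counter inhibition and every retained hit
at ≤ 6.4% — so the package defaults to 15%, mirroring the primary
threshold; any value between those observations reproduces the same
triage, and the parameter is configurable. "NI" (no inhibition) tokens
are preserved as provenance and treated as 0% in comparisons.

Hit rates divide each arm's hit count by its size, with the overlap arm
included in both model denominators and hits selected by both models
counted in both numerators. The extrapolation assumes untested available
compounds hit at the random-arm rate: possible hits = observed +
(available − assayed) × rate, reported after rounding to a whole
compound, with the possible rate over the available set and lower bounds
over the available set and the whole library. Reported percentages are
rounded half-up at one decimal (two for the small library bounds) at the
reporting layer only; internal values keep full precision. The
`reproduce_reported_statistics()` function re-derives all twelve headline
numbers of the modelled campaign from its transcribed per-compound hit
table and flow counts — including the published convention of using the
*rounded* 1.0% random rate inside the extrapolation — and the test suite
requires exact agreement at printed precision.

## Numerical and design choices

* Canonical structure identity = OpenBabel canonical SMILES of the
  charge-normalised largest fragment; used for deduplication, active/decoy
  exclusion and cross-set disjointness.
* Largest-fragment ties break by molecular weight, then lexicographically
  smaller canonical SMILES.
* Percent-inhibition activity records classify as active at ≥ 50%
  inhibition by default (the source databases do not state their rule;
  the threshold is a parameter).
* Concentration records standardise to micromolar; the activity threshold
  (≤ 10 µM) is inclusive and applied to the minimum across a compound's
  records, which makes classification monotone in any single value.
* Stratified folds are keyed by sorted compound id before the seeded
  shuffle, so fold membership is invariant to input order; classes place
  their remainder compounds on rotating folds so total fold sizes differ
  by at most one (52+52 at k = 5 gives sizes 21,21,21,21,20).
* AUCROC uses the rank statistic with tied scores counting one half;
  AUCPR integrates precision over recall steps at the distinct-score
  thresholds.
* All randomness flows through per-call seeds; the pipeline derives
  stage seeds as fixed offsets from one global seed, and re-running a
  configuration reproduces every artifact byte-identically (the one
  environmental timestamp OpenBabel writes into SDF headers is blanked).

## Problem sizes used by the tests and the acceptance script

The generator's defaults mirror the modelled campaign (108/106 known
actives/inactives, a 12,593-compound library, 21.3% availability). The
test suite and the acceptance script run the same machinery at reduced
scale — universes of 400–1,000 library compounds for unit and pipeline
tests, 600 per seed (three seeds) for the enrichment study, and one
10,000-compound library for the binomial check on planted hit rates —
sizes at which every statistical assertion retains comfortable power
while a full run stays within a coffee break on one CPU. The published
arithmetic checks use the real campaign's printed counts and are exact.

## Known limitations

* The fingerprint and logP are analogues, not re-implementations, of the
  proprietary descriptors; absolute similarity values differ from
  Pipeline Pilot's, and only set-arithmetic behaviour is exact.
* Aromaticity and implicit-hydrogen perception follow simple valence
  rules on the kekulised graph; exotic chemistry (charged species,
  organometallics, tautomer-dependent roles) is out of scope.
* The true-inactive universe plants a clean substituent-level class
  signal; real measured inactives are noisier, so RF-TI cross-validation
  on synthetic data is more flattering than the ~0.8 accuracy regime seen
  with real data.
* The assay simulator is a two-anchor linear readout with Gaussian
  noise; it cannot produce dose–response curvature or systematic plate
  effects.
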