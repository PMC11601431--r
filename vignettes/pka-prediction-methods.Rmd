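---
title: "Predicting protein pKa values and protonation states from structure"
author: "protpka authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein pKa values and protonation states from structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protpka)
```

## The problem

The six titratable amino acids (Asp, Glu, His, Cys, Tyr, Lys) exchange a
proton in the physiological pH range. Free in solution each sidechain has a
reference "model" pKa (Asp 3.7, Glu 4.2, His 6.5, Cys 8.5, Tyr 9.5,
Lys 10.4); the protein environment shifts a residue away from that value
through desolvation, hydrogen bonding and electrostatic interactions.
Knowing the shifted pKa tells you whether a residue is protonated,
deprotonated or titrating at a pH of interest — which controls catalysis,
pH sensing and the reactivity of nucleophilic Cys/Lys targeted by covalent
drugs.

`protpka` implements a complete structure-based prediction pipeline:

1. **Featurization** of titratable sites from PDB structures (burial,
   solvent accessibility, polar/charged neighbour counts and distances,
   secondary structure);
2. **Tree regressors** trained separately for acids (Asp, Glu, Cys, Tyr)
   and bases (His, Lys) under a leakage-free multi-holdout protocol;
3. An **atom-graph attention network (GAT)** trained on pKa *shifts* over
   the 10 Å microenvironment of each site, with ensembling and a
   pretrain/fine-tune path;
4. **Protonation-state classification** from predicted pKa values, with a
   critical-error-rate metric;
5. A seeded **synthetic-structure generator** so the entire pipeline is
   testable offline.

## Features of a titratable site

All microenvironment measurements are taken from the site's *anchor
point*: the centroid of the sidechain atoms that gain or lose the proton
(Asp OD1/OD2, Glu OE1/OE2, His ND1/NE2, Cys SG, Tyr OH, Lys NZ).

The versioned catalog `pkafeat-1` contains 28 features in three numeric
groups plus categoricals:

* **Accessibility** — `buried_ratio` (1 − sidechain SASA / reference
  maximum sidechain SASA, in [0, 1]), raw sidechain SASA, and heavy-atom
  packing counts at 6/8/10 Å. SASA uses an in-package Shrake–Rupley
  implementation (probe 1.4 Å, 960 deterministic golden-spiral quadrature
  points per atom, fixed vdW radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å,
  generic 1.8 Å fallback). The reference maximum sidechain SASA is
  computed once per session from an extended Gly-X-Gly tripeptide using
  the same implementation, keeping numerator and denominator
  method-consistent.
* **Hydrogen bonding** — counts of polar sidechains within 10 and 15 Å
  (`n_polar10`, `n_polar15`; polar set: Ser, Thr, Asn, Gln, Tyr, His,
  Cys, Trp sidechain O/N/S), nearest/second-nearest distances to polar
  sidechain atoms, His sidechain nitrogens (`d0_hbond_h`), backbone
  carbonyl O and amide N.
* **Electrostatics** — counts of positive (Lys NZ, Arg NH1/NH2/NE, His
  ring N) and negative (Asp/Glu carboxylate O, C-terminal OXT) partners
  at 10/15 Å, and nearest distances to negatively charged oxygens
  (`d0_neg_O`) and positive nitrogens.
* **Categorical** — residue type, 3-state secondary structure of the site
  and the majority class within 10 Å, and the sign of the summed formal
  charge within 10 Å (pH-7 standard states), all integer-coded.

Conventions: heavy atoms only (experimental structures rarely resolve
hydrogens), radii are inclusive (`<= r`), neighbour counts are
residue-level, the site's own residue is excluded, and an absent partner
class yields a 20 Å sentinel distance (twice the 10 Å electrostatic
relevance radius; trees handle the plateau). Every feature is invariant
under rigid motion (exactly for counts, 1e-6 Å for distances, ~1% for the
quadrature-based SASA terms).

Secondary structure is a deliberately small 3-state assigner: helix
requires helical backbone dihedrals *and* an i→i+4 / i→i+2 O···N contact
≤ 3.5 Å, strand requires extended dihedrals, everything else (including
incomplete backbones) is coil. It is not DSSP; at this feature resolution
only the coarse class matters.

```{r featurize-example}
spec <- synthetic_spec(n_sites = 1, seed = 7)
s <- read_structure(generate_structure(spec, 1))
site <- identify_titratable_sites(s)[[1]]
round(featurize_site(s, site)[c("model_pka", "buried_ratio", "n_polar10",
                                "d0_hbond_h", "d0_neg_O")], 3)
```

## Data model and leakage-free splits

Experimental pKa tables are read in a PKAD-style delimited layout, one
row per measurement. The unit of splitting is the *unique residue*
(accession + residue number + mutation tag + conformational-state tag):
the same residue can appear with several measurements and several
structures, and all of them always travel to the same side of a split.
Splits are stratified over five quantile bins of the per-key mean pKa
(the bin count is a package choice; strata too small to contribute a test
key are merged with a warning), with `n_splits` independent 90/10
partitions drawn from seeds spawned deterministically from one master
seed.

Training sets can be augmented with alternative conformers: records whose
absolute shift from the model pKa exceeds 2 units gain up to 10 conformer
copies carrying the original label. Augmentation happens strictly after
splitting and only on training keys, so conformers can never leak a test
residue into training. At desk scale the conformer source is the
generator's jittered-coordinate models; the interface accepts real
structural models unchanged.

## Tree models

Acid and base regressors are trained separately because the same physics
acts with opposite signs: burial and polar crowding stabilize the neutral
(protonated) form of an acid, raising its pKa, but destabilize the
charged (protonated) form of a base, lowering it. A partition guard
refuses to score rows of the other partition.

The gradient-boosting core is delegated to xgboost and the forest
families to ranger behind a single `tree_train_config()` interface with
five family presets (`catboost`, `gbm`, `xgb`, `randomforest`,
`extratrees`). The module owns the protocol: MSE loss on pKa,
hyperparameter selection by 10-fold cross-validated MSE over a small
documented grid (boosting: depth {4, 6, 8} × learning rate {0.05, 0.1} ×
rounds {300, 600}), full-data refit, seed determinism, and one prediction
per (record, structure) pair. `permutation_importance()` provides a
model-agnostic attribution stand-in.

## The graph attention network

Each site becomes an atom graph: nodes are the heavy atoms within 10 Å of
the anchor point, edges connect atoms within 4 Å (covalent bonds and
close contacts; the construction rule is a package choice). Node features
are a 42-wide physicochemical block (residue-type one-hot,
backbone/sidechain flag, formal-charge class, aromaticity, donor/acceptor
flags, four radial anchor-distance bins, the acid/base identity of the
central residue, element group; 37 informative positions padded to 42)
plus a 24-wide atom-type one-hot, total width 66. The regression target
is the pKa *shift*, and one network serves acids and bases — the
acid/base identity is a feature, not a model split.

The architecture is three single-head attention convolution layers with
42 channels and ELU activations, global average pooling, dense layers of
32 and 16 units with dropout 0.2, and a linear output. Because no graph
deep-learning backend exists in the target R environment, the forward
pass, analytic backpropagation and Adam (learning rate 1e-3, early
stopping patience 20) are implemented directly in R and verified against
finite differences in the test suite; training is exactly reproducible
given a seed. Ensembles train k members on rotating 9:1
train:validation folds and average predicted shifts; a
pretrain/fine-tune path continues training from pretrained parameters
with 0–2 leading attention layers frozen bitwise.

Capacity checks (memorizing a small graph set) are run with dropout
disabled, as regularization is deliberately not part of what such a check
measures; all other training uses the 0.2 preset.

## Protonation states and evaluation

The protonation probability of an independent site is the
Henderson–Hasselbalch fraction 1/(1 + 10^(pH − pKa)). Thresholding at
probability 0.75/0.25 gives pKa class boundaries pH ± log10(3), i.e.
6.52 and 7.48 at pH 7 (two-decimal display; classification uses full
precision to avoid double-rounding near the boundaries — the His model
pKa of 6.5 falls *below* the lower boundary 6.5229 and is classed
deprotonated). High pKa at fixed pH means protonated; the package follows
this self-consistent direction throughout.

Regression metrics (PCC, RMSE, maximum absolute error) are computed per
holdout split and reported as mean ± SD over splits. Classification
metrics are **pooled**: predictions from all splits accumulate into one
confusion table first. The two orders differ (a test asserts this on a
constructed counterexample) and the package fixes them as stated. An
instance is scored only when both its experimental and its predicted
class are non-titrating; the critical error rate (CER) is the fraction of
scored instances where a protonated residue is predicted deprotonated or
vice versa. Undefined metrics (a class never predicted) surface as NA,
never 0. The exclusion rule is recorded in every report so alternative
rules can be compared.

## The synthetic generator

`generate_structure()` builds a Gly-X-Gly host tripeptide with ideal
geometry, places single-residue surrogate fragments (Ser hydroxyl,
Glu carboxylate, Arg guanidinium, His imidazole) at planned anchor
distances with a 2.4 Å clash guard, and surrounds the sidechain with a
shell of carbon pseudo-atoms whose occupancy is monotone in the burial
level (candidates in a fixed interleaved order so burial grows gradually
and reproducibly). Planned neighbour counts and key distances equal the
featurized values exactly — a generator/featurizer consistency test.

Labels come from `ground_truth_model()`, a linear shift model whose signs
encode the physics (acid: burial +5, polar count +0.25, His-nitrogen
proximity −0.08 per Å of proximity; base: burial −4, polar count −0.20,
carboxylate-oxygen proximity +0.10), plus N(0, σ) noise, clipped to
[0, 16]. Default σ is 0.3 pKa units, matching a realistic experimental
uncertainty; every fifth site is forced to high burial so at least 10% of
sites carry the >2-unit shifts that exercise the augmentation path. The
generator emulates controllable burial and discrete neighbour chemistry;
it does not emulate folds, cooperative conformational change, or
correlated features of real proteins — passing tests demonstrate that the
pipeline recovers known structure-to-pKa signal, not that real-protein
accuracies transfer.

## Problem sizes and numerical choices

The test-suite and acceptance studies use: 20 splits × 500 keys for the
leakage audit; n = 2000 sites (σ = 0.3) for acid-tree parameter recovery
(holdout RMSE ≤ 0.45, generative feature ranked first by permutation
importance); n = 300 per partition for the sign-opposition
partial-dependence study; 20 graphs for the GAT capacity check (training
MSE < 0.05); smaller smoke datasets elsewhere. These sizes were chosen as
the smallest at which the corresponding statistics are stable.

Other numerical choices: altloc conformers resolve to highest occupancy
(first record on tie); insertion codes are part of the residue key; ties
in permutation importance break by catalog order; quantile strata merge
when too small; xgboost runs single-threaded for bit-reproducibility;
the GAT attention softmax is computed with a global max-shift for
overflow safety.

## Known limitations

* The feature catalog spans the stated accessibility / hydrogen-bond /
  electrostatics / categorical groups but is a package-defined list; a
  different published list can be added as a new catalog version.
* The secondary-structure assigner is a 3-state approximation, not DSSP.
* The GAT is CPU-bound pure R: appropriate for hundreds of graphs, not
  for tens of thousands.
* Synthetic structures are fragments plus occluders, not folded
  proteins; absolute SASA and burial values differ from any particular
  third-party SASA implementation by a method-dependent offset.
* Coupled multi-site titration, Hill coefficients and microscopic pKa's
  are out of scope; each site is treated as independent.
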