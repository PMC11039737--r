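---
title: "Pharmacophore screening with phorescreen: model, matcher and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore screening with phorescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phorescreen)
```

## The model

`phorescreen` implements ligand-based pharmacophore screening around a
five-kind feature vocabulary: aromatic centers (`Aro`), hydrophobic
centers (`Hyd`), H-bond acceptors (`Acc`), donors (`Don`) and metal
ligators (`ML`, atoms able to coordinate a metal such as the heme iron of
the tryptophan dioxygenases hIDO1 and hTDO2). A model feature couples a
boolean *feature expression* over these kinds with a centroid in Å and a
spherical tolerance radius; `|` is OR, `&` is AND and `&` binds tighter,
so `ML|Acc|Don` is a flat alternative while `ML&(Acc|Don)` demands a
metal ligator that is simultaneously an H-bond partner. The built-in dual
hIDO1/hTDO2 inhibitor model (`builtin_dual_model()`) has three `Aro|Hyd`
centers, a non-essential `ML|Acc|Don` point and one tight
`ML&(Acc|Don)` point of radius 0.4 Å; `min_match = 4` together with the
essential flags means a hit may drop only F4.

`geometry_report()` audits the model's internal geometry: five
inter-centroid distances and five apex angles (the angle "F1 with F3 and
F4" is measured at F1 between the directions to F3 and F4; this
convention reproduces the published description of the model from its
coordinates, and is used for all models). Distances are shown to 2 dp and
angles to 1 dp; full precision is kept internally.

## Feature perception

The typing rules behind commercial pharmacophore software are
proprietary, so perception here is an explicit, documented and
overridable rule table (`default_rules()`): aromatic-ring centroids for
`Aro`; aliphatic carbocycles (including cyclopropyl), halogens on carbon
and chains of two or more apolar carbons for `Hyd`; N–H/O–H for `Don`;
lone-pair N and O (excluding amide and pyrrole-type N) for `Acc`; and
carboxyl oxygens, azine nitrogens, thiol sulfur and phenolic oxygen for
`ML`. Rules are named structural predicates over the molecular graph
rather than SMARTS strings: none of the available R chemistry substrates
exposes SMARTS matching with atom maps, and the predicate registry keeps
the same `{kind, pattern, placement}` surface while remaining
serializable (`write_perception_rules()`) and user-restrictable.
Placements of any kind within 0.5 Å are merged into one composite
feature (a hydroxyl oxygen is `Don,Acc`; a carboxyl oxygen `Acc,ML`);
0.5 Å sits above co-location noise but below the smallest model radius,
so merging cannot conflate distinct model features. Molecules are
protonated (explicit hydrogens) before perception because donor detection
requires them; aromaticity is decided by a Hückel-style 4n+2 count on the
Kekulé graph.

Structures come in as V2000 SDF (coordinates used exactly as written;
multi-record files supply conformer ensembles) or as SMILES embedded to
3D with Open Babel's `gen3D` builder. One conversion is run per molecule
so records cannot influence each other; the builder's force-field cleanup
is stochastic and exposes no seed, so *coordinates* may differ between
runs while connectivity, perceived kinds and all 2D descriptors are
deterministic. Every packaged fixture assertion is therefore graph-level,
and geometry-sensitive work (matching, consensus, validation) is tested
on synthetic point-feature sets where determinism is total.

## The matcher

Matching asks whether a perceived feature set can be rigidly placed so
that every matched point lies inside its model feature's tolerance
sphere. The search has two stages:

1. **Correspondence enumeration** (`enumerate_correspondences()`): all
   injective, type-compatible maps of size ≥ `min_match` containing every
   essential feature, pruned pairwise — a mapped pair may distort the
   model's inter-center distance by at most
   `radius_scale * (r_i + r_j) + pair_slack` (slack default 1 Å, a
   completeness/cost compromise guarded by a brute-force oracle in the
   test suite).
2. **Containment fitting**: for each candidate, a proper rigid transform
   placing all matched points within the (scaled) radii is sought. The
   unweighted least-squares (Kabsch) superposition is tried first; if it
   narrowly fails, a tolerance-weighted fit (weights 1/r²) and then a
   minimax polish of max(residual/radius) are tried. The refinement
   matters because the radii are strongly heterogeneous (0.4–1.5 Å): the
   plain least-squares transform minimizes summed squared error, not the
   radius-relative worst case, and rejects genuinely placeable sets whose
   tightest feature (F5) is sacrificed to the loose ones. A hit is a
   statement of *feasibility* — the features can sit in their spheres —
   and the implementation reflects that reading; `superpose()` itself
   remains the classical unweighted estimator.

Only proper rotations are allowed (pharmacophores are chiral; an
enantiomer should not fit by reflection). Among accepted correspondences
the largest wins, ties broken by lowest RMSD of the accepting transform,
then lowest conformer index — an arbitrary but deterministic order. The
fitting score `n/m` counts matched features; with the built-in model a
5/5 fit uses all features and 4/5 means exactly the non-essential F4 was
dropped.

## Consensus model generation

`consensus_model()` emulates consensus feature extraction from an
ensemble of aligned actives: greedy complete-linkage clustering of all
perceived features (deterministic order: ligand index, then feature
index), a candidate joining the first cluster whose members are all
within the clustering tolerance and whose running kind-intersection it
overlaps. Clusters supported by strictly more than `threshold` (default
50%) of distinct ligands become features; support at or above
`essential_threshold` (default 90%) makes a feature essential, and
`min_match` is the number of essentials. The tolerance default of 1.15 is
interpreted as Å — consistent with the magnitudes of the feature radii —
and the derived radius is the cluster's maximal deviation floored at
0.4 Å (the smallest radius the feature vocabulary uses) so degenerate
clusters cannot produce zero-radius features. Conformational alignment
itself is out of scope: the ensemble must already share a frame
(flexible-alignment searches in commercial tools are stochastic and
proprietary); inputs are a multi-record SDF or a feature-set JSON-lines
file.

## Validation statistics

`metrics_from_counts()` computes the six screening statistics from
confusion counts — sensitivity TP/actives, specificity TN/decoys, FPR
FP/decoys, accuracy (TP+TN)/total, PPV TP/(TP+FP), NPV TN/(TN+FN) — as
fractions and percentages (displayed to 2 dp). A statistic with a zero
denominator is reported as undefined (`NA`) rather than 100%: an
internal, actives-only validation legitimately has no specificity. The
complement identities (specificity + FPR = 100%) and the
support-weighted accuracy decomposition are asserted algebraically in the
tests.

## The synthetic benchmark

Because the compound sets behind the original validation are not
published, `make_benchmark()` generates the *statistical shape* of that
design: labeled point-feature sets, by default 56 actives and 207 decoys.
An active places one point per model feature at its centroid plus
isotropic Gaussian jitter (default sd 0.2 Å per coordinate, small
against the radii), samples a random minimal kind set satisfying each
feature expression, drops non-essential features with probability 0.3,
and applies a random proper rigid motion. Decoys keep the generation
pipeline but break one necessary condition each, round-robin across
three modes: `type_scramble` (geometry intact, polar and apolar kinds
swapped so the three `Aro|Hyd` essentials cannot all be served),
`geometry_inflate` (kinds intact, all pairwise distances scaled by 3) and
`feature_deficit` (two essential features deleted). Each mode is
structurally unmatchable against the built-in model, making the expected
confusion table deterministic and the benchmark a calibration instrument
rather than a difficulty estimate. All randomness is seeded at the
benchmark level and provenance is recorded; regeneration is
bit-identical, and generation restores the caller's RNG state.

What passing the synthetic recovery tests shows — and what it does not:
they verify the matcher/validator machinery (high sensitivity at small
jitter, zero false positives on structurally broken decoys, sensitivity
monotone in jitter), but synthetic point sets have no conformational
flexibility, no perception ambiguity and no decoys that are *near*
misses, so they say nothing about enrichment on real libraries. The
named drug fixtures (ten screening hits, packaged as SMILES and verified
against their molecular formulas) cover the molecule-level path
qualitatively: they parse, perceive and pass the drug-likeness filter;
their fitting scores against the single embedded conformer are recorded
but not asserted, since scores depend on the conformer ensemble and the
proprietary typing scheme of the original analysis.

## Drug-likeness filtration

`druglikeness_table()` applies the rule of five (MW ≤ 500, logP ≤ 5,
HBD ≤ 5, HBA ≤ 10; pass with at most one violation, configurable) and
the Veber criteria (rotatable bonds ≤ 10, TPSA ≤ 140 Å², inclusive).
Donor/acceptor counts use the rule-of-five conventions (O–H/N–H
hydrogens; N+O atoms), rotatable bonds are acyclic single bonds between
non-terminal heavy atoms excluding amide C–N, and logP/TPSA come from
Open Babel's atom-contribution models. Thresholds are the canonical
published values; they are exposed as arguments because the original
filtration step did not document its exact settings.

## Problem sizes and numerical choices

The test suite and examples run at desk scale by design: benchmarks of
56/207 feature sets screen in a few seconds; brute-force oracle
comparisons are limited to instances with ≤ 8 perceived features (where
exhaustive enumeration is cheap); the consensus recovery uses 12 ligands
at jitter sd 0.2 Å with F4 dropped in 5 of 12 — mirroring the training
design in which 7 of 12 ligands fit all five features. Numerical
tolerances: containment checks allow 1e−9 slack for floating-point
round-off; superposition agreement with the numeric oracle is asserted at
1e−6; rigid-motion invariance of perception at 1e−6 Å. Degenerate
inputs are defined behavior: empty feature sets match nothing, a
single-pair superposition is a pure translation, collinear triples give
0°/180° angles, and coincident centers raise a degenerate-geometry error.

## Known limitations

* Perception is a documented approximation, not a reimplementation of any
  commercial typing scheme; fitting scores for real molecules are
  comparable within `phorescreen` runs, not across programs.
* No conformational search: conformer diversity must be supplied in the
  input (multi-record SDF). Single-conformer SMILES input will
  under-detect hits for flexible molecules.
* No excluded-volume spheres, no tautomer enumeration, no
  pKa-dependent ionization sampling, and no docking or dynamics — the
  package covers the ligand-based screening and validation stages only.
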