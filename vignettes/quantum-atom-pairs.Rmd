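---
title: "Quantum-informed atom pairs: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-informed atom pairs: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qapair)
```

## The descriptor model

A Carhart-style atom pair is the triple (code~A~, code~B~, *d*): two atom
codes and the topological distance *d* in bonds along the shortest path
between the atoms. Each atom code is itself a triple — the element symbol,
the number of bonded non-hydrogen atoms, and the number of π-bonding
electrons the atom contributes. We count π electrons from kekulized bond
orders as Σ(order − 1) over the atom's bonds, so an aromatic ring carbon
contributes 1 regardless of which Kekulé structure the parser chose (each
ring atom carries exactly one double bond in either assignment; the suite
asserts this invariance on aromatic and alternating-bond spellings).
Hydrogens are excluded everywhere: they carry no code, do not count toward
degree, and never form pairs. Pairs are collected for 1 ≤ *d* ≤ 4 by
default, bounds inclusive; bonded atoms (*d* = 1) are included since
nothing in the pair definition excludes them, and `max_distance` is a
parameter for users who want otherwise.

The quantum enrichment attaches to each pair code aggregates of eleven
quantum-chemical properties computed over a reference database of small
organic molecules (elements restricted to C, N, O, F, S, Cl, Br): dipole
moment (Debye), isotropic polarizability (a.u.), HOMO and LUMO energies,
their gap, zero-point vibrational energy, internal energies at 0 and
298.15 K, enthalpy and free energy at 298.15 K (all Hartree), and heat
capacity at 298.15 K (cal/(mol·K)). For a molecule containing pair *p*
with occurrence count *n*, the molecule contributes its property vector
divided by *n* — once per distinct pair, however many times the pair
occurs. A pair's stored statistics are then:

* **mean** — the arithmetic mean of these occurrence-divided contributions
  over the molecules containing the pair. Each molecule counts once; the
  mean is *not* re-weighted by occurrence count. This is the reading of
  "mean over molecules containing the pair" that keeps the two aggregation
  steps (within-molecule division, across-molecule mean) orthogonal.
* **histograms** — per property, a 10-bin histogram of the same
  contributions, with equal-width bins spanning that pair's observed
  contribution range. Bin edges are stored with the lookup so featurization
  is reproducible. A degenerate range (support 1, or identical values)
  puts all mass in the center bin. Histograms are stored as relative
  frequencies summing to 1 — raw counts would leak the pair's support size
  into the descriptor — with a `hist_mode = "count"` switch for the other
  convention.
* **support** — the number of contributing molecules.

Three descriptor layouts derive from the lookup:

| layout | width | construction |
|---|---|---|
| sumQAP | 11 | Σ over the molecule's pairs of count × mean vector |
| hQAP | 110 | Σ over pairs of count × concatenated histograms |
| spQAP | 11 × #pairs | one 11-value mean block per lookup pair, zero if absent |

sumQAP and hQAP multiply by occurrence count by default, which makes them
additive over disconnected fragments (`count_weighted = FALSE` gives the
unweighted variant). spQAP is presence-gated by default — the block is the
pair's mean vector whether the pair occurs once or five times — because a
sparse positional layout already encodes *which* pairs occur, and the
count-weighted variant is one flag away. With a lookup of 1089 pairs the
spQAP width is 11 979.

## Applicability domain

The enrichment only knows pairs that occur in the reference database, so
the applicability domain is: every pair of the molecule (within
`max_distance`) must exist in the lookup, the molecule must contain at
least one pair, and its heavy atoms must stay within the reference
element set. Molecules with a single heavy atom are out of domain by
decision — their descriptor would be identically zero and carry no
information. `filter_domain()` reports the first failing reason per
molecule (`parse_error`, `forbidden_element`, `no_pairs`, `unknown_pair`)
and guarantees that featurization of the retained subset never encounters
a missing key.

Molecule parsing is delegated to OpenBabel, which is lenient: some
malformed strings (for example unbalanced parentheses) are silently
repaired rather than rejected. "Unparseable" therefore means rejected by
OpenBabel itself. Aromatic input is kekulized by the parser before π
counting.

## Evaluation protocol

`repeated_cv()` reproduces the benchmark protocol: a random forest with
500 trees and `mtry = floor(0.3 · p)` (ranger, single-threaded, seeded),
evaluated by 10-times-repeated 10-fold cross-validation — 100 held-out
evaluations per metric. Repeat *r* draws its fold partition from seed
`random_seed + r`; the forest in fold *f* of repeat *r* is seeded with
`random_seed + 1000·r + f`. Two runs with the same configuration are
bit-identical. Classification folds are stratified by dealing each class
round-robin from a seeded random start, which keeps a 1:12-imbalanced
minority spread to within one molecule per fold; regression folds are a
seeded random permutation.

Regression is scored by RMSE and by R² in both senses — the coefficient
of determination on held-out data (the default, and negative when a model
underperforms the held-out mean) and the squared Pearson correlation
(`pearson_r2`), since the two are frequently conflated in the QSAR
literature. Classification is scored by balanced accuracy (mean of
per-class recalls) and ROC AUC computed from the forest's class-1 vote
fraction, not hard labels. Baselines predict the training mean
(regression) or the majority training class, ties broken toward the
lexicographically smaller label (classification); the classification
baseline emits the training prevalence as its constant probability score.

`relative_metric()` compares two representations fold by fold —
value~A~/value~B~ − 1 on identically partitioned folds, with zero
denominators dropped and counted — and `compare_mannwhitney()` applies a
two-sided Mann–Whitney U test to the two pooled sets of 100 per-fold
values (unpaired; exact null for small untied samples, normal
approximation with tie correction otherwise, which is `wilcox.test`'s
own switching rule).

Reference representations for comparison come from established
implementations where the environment provides them: circular ECFP4-style
bits (4096) and linear-path FP2 bits (1024) from OpenBabel, Carhart pair
counts from ChemmineR, and a whole-molecule property panel from OpenBabel.
Topological torsions have no R-side implementation, so the package counts
canonical 4-atom linear paths labelled with its own atom codes — a
faithful torsion analogue, not a bit-compatible reimplementation of any
particular toolkit's variant.

## The synthetic study system

Real reference databases and benchmark datasets require external
downloads, so the package carries a seeded generator that emulates their
schema and makes every claim testable end to end.

* **Molecules** are grown by random attachment over a fixed element pool
  (C-rich weights: C 0.60, N 0.14, O 0.14, F 0.04, S 0.04, Cl 0.02,
  Br 0.02), single bonds only, up to 9 heavy atoms by default (the usual
  small-organic reference range; the oracle-equivalence suite raises this
  to 12), plus at most one ring closure between atoms 3–5 bonds apart.
  Single bonds keep valence bookkeeping trivial and put all π-electron
  coverage on curated real-SMILES test cases instead.
* **Properties** are additive over pairs by construction: each pair code
  carries an 11-value latent weight drawn once from seeded standard
  normals, and a molecule's property is the occurrence-weighted sum of its
  pairs' weights plus Gaussian noise (sd 0.1 by default). Additivity makes
  sumQAP the correct sufficient feature, so "the forest recovers the
  signal" is a provable property of the pipeline rather than an empirical
  hope, and at zero noise the lookup means converge exactly to the latent
  weights for single-occurrence pairs.
* **Targets**: the regression target is a known *sparse* linear
  combination of the sumQAP features — 3 of the 11 standardized property
  aggregates carry standard-normal coefficients, the signal is scaled to
  unit variance, and noise with sd 0.2 (signal-to-noise ratio 5) is added.
  Sparsity is deliberate: measured endpoints track a small number of
  underlying quantum properties, and the 11 aggregates are strongly
  collinear (the four thermochemical energies nearly coincide), so a dense
  combination over all 11 would describe no realistic endpoint. The
  classification target thresholds the same continuous score at the
  quantile that produces a requested minority:majority ratio (the 1:12
  setting mirrors a strongly imbalanced toxicity panel) and errors if the
  achieved count misses the request by more than 10%.

What the generator does *not* emulate: physically realistic property
values and correlations, multiple rings and aromatic systems, charged or
stereodefined molecules, and activity cliffs. Passing tests therefore
demonstrate that the machinery is correct and the protocol reproducible —
not that QAP descriptors will rank above or below any particular
representation on real assay data.

## Numerical choices and degenerate inputs

* Pair-code order is lexicographic on (element, degree, π), radix-sorted
  for locale independence; the two codes of a pair are stored in that
  order so pair(a,b,d) = pair(b,a,d).
* Histogram binning uses `findInterval` with `all.inside = TRUE`, so the
  maximum value falls in the last bin rather than outside it.
* The variance filter uses the population standard deviation (denominator
  *n*) computed once on the full design matrix before any fold splitting,
  and dismisses strictly below the threshold: a column with sd exactly
  0.05 is retained.
* Lookups serialize to JSON with 17 significant digits, the minimum that
  round-trips IEEE doubles exactly; a load of a save is `identical()` to
  the original and re-serializes byte-identically.
* Multi-fragment molecules enumerate pairs within fragments only (distance
  is undefined across fragments) and warn; cross-fragment distance queries
  return `NA` with a warning rather than a sentinel value.
* Mann–Whitney on two identical constant samples short-circuits to
  p = 1 instead of erroring inside the rank machinery.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at sizes chosen to exercise every code path while keeping a full run
comfortable on one CPU: reference databases of 60–650 molecules,
oracle-equivalence sweeps over 200 molecules of up to 12 heavy atoms, and
full 10×10 cross-validation at n = 500 (regression) and n = 650
(classification, 1:12). Larger reference databases change nothing
structurally — lookup construction is linear in records and pairs.

## Known limitations

* Atom codes ignore formal charge, isotopes and stereochemistry; two
  differently charged forms of the same skeleton share codes.
* OpenBabel's lenient SMILES reader accepts some strings other toolkits
  reject, so domain reports can differ across toolkits at the margin.
* The per-pair histogram bins are data-dependent (per-pair ranges), so
  hQAP vectors from lookups built on different reference databases are not
  directly comparable.
* The torsion reference scheme is this package's own canonicalization;
  absolute widths are not comparable to other toolkits' torsion bits.
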