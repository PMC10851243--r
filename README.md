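# qapair — quantum-informed atom pair descriptors

`qapair` builds and evaluates **quantum-informed atom pairs (QAP)**:
molecular descriptors for QSAR/QSPR modeling in which classic
Carhart-style atom pairs are enriched with aggregated quantum-chemical
properties from a reference database. It is aimed at cheminformaticians
who want pair-based descriptors that carry electronic-structure
information without running any quantum-chemistry calculation at
prediction time.

## The model

An atom pair is `(code_A, code_B, d)`: two atom codes plus the
topological distance `d` (shortest path, in bonds, `1 ≤ d ≤ 4` by
default). An atom code is `(element, heavy degree, π electrons)` — π
electrons counted from kekulized bond orders as Σ(order − 1), so an
aromatic carbon contributes 1 and a nitrile nitrogen 2. Hydrogens never
enter codes or pairs.

From a reference database of molecules with 11 quantum properties
(dipole moment, polarizability, HOMO/LUMO/gap, ZPVE, U(0), U(298),
H(298), G(298), C_v), each pair accumulates per-molecule contributions
`properties / n` (a pair occurring `n` times in a molecule contributes
its property vector divided by `n`, once per molecule). The lookup stores
per pair: the arithmetic **mean** vector over contributing molecules,
per-property 10-bin relative-frequency **histograms** of those
contributions, and the **support**. Three descriptor layouts follow:

* **sumQAP** (11 values): occurrence-weighted sum of pair mean vectors,
* **hQAP** (110 values): occurrence-weighted sum of pair histograms,
* **spQAP** (11 × #pairs values; 11 979 for a 1089-pair lookup): one
  mean-vector block per lookup pair, zero when absent.

Molecules whose pairs are not all present in the lookup — or that contain
elements outside C/N/O/F/S/Cl/Br — are outside the **applicability
domain** and are filtered before featurization. A variance filter drops
descriptors with population standard deviation below 0.05.

The benchmark harness reproduces the evaluation protocol: random forest
(500 trees, `mtry = floor(0.3 p)`, seeded), 10×10-fold cross-validation
(stratified for classification), mean/majority baselines, reference
fingerprints (ECFP4-style circular bits, path fingerprints, classic atom
pairs, topological torsions, a whole-molecule descriptor panel),
per-fold relative metrics, and a two-sided Mann–Whitney U comparison of
per-fold metric distributions.

A seeded synthetic generator produces valence-legal molecules with
pair-additive properties, so the whole pipeline is testable end to end
without downloads.

## Worked example

```r
library(qapair)

spec   <- synthetic_spec(n_molecules = 200, seed = 1)
db     <- generate_quantum_db(spec)           # SMILES + 11 properties
lookup <- build_lookup(db, source = "synthetic-demo")
lookup
#> <qap_lookup> 304 atom pairs (max distance 4, 10 bins, frequency histograms)
#>   source: synthetic-demo (200 contributing record(s))
#>   support: min 1, median 4, max 63

dom <- filter_domain(db$smiles, lookup)
dom$report
#> <domain report> 200 of 200 molecule(s) in domain

x <- featurize_matrix(dom$molecules, lookup, method = "sum")
round(x[1:2, 1:4], 3)
#>      qap_sum|mu qap_sum|alpha qap_sum|homo qap_sum|lumo
#> mol1      0.194        -0.342        0.017       -0.566
#> mol2      0.075        -0.990        1.504       -0.253

task <- generate_task(db, "regression", seed = 2)   # known sparse signal
cfg  <- benchmark_config("regression", n_repeats = 2, random_seed = 42)
rf   <- repeated_cv(task$features, task$targets, cfg, representation = "sumQAP")
rf
#> <cv report> sumQAP (forest, regression, 2x10-fold)
#>   pearson_r2         0.8033  [95% CI 0.7496, 0.8570]
#>   r2                 0.7256  [95% CI 0.6664, 0.7849]
#>   rmse               0.4748  [95% CI 0.3900, 0.5597]

base <- repeated_cv(task$features, task$targets, cfg,
                    model = "baseline", representation = "baseline")
compare_mannwhitney(rf, base, "r2")
#> <comparison> sumQAP vs baseline on r2
#>   mean relative difference: -411.1209 (20 fold pairs)
#>   Mann-Whitney U = 400.0, p = 1.451e-11 (significant at 0.05)
```

Reading the output: the lookup aggregated 304 distinct pairs from the
200 reference molecules; all 200 are in-domain (they generated the
lookup). The forest recovers the synthetic pair-additive target with
held-out R² ≈ 0.73 on 2×10 folds (the full 10×10 protocol at n = 500
reaches ≈ 0.85), while the mean-predicting baseline sits slightly below
zero, and the per-fold R² distributions differ significantly. The huge
relative difference is an artifact of dividing by near-zero baseline
R² values — relative metrics are meaningful between informative
representations, which is how the harness uses them.

A thin command-line front end over the same functions ships in
`exec/qap` (subcommands `synth-db`, `build-lookup`, `filter-domain`,
`featurize`, `benchmark`, `compare`).

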