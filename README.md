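# ionNTCP

Paired dosimetric and NTCP comparison of photon, proton and helium ion
radiotherapy treatment plans from exported dose–volume histograms (DVHs).

Pediatric brain-tumor radiotherapy (the motivating setting is posterior-fossa
ependymoma, 54 Gy in 30 × 1.8 Gy) must balance target coverage against
late sequelae — endocrine dysfunction, hearing loss, neurocognitive
impairment — driven by dose to the pituitary, inner ears and hippocampi.
Scanned helium ions scatter less laterally than protons and promise steeper
dose gradients. ionNTCP provides the analysis toolchain such in-silico
comparisons need, for medical physicists and methodologists:

* a plain-text DVH interchange format with validated curve objects
  (`DVHCurve`, `PlanSet`; cumulative ↔ differential conversions),
* the dosimetric index battery — D<sub>x</sub> quantiles, D<sub>mean</sub>,
  homogeneity index HI = (D₅ − D₉₅)/D<sub>p</sub> × 100, inhomogeneity
  coefficient IC = (D<sub>max</sub> − D<sub>min</sub>)/D<sub>mean</sub>,
  integral dose ID = D<sub>mean</sub> × V,
* Lyman–Kutcher–Burman NTCP via the generalized equivalent uniform dose:
  gEUD = [Σᵢ vᵢ Dᵢ^(1/n)]ⁿ, t = (gEUD − TD₅₀)/(m·TD₅₀), NTCP = Φ(t),
  with a shipped, editable endpoint registry (cochlea/tinnitus 46.52 Gy,
  0.35, 1; cochlea/hearing loss 55.57 Gy, 0.14, 1; pituitary/endocrine
  dysfunction 60.6 Gy, 0.08, 1),
* paired three-modality statistics: per-patient relative differences
  (He vs H⁺, H⁺ vs Ph), low-dose exclusion rules, Friedman test and exact
  Wilcoxon signed-rank post-tests (permutation-exact p-values for small n),
* a seeded synthetic cohort generator (15 patients × 3 modalities × 9
  structures by default) with a voxel-level brute-force oracle validating
  every DVH-derived quantity.

## Worked example

NTCP of a cochlea receiving 54 Gy uniformly, under the tinnitus parameters:

```r
library(ionNTCP)
tin <- defaultLKBParameters()[["cochlea.tinnitus"]]
ntcpFromDVH(uniformDVH(54), tin)
#>   patient_id modality structure endpoint geud      t    ntcp
#> 1       anon   photon structure tinnitus   54 0.4594 0.67703
```

gEUD equals 54 Gy (n = 1: the mean dose), t = (54 − 46.52)/(0.35 · 46.52)
= 0.459, and the modeled tinnitus probability is 68%. A whole cochlea at
exactly TD₅₀ = 46.52 Gy returns NTCP = 0.5 by construction.

The full pipeline on a synthetic default cohort:

```r
res <- runPipeline(cohortConfig(seed = 1), outDir = "comparison_out")
renderComparisonTable(res$comparison_dosimetric)[23:26, ]
#>    structure metric helium       proton       photon       he_vs_pr         pr_vs_ph
#> 23 pituitary Dmean  10.9 ± 1.6   14.6 ± 2.2   18.3 ± 2.7   -25.37 ± 0.48 *  -20.32 ± 0.39 *
#> 24 pituitary D1     14.0 ± 1.6   18.4 ± 2.2   23.1 ± 2.7   -23.94 ± 0.40 *  -20.20 ± 0.33 *
#> 25 pituitary D50    10.9 ± 1.6   14.6 ± 2.2   18.3 ± 2.7   -25.38 ± 0.48 *  -20.32 ± 0.39 *
#> 26 pituitary ID     1.97 ± 0.28  2.63 ± 0.37  3.30 ± 0.46  -25.30 ± 0.51 *  -20.25 ± 0.42 *
```

Cells are mean ± standard error over the 15 patients; contrast columns are
per-patient percent differences with `*` marking Wilcoxon p < 0.05; rows
excluded by the low-dose rule (below 1 Gy in all modalities for more than
five patients, e.g. skin D₅₀) render as `nan ± nan`. `comparison_out/`
receives the generated `.dvh` files, long-format `metrics.csv` and
`ntcp.csv`, per-patient `delta_ntcp.csv` (NTCP<sub>He</sub> −
NTCP<sub>H⁺</sub>), both comparison tables, DVH-overlay and NTCP-boxplot
figures, and a JSON manifest with the seed.

A thin CLI wrapping the same functions ships at `inst/cli/dvhcompare`
(`simulate | metrics | ntcp | compare | run-all`).

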