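# ldsig

Genetic differences between radiation-sensitive and radiation-resistant
mouse strains show up in their tissues before any exposure, and their
transcriptional responses to low-dose (LD, < 10 cGy) ionizing radiation are
strongly nonlinear in dose. `ldsig` implements, as a tested and reusable R
pipeline, the inference chain that links such strain-differential and
LD-responsive mouse transcription to human breast-cancer outcomes:

1. **Graded differential-expression lists** — per-gene Welch t contrasts on
   log2 intensities, listed at |log2 FC| ≥ log2 1.5 with dose-graded p
   cutoffs (p ≤ 0.01 at high dose, p ≤ 0.1 at low dose, p ≤ 0.05 for
   baseline strain contrasts).
2. **Systemic baseline signature** — genes whose strain difference is
   significant, ≥ 1.5-fold, and sign-concordant in *both* blood and mammary
   gland, with the blood-vs-mammary log-ratio correlation r² reported
   descriptively.
3. **Cross-species transfer** — mouse→human ortholog mapping (lossy by
   design), then a per-patient **sum-score** S_j = Σ_i d_i z_ij of the
   z-scored ortholog expressions (optional ±1 directions d_i).
4. **Median-split survival association** — patients dichotomized at the
   cohort median score; Kaplan–Meier product-limit curves per group and a
   two-group log-rank test (hypergeometric variance, tied event times
   handled), both implemented from the formulas.
5. **COA refinement** — per-gene Welch t between above- and below-median
   patients at p < 0.01 yields the cancer-outcome-associated (COA) subset,
   with a directed re-test of the genes that are risk-associated when
   *down*-regulated.
6. **Dose-nonlinearity classes** — `thresholded` (HD response in both
   strains, LD response only in the sensitive strain), `plateau` (equal LD
   and HD magnitudes), `opposite` (sign flip between doses).
7. **Micronucleus statistics** — per-animal MN frequencies per 10⁴ cells,
   baseline strain comparison by unequal-variance t, and dose-vs-sham
   comparisons via a Monte-Carlo Dunnett adjustment inside a pooled
   one-way ANOVA.
8. **Concordance calls** — a gene is cross-species concordant when it is up
   in the sensitive strain, down-or-unchanged in the resistant strain, and
   up in the human comparator set, or the full mirror image.

A seeded synthetic-data generator (`synth_config()`, `gen_mouse_study()`,
`gen_cohort()`, `gen_mn_counts()`, `gen_ortholog_table()`) emulates the
two-strain × two-tissue × {sham, LD, HD} × {4 h, 1 month} design with known
planted structure, so every stage is testable without external downloads.
Plain-text transcriptions of the published COA, overlap, and
thresholded-gene tables ship in `inst/extdata/`.

## Worked example

```r
library(ldsig)
run <- run_all(synth_config(seed = 1))
print(run)
#> ldsig_run (seed 1)
#>   systemic signature: 131 genes, r^2 = 0.972
#>   human orthologs: 102 (dropped 29)
#>   survival log-rank p = 6.45e-12 (control p = 0.777)
#>   COA genes: 102 (18 inverse)
#>   thresholded genes recovered: 28
```

Reading: from 10,000 synthetic genes the pipeline recovers all 131 planted
cross-tissue strain-baseline genes with tightly correlated blood/mammary
ratios (r² = 0.97); 102 of them map to human orthologs under the 28%
mapping loss; patients above the median ortholog sum-score have sharply
worse disease-free survival (log-rank p ≈ 6×10⁻¹²) while a size-matched
least-differential control signature shows no association (p = 0.78); COA
refinement flags the genes driven by the latent risk factor, including the
18 planted with negative loadings (the "risky-when-low" subset); and all 28
planted thresholded genes are classified as such.

## Layout

- `R/` — implementation (data IO, synthetic generators, differential
  expression, systemic signature, ortholog mapping, survival association,
  concordance, micronucleus statistics, pipeline).
- `inst/extdata/` — printed-table fixtures (TSV).
- `tests/testthat/` — unit, property, and acceptance suites with
  brute-force/permutation oracles.
- `vignettes/ldsig-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, and limitations.
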