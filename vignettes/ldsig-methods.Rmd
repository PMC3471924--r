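---
title: "Methods: from strain-differential mouse transcription to human survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from strain-differential mouse transcription to human survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldsig)
```

## The problem

Inbred mouse strains differ widely in their susceptibility to
radiation-induced mammary cancer, and those differences are visible in
tissue transcription before any exposure. `ldsig` provides the statistical
machinery to (i) find genes whose baseline expression separates a
sensitive from a resistant strain *consistently across tissues*, (ii) ask
whether the human orthologs of such a signature stratify breast-cancer
patients by disease-free survival, (iii) characterize how low-dose (LD)
and high-dose (HD) transcriptional responses deviate from dose linearity,
and (iv) analyze micronucleus (MN) frequencies as the genomic-instability
endpoint of the same design. Because the real inputs are external
accessions, the package pairs the analysis code with a synthetic-data
generator that reproduces the *statistical structure* of the design with
known ground truth; packaged fixtures carry the published summary tables.

## Two-group statistics and graded gene lists

All two-group comparisons use Welch's unequal-variance t-test on log2
intensities — one test everywhere keeps gene lists comparable across
contrasts, and the unequal-variance form is the weakest assumption that
still gives a calibrated test at n = 4 arrays per group. Degenerate input
(both groups constant, equal means) returns p = 1 by convention.

Response lists use a fold-change floor of 1.5-fold applied symmetrically
on the log2 scale (|log2 FC| ≥ log2 1.5 ≈ 0.585) with dose-graded p
cutoffs: 0.01 at HD, 0.1 at LD, 0.05 for baseline strain contrasts. The
laxer LD cutoff admits the smaller effects expected below 10 cGy; lists
are inputs to enrichment and concordance analyses, not per-gene claims, so
no multiplicity correction is applied at this stage (Benjamini–Hochberg
q-values are reported alongside for information). `gene_list()` is
monotone in both thresholds by construction.

## The systemic baseline signature

The qualitative idea — genes with "the same relative ratio" of expression
between strains in mammary gland and blood — is operationalized as: the
strain contrast is significant (p ≤ 0.05), at least 1.5-fold, and
sign-concordant in *both* tissues. The exact numeric filter behind the
published 131-gene signature is not recoverable from the source text, so
the thresholds are exposed as arguments and the squared Pearson
correlation of the blood versus mammary log-ratios is reported
descriptively rather than used as a filter. Ratios are oriented
sensitive-minus-resistant throughout.

The negative control takes the k genes minimizing
max(|blood log2 FC|, |mammary log2 FC|), ties broken by the larger
p-value and then by symbol — a deterministic "least systemic difference"
signature of matched size.

## Ortholog mapping

Translation to human gene space is a plain table lookup: lossiness is
data, not an error (the motivating analysis retained 94 human orthologs
of 131 mouse genes). One-to-many mappings resolve to the lexicographically
first human symbol — deterministic and auditable — with an `expand`
option; many-to-one collisions deduplicate with a warning. Mouse symbols
are title case, human upper case, and no case-folding shortcut is taken.

## Survival association

The per-patient score is the sum of the signature orthologs' expression.
Whether the original analysis standardized intensities before summing is
not stated; the default here is per-gene z-scoring across patients, which
makes the sum scale-free (invariant to per-gene affine transforms, a
tested property) — `raw` mode is retained for fidelity experiments.
Optional ±1 directions let the inverse COA subset be scored as a
"risky-when-low" signature.

The median split sends strictly-greater-than-median scores `above`; ties
and the median itself go `below`. The rule is documented because it
changes group sizes on discrete data.

Kaplan–Meier curves use the product-limit estimator over distinct event
times; the two-group log-rank test accumulates observed-minus-expected
events with the hypergeometric variance, which handles tied event times.
Both are implemented from the formulas rather than delegated so that the
tie-handling and the permutation-oracle comparisons in the test suite
exercise *this* code; `survival::survfit`/`survdiff` appear in the tests
as independent cross-checks only. Zero events overall returns p = 1 with
a warning.

COA refinement applies a per-gene Welch t between the above- and
below-median patient groups at α = 0.01 (the published tables' cutoff;
configurable). Genes expressed at lower levels in the above-median group
form the inverse subset, re-tested as a directed signature with −1 signs.

## Dose-response nonlinearity

Classification runs over the four strain × dose contrasts at one time
point, with significance defined by the same graded criteria as the gene
lists:

- `thresholded`: HD-significant in both strains with the same sign, and
  LD-significant (same sign) in the sensitive strain only;
- `plateau`: LD and HD significant, same sign, |LD|/|HD| within [2/3, 3/2]
  — "similar magnitudes" has no published number, so the band is chosen
  symmetric on the log scale and exposed as an argument;
- `opposite`: LD and HD significant with opposing signs;
- `other`: the remainder. `thresholded` takes precedence when a gene
  satisfies both it and `plateau`.

The published magnitude comparison between strains' responses does not
name its test; `magnitude_comparison()` adopts a two-sided paired t on
the |log2 FC| vectors as the natural choice for gene-aligned magnitude
vectors, and this is a package decision, not a source fact.

## Micronucleus statistics

Frequencies are exact per-animal rates per 10⁴ cells scored and are
analyzed untransformed (matching how such data are presented; an
arcsine-square-root option was considered and rejected as unnecessary at
these event counts). Baseline strain gaps are percent differences with a
Welch t. Dose groups are compared against the strain-matched sham inside
a pooled-variance one-way ANOVA with Dunnett adjustment; one family is
fitted per strain × cell class × time point, the finest stratification
consistent with the assay design.

The Dunnett reference distribution — max over k correlated t statistics
sharing the control mean and the pooled error variance — is evaluated by
seeded Monte Carlo (default 10⁵ draws, SE ≤ 0.0016 on a p-value near
0.05) rather than from tables: group means are drawn as independent
normals with variance 1/n_j, the error variance as χ²_ν/ν on the ANOVA
error df, and the statistics assembled exactly as for the data. The
adjusted p is floored at the unadjusted p. `multcomp`'s numeric
integration serves as the oracle in the tests, agreeing within 0.005.

## The synthetic-data generator

`gen_mouse_study()` simulates log2 intensities as independent Gaussian
residuals (SD 0.25 log2 units — typical replicate noise for normalized
arrays) around per-gene baselines, over the full factorial design with 4
replicates per cell, and plants:

- 131 baseline-signature genes with a ±1.0 log2 strain offset applied
  concordantly in both tissues (±1 directions random);
- 28 thresholded, 76 plateau, and 35 opposite-direction genes — subset
  sizes taken from the published counts — with LD effect 1.0 and HD
  effect 1.5 log2 units in mammary tissue at the early time point;
- 105 (sensitive) and 100 (resistant) generic LD-response genes at the
  late time point, half up and half down.

`gen_cohort()` draws patient expression standard normal per gene; each
signature gene loads ±0.55 on one shared latent factor F ~ N(0,1)
(residuals rescaled to unit variance), with 85% of genes loading
positively — mirroring the published COA split of 46 risk-when-high to 9
risk-when-low. Event times are exponential with log hazard log(2.5)·F, so
proportional hazards holds exactly and the sum-score estimates the
planted risk direction without per-gene hand-tuning. Censoring is uniform
on (0, τ) with τ solved by root-finding so the expected censored fraction
is 0.3; n = 159 patients. The default cohort size, hazard ratio and
censoring are calibration choices at the scale of the emulated cohorts,
not published values.

`gen_mn_counts()` draws binomial counts at 20,000 cells scored per animal
and cell class, 6 animals per group: sham rates 27.2 vs 20 per 10⁴
(MN-RET, a 36% gap) and 15.7 vs 10 (MN-NCE, 57%), dose multipliers at the
early sampling times (RET ×5 at HD; NCE ×1.2 at LD, ×3 at HD), and at 1
month all groups revert to baseline except the sensitive strain after HD,
which stays elevated — persistent genomic instability in the sensitive
genotype only.

Every generator consumes a child seed derived from the master seed and
restores the caller's RNG state; the same seed reproduces every byte.

What the generator does *not* emulate: probe-level/array artifacts, batch
and plate effects, estrous-cycle covariates, correlated gene–gene noise
beyond the single latent factor, platform differences between cohorts,
and overdispersion of MN counts beyond binomial. Passing tests therefore
demonstrate that the *statistics* behave as designed under the assumed
models, not that real data meet those assumptions.

## Numerical choices and degenerate inputs

- Welch t with both groups constant and equal means → t = 0, p = 1;
  unequal means → error.
- Median split with all scores identical → error (no split exists).
- Log-rank with zero events → p = 1, flagged.
- Constant gene in z-score mode → contributes 0 to the score, warned.
- Fewer than 3 qualifying signature genes → r² undefined (NA), warned.
- Asymptotic-vs-exact comparisons in the tests allow for the granularity
  of small permutation distributions (70 splits at n = 4 + 4) and the
  chi-square approximation at n ≤ 10 per arm.

## Problem sizes used by the test and acceptance suites

Simulation-backed checks run at: 10,000 genes × 96 arrays for signature
recovery; 1,000 replicates of n = 200-patient null cohorts for log-rank
type-I error; 100 replicates at n = 159 and hazard ratio 2.5 for power;
200 seeds for the negative-control calibration; 1,000 null replicates of
a 4-group design (n = 6) for the Dunnett family-wise error; 4×10⁵
Monte-Carlo draws for the Dunnett oracle comparisons. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands.

## Known limitations

- Gene lists rest on raw graded p cutoffs by design; they are screening
  lists, and the reported q-values should be consulted before any
  per-gene interpretation.
- The survival association is a median-split log-rank, not a Cox model:
  no covariates, no continuous-score inference, and pooling of cohorts is
  simple concatenation.
- The plateau band and the paired-t magnitude comparison are package
  decisions where the source analysis is silent; both are exposed as
  arguments.
- The Monte-Carlo Dunnett assumes the balanced/unbalanced normal ANOVA
  model; it does not model binomial sampling of MN counts directly.
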