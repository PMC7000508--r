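---
title: "Methods: approximating and comparing two breast-cancer expression scores as predictors of neoadjuvant response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: approximating and comparing two breast-cancer expression scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscore)
```

## The question the package answers

Pathologic complete response (pCR) to neoadjuvant chemotherapy is rare in
ER-positive, HER2-negative breast cancer (~8%), which makes a pre-treatment
response biomarker valuable. Two commercial prognostic signatures — the
12-gene molecular score (MS) and the 21-gene recurrence score (RS) — are
both composites of a proliferation module and ER-signaling genes, and both
can be approximated from probe-level microarray matrices. `neoscore`
implements the approximation and the head-to-head comparison: which score,
standardized per cohort, predicts pCR better, alone and jointly?

## From probes to scores

**Input model.** The pipeline consumes already-normalized log2 expression
matrices (probes × samples), a probe→gene annotation table, and a clinical
table (`sample_id`, `cohort`, `er_status`, `her2_status`, `pcr`). Raw-array
preprocessing (RMA of CEL files, bead-level processing) is out of scope;
those are published external procedures and every public deposit provides
their output. A simple-scaling normalization (`scale_normalize()`) is
available for bead-array data: each sample column is shifted so its mean
equals the grand mean — location only, never variance.

**Probe collapsing.** All probes mapping to a gene symbol are averaged with
equal weight (`collapse_probes()`); no variance or cross-hybridization
filtering is applied, because the score algorithms are defined on per-gene
averages and any filtering rule would be an invention. Genes without a
mapped probe are reported as missing, never silently dropped; the decision
of what to do lives with the signature.

**Annotation version.** Probe→gene matching is deliberately an input (a
two-column table) rather than a pinned platform annotation release, since
symbol assignments drift across releases and the right table depends on the
deposit being analyzed.

**Signature definitions.** Both signatures ship as editable YAML configs
(`ms12.cfg`, `rs21.cfg`). The MS is a weighted sum of 8 genes; the RS is a
weighted combination of four gene groups (proliferation, ER, HER2,
invasion; group score = weighted mean of member genes) plus three singleton
genes. The configs carry the published group weights (+1.04 proliferation,
−0.34 ER, +0.47 HER2, +0.10 invasion; CD68 +0.05, GSTM1 −0.08, BAG1 −0.07)
and within-group weights (0.9/0.1 for GRB7/ERBB2, 0.8/1.2/1/1 for
ESR1/PGR/BCL2/SCUBE2). Validation checks structure and sign pattern only,
not magnitudes: per-cohort z-standardization makes every downstream result
invariant to positive affine rescaling of the weights (a tested invariant),
so the clinical-report scalings of either assay (RS 0–100, MS 0–15) are
deliberately not reproduced. For the same reason the assays'
housekeeper/normalization genes are unused — matrices arrive between-array
normalized, making per-sample reference-gene normalization redundant.

**Missing genes.** Grouped genes absent from a platform are dropped and the
group mean renormalizes over the remaining members — the only policy
consistent with "group score = mean of available gene averages" (the real
instance is one proliferation gene absent from one bead-array platform). A
group losing *all* members, or a missing singleton or MS gene, is an error:
at that point the score is no longer the published object.

## The proliferation floor

The RS algorithm floors its proliferation group: values below a threshold
are raised to it, removing discrimination at the low end. Choices pinned
here:

* **Percentile definition**: linear interpolation between order statistics,
  `h = (n−1)p/100 + 1` (`stats::quantile` type 7), the most common
  convention — it must be pinned for reproducibility.
* **Reference population**: ER-positive patients *within each cohort*,
  consistent with everything else being per-cohort. Whether the original
  analysis pooled cohorts for this threshold is not documented; per-cohort
  is the choice that does not mix platforms.
* **Scope**: only the proliferation group is floored. The RT-PCR assay also
  floors its HER2 group on the PCR scale, but no such threshold is
  described for the microarray approximation, so none is applied.
* `p = 0` is the exact identity, and the floor applies to *all* samples
  while being estimated on the reference subset only.

A sensitivity sweep (`sensitivity_sweep()`) re-thresholds, re-combines and
re-standardizes the RS at each percentile of a grid (default 75, 80, 85,
90) and refits all models; the MS has no threshold and changes only through
the combined model.

## Standardization and association

Raw scores are transformed to z-scores within cohort
(`zscore_by_cohort()`), with mean and sample SD (n−1) computed over the
analysis subset — ER-positive/HER2-negative samples with evaluable
response — so that effect sizes are "per 1 SD of the analysis population"
and cohort/platform location and scale cancel. Receptor-status parsing is
permissive on encodings (`P/pos/positive/1`, `N/neg/negative/0`,
case-insensitive) but strict in effect: anything else becomes `unknown` and
never passes the population filter.

Association uses a package-authored IRLS logistic fitter
(`fit_logistic()`) with a pinned numerical contract: Newton steps with step
halving, convergence when the largest score-gradient component is below
1e-10 or the relative log-likelihood change is below 1e-13 (comfortably
inside the 1e-8 gradient accuracy asserted by the tests), at most 100
iterations, Wald covariance from the inverse observed information.
Degenerate inputs fail loudly: single-class outcomes, rank-deficient
designs, suspected perfect separation (diverging coefficients with a
near-perfect classifier), and non-convergence are errors, not warnings. The
test suite checks the fitter against the closed-form 2×2 odds ratio on an
exhaustive grid of tables and against an independent implementation
(`stats::glm`) on random designs, and verifies Wald/likelihood-ratio
agreement away from the α = 0.05 boundary.

Models: single-score `pCR ~ z + cohort` and combined
`pCR ~ z_MS + z_RS + cohort`, cohort as reference-coded dummies with the
alphabetically first cohort as reference (score ORs are invariant to the
reference; pinning it makes reports byte-stable). 95% CIs are
`exp(β ± 1.96·SE)` and p-values two-sided Wald — the convention matching
how such results are reported. No interaction terms, no clinical
covariates (consistently unavailable across public deposits), no
multiplicity adjustment (single pre-specified comparison per model).
Near-collinear scores (|r| > 0.999) are refused in the combined model.

**Response curves.** Predicted pCR probability along the z axis is computed
by marginal standardization: averaging `invlogit(α + βz + γ_c)` over the
observed cohort distribution of the analysis samples. The alternative —
conditioning on a reference cohort — would make the curve depend on an
arbitrary label; marginal standardization gives a population-level curve
and is stated explicitly so the output is reproducible.

**Correlation.** The MS–RS correlation is the Pearson correlation of pooled
per-cohort z-scores (pooling raw scores would be confounded by platform
shifts), with per-cohort values reported alongside.

## The synthetic-data generator

`generate_study()` emulates the structure the analysis assumes, with known
ground truth. Per sample, two standard-normal latent factors — proliferation
`P` and ER signaling `E`, correlation ρ — drive gene expression
(`baseline + cohort shift + load_p·P + load_e·E + N(0, resid_sd)`), each
gene measured by ≥1 probes with fixed seeded offsets plus `N(0, 0.2)`
measurement noise (so probe collapsing is a real denoising step; the fixed
offsets are constant per cohort and cancel under z-scoring). The outcome is
`pCR ~ Bernoulli(invlogit(α_c + β_P·P + β_E·E))`. ER/HER2 status is
independent of expression by default — the percentile floor only needs the
reference subset to *exist* — with an optional mode tying ER positivity to
`E` for realism. A single seed expands into fixed per-cohort substreams, so
adding a cohort never perturbs existing ones.

**Default configuration** (`default_paperlike_config()`), chosen once and
frozen:

* Six cohorts with the published total sizes (178, 278, 115, 279, 486,
  178); ER-positive and HER2-negative fractions 0.72 each and 2.3% missing
  response, so the expected evaluable ER+/HER2− pool is ~764 of 1514;
  per-cohort baselines `α_c` solved numerically (Gaussian integral +
  root-finding) so expected pCR rates match the published per-cohort rates,
  pooling to ~8%.
* Outcome direction `(β_P, β_E)` proportional to the latent loading of the
  MS weight vector — the scenario under study is "response driven by the
  combination the MS measures" — with magnitude set so the true log-OR per
  1 SD of that latent combination is `log(2.2)`. This is stronger than the
  published point estimate (~1.7/SD): the package's stochastic acceptance
  checks require the qualitative joint-model pattern (MS significant, RS
  not) to appear in ≥80% of replicates at pooled n≈764 with ~8% events, and
  at OR ≈ 1.7 the combined-model power is only ~0.6–0.75, which would make
  the *qualitative* property itself a coin flip. The magnitude is a
  stability choice, not a claim about the real effect size.
* Gene noise: residual SD 0.25 on the 8 MS genes (keeping the measured MS a
  high-fidelity readout of its latent combination; measurement attenuation
  of the recovered OR stays ~2%), 0.6 on the RS-only genes and ρ = −0.2 —
  together calibrated so the pooled correlation between the two
  standardized scores lands near the ~0.7 reported for these
  approximations, which also sets a realistic variance inflation for the
  combined model. Housekeepers at 0.2; HER2 genes load on neither factor;
  invasion genes load weakly (0.2) on `P`.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: array artifacts (spatial effects, saturation,
background at the low end of the dynamic range), copy-number or subtype
structure beyond two factors, probe-level cross-hybridization,
gene-specific platform biases, and any dependence of treatment or response
ascertainment on expression. The two-factor model makes ground truth
well-defined but is a simplification: real scores correlate through many
co-regulated modules, not two.

## Numerical choices and degenerate inputs

* Percentile: type-7 interpolation (above); ties need no special rule.
* z-scores: sample SD (n−1); a zero-variance or <2-sample cohort is an
  error naming the cohort.
* IRLS tolerances and separation heuristics as above; the 2×2 grid check
  bounds the worst-case log-OR error at 1e-8.
* Readers are strict: duplicate probe/sample ids, non-numeric or
  non-finite cells (named by probe and sample), fewer than two samples,
  and malformed series-matrix blocks are errors.
* All analysis-path code is deterministic; randomness exists only in the
  generator, governed by the single seed.

## Problem sizes used by the test suite

Unit tests run on fixtures of tens of samples. The stochastic acceptance
checks use: the exhaustive 2×2 grid (30⁴ tables); 1000 random fixtures for
the dot-product oracles; 200 full-pipeline replicates at the default
six-cohort scale for parameter recovery against a 10⁶-sample brute-force
oracle; 1000 replicates at n = 2000 for CI coverage; and 100 replicates for
the joint-model dominance rate and floor sweep. These sizes give
Monte-Carlo standard errors comfortably below the assertion margins while
keeping the default test run in the minutes range.

## Known limitations

* The signature weight configs are transcriptions of the published
  algorithms; only their sign pattern and structure are validated. Users
  with access to assay documentation can edit the YAML configs without
  touching code.
* Scores are unscaled approximations: no clinical-report ranges, no
  risk-category cutoffs. They are suitable for association analysis, not
  for clinical interpretation of individual samples.
* The per-cohort threshold reference and the marginal-standardization
  choice for curves are pinned package decisions where the original
  analysis is ambiguous; both alternatives (pooled reference, reference
  cohort conditioning) would change numbers slightly but not structure.
* Real-data reproduction requires the six GEO series; the package ships
  only their published per-cohort summary counts (`geo_cohort_counts()`)
  and the readers needed to ingest the deposits.
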