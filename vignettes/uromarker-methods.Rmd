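---
title: "uromarker: models, conventions and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{uromarker: models, conventions and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind each pipeline stage,
the defaults and why they have the values they do, the numerical
conventions at edge cases, and the design choices made where more than
one defensible option existed. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The study design being modelled

A four-group urinary proteomics case/control study: the case group DVD
(vascular dementia comorbid with type-2 diabetes, n = 12) against normal
controls (n = 21), T2DM-only (n = 22) and VD-only (n = 14) — 69 subjects,
each measured in two technical replicates. All diagnostic evaluation
contrasts DVD against the 57 pooled others. These group sizes are the
simulator's defaults and the denominator structure behind the ROC lattice:
attainable sensitivities are multiples of 1/12 and attainable
1−specificity values multiples of 1/57.

## Quantification

Label-free protein quantification follows the Top-3 principle: a
protein's abundance in a sample replicate is the mean of its three most
intense peptides, on the argument that the highest-ionizing peptides are
the most reproducible reporters of protein amount.

Choices that were genuinely open:

* **Top-3 statistic.** Mean, not sum (`statistic = "sum"` is available).
  The mean keeps the value on the intensity scale of a single peptide and
  is the common convention of Top-N estimators.
* **Fewer than 3 detected peptides.** The mean of those available is used
  (a 2-peptide protein passes the identification filter and remains
  quantifiable); no intensity is imputed.
* **Normalization target.** Columns are rescaled to the *mean of the
  original column totals* rather than to 1, so abundances keep the raw
  magnitude (~10⁷–10⁹) on which optimal cutpoints are reported.
* **Order of operations.** Normalize per replicate column, then average
  replicates. The reverse order is not distinguishable from the methods
  available; one order had to be fixed for determinism.
* **Zeros in replicate averaging.** A zero replicate participates in the
  mean: after zero substitution a zero is a measurement (non-detection),
  not a missing value.
* **CV definition.** The coefficient of variation is sd/mean over a
  group's nonzero values. The source methods text prints the inverted
  ratio ("mean/SD"), which we treat as a typographical inversion of the
  universal definition; `definition = "mean_over_sd"` computes the
  literal inverse for comparison, and no further intent is guessed.

## Differential expression

Each protein in each contrast is first routed by its **zero pattern**.
With strict majorities ("more than half", > 0.5, so exactly 50% fails
both clauses):

| case nonzero > ½ | control nonzero > ½ | status | p | regulation |
|---|---|---|---|---|
| yes | yes | testable | pooled t-test | by thresholds |
| yes | no (zero > ½) | case_specific | 0 | up |
| no (zero > ½) | yes | control_specific | 0 | down |
| otherwise | | untestable | — | none |

The *untestable* category is our addition: majority-zero in both groups
is covered by neither original clause, and calling such proteins either
way would be arbitrary.

**Fold change** is the ratio of group means *including zeros*;
**the t-test** runs on log2 of the *nonzero* values (log 0 is undefined).
This asymmetry is deliberate and documented rather than hidden: the FC
reflects the full zero-substituted data, the test the detected
distribution. A testable protein is a DEP when p < 0.05 and FC > 1.20 or
FC < 0.83. The t-test is Student (pooled variance) by default — matching
the classic spreadsheet/SPSS-era convention of such analyses — with Welch
behind `var_equal = FALSE`. No multiple-testing correction enters the DEP
decision (the original filter is at raw p); a BH column is emitted for
users who want it. p-values from the zero-pattern rule are recorded as
exactly 0 and excluded from volcano coordinates (−log10 is infinite).

## Marker evaluation

Candidates are common DEPs expressed in all groups (< 50% zeros in every
group, strict) with the same regulation direction in all three contrasts.
Single markers use the protein's abundance as the score; positivity is
"score ≥ cutpoint", and if a marker's AUC is below 0.5 the score sign is
flipped automatically (direction "≤ cutpoint"), with the flip recorded in
the output.

* **AUC** is the tie-corrected Mann–Whitney statistic; on tie-free data it
  equals the trapezoid area under the empirical ROC polygon to 1e−9
  (property-tested).
* **CI**: DeLong's placement-value method by default; Hanley–McNeil
  behind `ci_method = "hanley"`. The method was not stated in the source
  analysis; DeLong is the distribution-free standard.
* **Significance**: two-sided normal-approximation Wilcoxon rank-sum test
  (no continuity correction), i.e. the large-sample z-test on ranks.
* **Optimal cutpoint** minimizes E = (1−Se)² + (1−Sp)²; ties broken by
  higher sensitivity, then lower threshold, so output is deterministic.
* **Composites** fit `label ~ z(a) + z(b)` by maximum-likelihood logistic
  regression and score by fitted probability — monotone in the linear
  combination, hence ROC-equivalent to it, and consistent with composite
  cutpoints lying in (0, 1) near the case prevalence 12/69 ≈ 0.17.
  Separation (fitted probabilities pinned to 0/1) is flagged with a
  warning and the probabilities clamped to (1e−12, 1−1e−12); the row is
  kept because apparent separation at n = 69 is common for strong planted
  effects and the rank-based summaries remain well defined.
* **Panel gating.** The original analysis discards one upregulated and
  all downregulated candidates for "no statistical significance" without
  stating the gate; the CLI's `markers` stage gates panel membership on
  the single-marker Wilcoxon p < 0.05 and reports AUC CI and Se@95%Sp
  alongside, without asserting that this reproduces the original rule.
* Evaluation is **in-sample** (apparent performance), mirroring the
  original report; there is no internal cross-validation.

## Enrichment

One-sided (over-representation) Fisher's exact test, i.e. the
hypergeometric upper tail P(X ≥ k) of the 2×2 table, per term with at
least one population hit. The background population is a required
explicit argument: the original analysis does not state whether its
background was the identified proteome or the annotated genome, and the
choice changes every p-value, so no default is supplied. Corrections:
Bonferroni, Holm, BH (default, at 0.05) and BY; the test oracles recompute
BH/BY/Holm from their step-up/step-down definitions.

## The simulator: a stated world

`simulation_config()` defaults *are* the modelled study, not tuning
knobs:

| parameter | default | rationale |
|---|---|---|
| group_sizes | NC 21, T2DM 22, VD 14, DVD 12 | the study design |
| replicates | 2 | two technical replicates per sample |
| baseline_log2_mean / sd | 27 / 1.5 | raw intensities ~1.3×10⁸, the magnitude of reported cutpoints; ~3 decades of dynamic range |
| within_group_log2_sd | 1.0 | 2-fold typical biological spread, realistic for urine |
| replicate_log2_sd | 0.2 | technical CV ~15%, typical label-free repeatability |
| dep_fraction | 0.10 | a discovery-scale fraction of true changes |
| dep_log2fc_range | [0.5, 3.0] | spans the reported DEP effect sizes (~0.93–2.90), lower bound clears log2 1.20 |
| group_specific_fraction | 0.05 | presence/absence proteins exist but are a minority |
| detection_log2_threshold | 20 | censoring ~7 log2 units below baseline: zeros are rare for average proteins, common in low-abundance tails |
| dropout_rate | 0.05 | stochastic peptide-sampling misses beyond pure censoring |

Intensities are log-normal with left-censoring — label-free MS intensities
are approximately log-normal, and the observed zeros conflate "below
detection" with "absent", so both mechanisms (threshold and random
dropout) are provided. Peptides split protein intensity by flat-Dirichlet
proportions drawn once per protein, making Top-N a consistent
protein-specific-scale estimator. Markers are planted as DVD-upregulated
shifts Δ = √2·σ·Φ⁻¹(AUC) (the equal-variance binormal relation), so a
planted marker is also a planted DEP. All randomness flows from the
single `seed` through one stream in a fixed draw order; identical seed ⇒
byte-identical output (tested).

**What the simulator does not emulate** — and hence what a green test
does *not* establish: correlated proteins (co-regulation, shared
complexes), sample-level batch or loading effects beyond what
normalization removes, heavy-tailed or protein-dependent technical noise,
shared/razor peptides, identification error, and any relationship between
abundance and detectability other than hard thresholding. Recovery rates
on synthetic data are upper bounds on real-data behaviour.

## Calibration results the suite computes

* Null simulation (no effects, no zeros, 2,000 proteins at the study's
  group sizes): fraction of t-test p < 0.05 within 0.05 ± 0.02.
* Planted log2FC at n = 200/group: recovered with mean absolute error
  ≤ 0.1 across planted DEPs. The per-protein sampling SE at this n and
  σ = 1 is itself ≈ 0.1, so the calibrated quantity is the average
  recovery error, not a per-protein bound.
* Planted AUC 0.85 at 500 cases / 500 pooled controls: empirical AUC
  within ± 0.05.
* Planted group-specific proteins at 5% dropout: ≥ 95% classified
  case-specific by the zero-pattern rule against every other group.
* **Recovery through the common-DEP overlap.** At the study's own sizes
  (12 cases vs 14–22 controls) the pooled t-test has ≈ 23% power at
  |log2FC| = 0.5, the bottom of the planted range, so near-complete
  recovery of all planted DEPs is mathematically unattainable in this
  world. The property test therefore asserts ≥ 90% recovery of planted
  effects with |log2FC| ≥ 1 (where power is adequate) and ≥ 60% overall;
  the generator was not altered to force a stronger claim.

## Numerical conventions

* FC with control mean 0 is +∞ (log2fc +∞); both means 0 gives NA.
* Zero pooled variance in the t-test: p = 1 when means agree, p → 0
  otherwise (the limit of the t statistic).
* `wilcox.test` with all scores identical returns NaN; this is mapped to
  p = 1 (a zero-variance rank test carries no evidence).
* ROC thresholds include −∞ and +∞ so the curve always reaches both
  trivial corners; with < 2 members in a class the AUC is still computed
  but the CI is NA and flagged.
* Results tables are tab-separated UTF-8 with "." decimals; round-trips
  preserve labels exactly and numerics to at least 6 significant digits.

## Known limitations

In-sample marker evaluation overstates transportable performance;
composite fits at n = 69 frequently separate; the enrichment stage does
no ontology-graph propagation (annotations are taken as given); and the
quantification makes no attempt at match-between-runs, iBAQ-style
absolute scaling, or censoring-aware imputation — zeros stay zeros, as in
the analysis being modelled.
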