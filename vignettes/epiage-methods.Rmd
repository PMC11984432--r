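---
title: "Methods: epigenetic clocks and age acceleration in epiage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic clocks and age acceleration in epiage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiage)
```

# Overview

`epiage` builds sparse elastic-net epigenetic clocks from RRBS methylation
matrices, derives per-subject age-acceleration measures from leave-one-out
cross-validated age estimates, and relates those measures to behavioral
indicators of aging. This vignette documents the statistical model, every
default parameter and why it was chosen, the calibration of the synthetic
data generator, and the known limitations.

# Data model

The central structure is the `meth_matrix`: a pair of aligned sites × samples
matrices holding the methylation fraction (methylated reads over total reads
at a CpG) and the read depth. A depth of zero is synonymous with a missing
fraction (`NA`); the constructor enforces this invariant, together with
fractions in [0, 1] and unique `chrom:pos` site identifiers.
`read_coverage_files()` assembles one from per-sample Bismark coverage files,
taking the union of sites across samples and recomputing fractions from the
methylated/unmethylated counts rather than trusting the percentage column.

# Site-exclusion cascade

`run_filter_cascade()` applies four filters in a fixed order and reports the
sites each one removes:

1. **Polymorphic positions.** CpGs overlapping known variable positions are
   removed because an apparent methylation difference there may be genotype,
   not epigenetics. Intervals follow BED convention (0-based, half-open), so
   a 1-based site *p* on the same chromosome is excluded iff
   `start < p <= end`.
2. **Mean methylation.** Sites with cohort mean fraction strictly below 0.1
   or strictly above 0.9 carry little usable variance and are dominated by
   measurement noise near the boundaries; sites at exactly 0.1/0.9 are kept.
3. **Mean depth.** Sites averaging fewer than 5 reads are too noisy to trust.
4. **Missingness.** The penalized regression requires a complete matrix, so
   any site with at least one missing value is dropped (no imputation).

The order matters only for the per-step removal counts; the retained set is
order-invariant, and the test suite checks both properties.

# Clock fitting

`epiclock()` z-scores every site using the cohort mean and standard
deviation (sample SD, n − 1), recording the constants so they can be
reapplied verbatim to new samples; a zero-variance site gets scale 1 so the
transform stays defined. The model is an elastic net fit with `glmnet`:

* mixing parameter α = 0.5 (equal ridge/lasso weighting — sparse, but stable
  when informative CpGs are correlated);
* `standardize = FALSE`, because normalization is owned by the package and
  must be reproducible at prediction time;
* penalty λ chosen by internal 10-fold cross-validation minimizing mean
  squared error over a 100-value path spanning four decades
  (`lambda.min.ratio = 1e-4`); ties resolve to the largest (most
  parsimonious) λ;
* an explicit `lambda` argument bypasses CV — the model is then fit along a
  descending path ending exactly at the requested value so warm starts
  stabilize convergence (λ = 0 reproduces OLS to ~1e-6, which the tests
  verify against the normal equations).

The returned `epiclock` object is a classic S3 fitted model with `print`,
`summary`, `coef`, `predict` and `plot` methods, and `write_clock` /
`read_clock` give a versioned plain-text serialization.

## Leave-one-out age estimates

Reporting in-sample fitted ages would be optimistic: each subject's own
methylation helps choose both the normalization constants and λ.
`loocv_clock()` therefore refits the *entire* pipeline — normalization,
CV-driven λ selection, coefficients — once per held-out subject. Each fold
uses a deterministic seed derived from the top-level seed, so results are
exactly reproducible. The leakage property is tested directly: perturbing a
held-out subject's age must not move that subject's estimate.

# Delta age

Two acceleration measures are computed from the LOOCV estimates:

* **Difference:** `epigenetic − chronological`.
* **Residual:** the residual from the cohort-level OLS regression of
  epigenetic on chronological age. This removes the systematic compression
  of clock estimates toward the cohort mean (regression to the mean), at the
  cost of being cohort-relative: residuals sum to zero by construction.

Both are categorized at a ±1-year threshold, with the endpoints assigned to
the outer categories (δ ≤ −1 decelerated, δ ≥ +1 accelerated). Age groups
use half-open five-year bins: juvenile [0, 5), young adult [5, 10), older
adult [10, 15), geriatric [15, ∞).

# Behavioral indicators and models

**Walking speed** is the mean of per-bout speeds (distance/time), requiring
at least 10 bouts; subjects below that are flagged and excluded. The mean of
ratios — not the ratio of sums — weights each bout equally regardless of
length. **Fine motor performance** is the mean raisins-per-second rate over
8 trials (two sessions of four); a trial not finished within the 180 s cap
is scored as raisins retrieved over 180 s (optionally droppable).

Models are ordinary least squares, `outcome ~ sex + rearing + age`, with
treatment coding and female / mother-reared reference levels; subjects of
unknown rearing are excluded. Main-effects ANOVAs use `drop1` F tests
(equivalent to Type II/III sums of squares in the absence of interactions),
with group means, standard errors and Bonferroni-corrected pairwise t tests
on the pooled error mean square. Speeds convert to inches per minute by
× 39.3701 × 60.

# Synthetic data generator and its calibration

The generator is the package's substitute for primate data, and its defaults
were fixed **analytically, before running the pipeline**, from the cohort
structure we aim to emulate; they are study conditions, not tuning dials.

**Cohort.** 140 subjects, ages uniform on [1.17, 19.33] years, 118/140
female, 86/138 nursery-reared with 2 unknown; composition counts are
deterministic (rounded fractions, randomly assigned). An alternative
grouped-age distribution reproduces a 13/49/58/20 split across the four age
groups.

**Biological age.** Each subject carries a latent offset
δ ~ N(0, 1.5²) years; methylation tracks `age + δ`, so the generator knows
the ground-truth acceleration that the pipeline must recover.

**Methylation.** 2000 CpGs: 150 age-informative (baseline U(0.25, 0.75),
slope magnitude U(0.02, 0.04) per year with random sign), 200 invariant-low,
200 invariant-high, 100 polymorphic (Hardy–Weinberg genotype mixtures with
minor-allele frequency U(0.2, 0.8)), the rest stable non-informative.
Observed fractions add N(0, 0.02) noise and binomial sampling at
Poisson(20) read depth (floored at 1); 5% of sites receive missing cells.
The slope range is the one genuinely free effect-size knob; it was set so
that the default clock achieves the regime the package targets (LOOCV
r > 0.9, mean absolute error < 1.5 y), accounting for the attenuation that
binomial sampling and site filtering impose.

**Behavior.** Latent walking speed
`0.70 − 0.009·age + 0.103·male + N(0, 0.098)`, observed as ≥10 bouts with
per-bout noise SD 0.05; latent motor rate
`0.60 − 0.014·age − 0.19·male + N(0, 0.068)`, observed as 8 trials with
per-trial noise SD 0.03. The intercepts and noise SDs were derived in closed
form so that a 129-subject speed study (109 female / 18 male analyzed)
averages ≈ 0.63 m/s with adjusted R² ≈ 0.26, and a 38-subject motor study
(27 female / 11 male) lands near sex means of 0.46 (female) and 0.28 (male)
raisins/s with adjusted R² ≈ 0.73. Problem sizes (129 and 38, and the 200-
and 100-replicate averages in `scripts/acceptance.R`) are the package's own
choice of representative study sizes.

# Reproducibility machinery

Every stochastic function takes a `seed`; `with_seed()` restores the global
RNG state afterwards, so library calls never perturb a caller's stream. The
pipeline derives per-stage seeds as fixed offsets from one global seed
(cohort +1, aging +2, methylation +3, behavior +4, clock +10), which makes
stages independently reproducible: disabling one stage leaves the others'
outputs byte-identical.

# Limitations

* The generator's CpGs are independent given age; real methylation has
  block correlation (co-methylation), which elastic nets exploit. Absolute
  error levels here should not be read as predictions for real RRBS data.
* Linear age trajectories only; real clocks often need log-linear age
  transforms for juveniles.
* The residual delta-age measure is cohort-relative and changes if the
  cohort composition changes.
* LOOCV refits the full pipeline n times; with the default 140 × ~1400
  matrix this takes tens of seconds, and scales linearly in subjects.
* The ANOVA helpers assume homoscedastic errors (pooled-MSE post-hoc
  tests); they do not implement Welch corrections.
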