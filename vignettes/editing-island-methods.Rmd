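---
title: "Methods: simulating and analysing the PDE8A intron-9 editing island"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing the PDE8A intron-9 editing island}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editisland)
```

## The problem

A-to-I RNA editing converts adenosine to inosine in double-stranded RNA;
sequencers read inosine as guanosine, so editing appears as A→G mismatches
against the reference. Intron 9 of human *PDE8A* contains an *editing
island*: a 225-bp stretch with a cluster of edited adenosines, named by
letters (A–N). In whole blood, one site (B) is edited at around 20% while
a handful of neighbours (C–F) are edited at 0.2–0.6%; the remaining
candidate positions stay at sequencing-error background (< 0.05%).
Because several sites can be edited on the *same* transcript, reads carry
co-editing patterns — here called *isoforms*: the set of edited sites on
one molecule, with `NonEdited` for the pattern with no editing. The
site-level editing percentage is by construction the sum of the relative
proportions of all isoforms containing that site.

This package implements the full desk-side analysis around that island:

1. a read/cohort simulator with known ground truth,
2. quantification (alignment → base counts → site calling → per-read
   isoform enumeration → replicate aggregation),
3. clinical severity filtering and group statistics,
4. a random-forest discriminator of suicide attempters (SA) versus
   controls (Ctrl).

Patient blood samples are not publicly deposited, so every analysis here
runs on simulated cohorts whose structure mirrors the published study
design; the simulator is first-class, tested code, and its defaults *are*
the study conditions.

## The simulator

`simulate_reads()` draws reads from an `isoform_distribution`: a read with
pattern *S* carries `G` at the offsets of the sites in *S* and the
reference base elsewhere, then independent per-base substitution errors
(uniform over the three alternative bases) are applied. Reads are
full-length, ungapped, constant quality (Q37): quality trimming and indel
handling are deliberately out of scope, because the quantification
operates on anchored, fixed-length amplicons.

The shipped control distribution is

```{r}
default_control_distribution()
```

calibrated so that site B sits at exactly 20% and the minor sites C–F at
0.2–0.6%, with every multi-site pattern containing B (multi-site isoforms
without B were never observed in blood). Site A and sites G–N carry no
true editing; with the default error rate of 4×10⁻⁴ per base their
*observed* G-percentage is about `error_rate/3` ≈ 0.013%, safely below
the 0.05% background note level. Patient groups are derived by scaling
the whole edited mass — ×0.7 (DEP) and ×0.6 (SA) — with the released
probability moved to `NonEdited`. These factors reproduce the *direction
and ordering* of the published group differences (decrease at B/C/E,
mirrored rise of the non-edited isoform) without inventing unprinted
effect magnitudes; they are configurable in `cohort_config()`.

### Subject-level variability

Two nested sources of biological variability sit between the group mean
and a read:

* an **editing-activity factor** per subject: a lognormal multiplier
  (mean 1, `activity_sdlog = 0.25`) applied to the whole edited mass.
  This models the concerted, island-wide modulation of ADAR activity: all
  site levels move together across subjects, which is what makes every
  pairwise site correlation strongly positive — a plain Dirichlet draw
  alone would leave distinct minor isoforms (and hence site pairs such as
  C/D) weakly *negatively* correlated, contradicting the observed
  correlation structure. The value 0.25 gives a between-subject SD of
  about 5 percentage points at a 20% site, a realistic spread that keeps
  the downstream classification problem non-trivial;
* **Dirichlet pattern jitter** around the activity-scaled mean
  (`concentration = 2000`), guaranteeing valid probability vectors and
  adding pattern-level wobble.

Technical replicates (5 per subject, the study's design) are independent
multinomial draws of `reads_per_replicate` reads (default 2,000) from the
subject's vector. Per-subject variance of editing is not reported in the
source study, so both dispersion parameters are free choices, made once
on biological-plausibility grounds and not tuned afterwards.

Severity scores (MADRS, IDS-C30) are drawn from a shared latent severity
factor per subject with within-group correlation √0.90, rounded to
integers and clipped at 0; group means/SDs are the published descriptive
statistics. Pooled over patients this yields an empirical r² of ~0.89
(rounding and clipping shave a little off the target 0.90). Treatments,
CRP, BMI and substance-use covariates are not simulated — they would be
inert metadata for this pipeline.

## Quantification

`align_reads()` performs anchored, ungapped alignment at offset 0: a read
is accepted when its length matches and its Hamming distance to the
reference *outside candidate offsets* is ≤ 5 (configurable); mismatches
at candidate sites are the signal and never penalised. This replaces
genome-scale alignment, which a fixed single-amplicon design does not
need.

`count_bases()` tallies A/C/G/T/other per position; the editing level is
`100 · G/(G + A)` with C/T/N calls excluded from both numerator and
denominator (`editing_percentage()`), and is reported as missing — never
as zero — when no A or G call is present. `call_sites()` marks a
candidate position as an editing site when its level is **strictly**
above 0.1%; a site at exactly 0.1% does not pass.

`enumerate_isoforms()` classifies each read by the set of passing sites
where it carries `G`. A read with a C/T/N call at any passing site is
excluded from classification (and counted): this keeps the isoform
denominator consistent with the site formula, which likewise ignores
non-A/G calls. Proportions are percentages of classified reads and sum to
100 before any threshold; patterns under the 0.1% inclusion threshold are
flagged `below_threshold` but kept in the table.

Two design points were genuinely open and are resolved as follows:

* **Threshold scope.** Whether the 0.1% thresholds apply per sample, per
  group mean, or cohort-wide is ambiguous. The analysis site set for a
  cohort is fixed on the **control-group mean** profile, so every sample
  shares one feature space; per-sample calls remain available via
  `call_sites()`.
* **Replicate aggregation.** The rule for combining the five technical
  replicates is unstated. `aggregate_replicates()` takes the unweighted
  mean of per-replicate proportions rather than pooling reads: replicates
  are independent library preparations and pooling would weight them by
  depth. The variance-reduction benefit is verified by simulation in the
  test suite (the aggregate's mean absolute error is well below a single
  replicate's; note that the aggregate beats a designated single
  replicate in only ~74% of draws, and the *best* of five replicates more
  often than not — a mean is better on average, not uniformly).

Coordinates are 0-based internally; site letters are the public names and
exported tables carry 1-based positions with the convention stated.

## Group statistics

`filter_analysis_set()` retains all controls and patients with
MADRS ≥ 20 **or** IDS-C30 ≥ 24. The inclusive `≥ 20` (rather than a
strict `> 20`) is deliberate: the moderate-severity bin starts at
MADRS = 20, and only the inclusive boundary reproduces the published
analysis-group sizes (82 DEP, 76 SA, 158 merged MDD) from the printed
severity breakdown. Severity classing (`classify_severity()`) resolves
the "and/or" in the bin definitions by giving MADRS precedence and using
IDS-C30 only when MADRS is missing, which makes contradictory joint
scores deterministic.

`differential_table()` runs, per feature and comparison (Ctrl vs MDD,
Ctrl vs DEP, Ctrl vs SA, DEP vs SA), both the Wilcoxon rank-sum test
(exact for small untied samples, normal approximation with tie correction
otherwise) and Welch's *t*-test, reporting means ± SEM (SD/√n). BH
adjustment is applied across the feature family *within one comparison*,
separately per test; the significance flag uses the adjusted Wilcoxon p
at 0.05, since which of the two tests produced the published asterisks is
not stated — both columns are reported. `welch_t_summary()` computes
Welch from summary statistics (mean, SD, n), which is how printed
demographic rows can be checked; on the age row it gives p = 0.021
(two-decimal 0.02; the printed 0.022 corresponds to Student's pooled *t*,
as the table's own footnote says).

`mean_variation()` is the percent change of a case mean against the
control mean, `100 · (case − control)/control`, the quantity used to
compare blood against the published brain profile; it is undefined (NA)
for a zero control mean. `qpcr_relative_expression()` divides a target
gene's second-derivative absolute quantity by the geometric mean of the
four housekeeping genes (HPRT1, GAPDH, TBP, PGK1).

## The classifier

`split_train_test()` makes a stratified 2/3–1/3 split: per-class train
counts are `round(fraction × class size)` (half up), then the largest
class absorbs the rounding remainder so the overall training size equals
`round(fraction × n)`. For 99 controls + 76 attempters this yields
117/58 — an exact stratified 2/3 split cannot produce the published
125/50, whose construction is not recoverable; the fraction is
configurable. Feature selection (BH-adjusted p < 0.05 in the SA-vs-Ctrl
table) runs on the **training split only**; whether selection preceded
the split originally is unstated, and training-only selection is enforced
here because the alternative leaks test labels (a property the test suite
checks on pure-noise features). With no significant feature the selection
falls back to all features with a warning.

`train_random_forest()` wraps `randomForest` with the published
hyperparameters (mtry = 2, ntree = 1000); a 10-fold cross-validated mtry
grid is available behind `tune = TRUE`. `evaluate_classifier()` builds
the ROC from the forest's class probabilities on the held-out third:
trapezoid AUC, a 95% CI by stratified bootstrap (2000 resamples — the
published interval's method is unstated, so a standard choice is made and
recorded), and the operating point at maximum Youden index, with
sensitivity at fixed 90% specificity reported alongside since the
published operating point's selection rule is also unstated.

## Problem sizes and numerical choices

The shipped defaults simulate 284 subjects × 5 replicates × 2,000 reads.
Sequencing-depth noise at 2,000 reads adds ~0.9 percentage points of SE
at a 20% site, small against the 5-point biological spread; analyses that
probe sampling error specifically (site-B recovery) use 5 × 50,000
error-free reads instead. Tests and the analysis scripts regenerate
cohorts deterministically by seed rather than shipping read files.
Probability vectors must sum to 1 within 1e−9; isoform proportions sum to
100 within 1e−6; Dirichlet components with zero mean stay exactly zero,
so truth tables contain no spurious patterns. Ties in the Youden optimum
take the first optimum on the threshold grid.

## What passing tests do and do not show

The simulator reproduces the *structure* the analysis assumes — one
dominant site, minor companion sites riding on it, concerted island-wide
modulation, replicate structure, severity correlation — not blood
biology. Classifier performance on simulated cohorts (held-out AUC ≈ 0.9
under the default effect sizes) shows the pipeline can recover a
configured group difference; it is not evidence about real patients.
Known limitations: no PCR duplicates or chimeras, no indels or quality
degradation, no SNP-versus-editing disambiguation (no genomic DNA track
exists in an amplicon design), no treatment/covariate effects, and a
single fixed amplicon rather than genome-wide editing detection.
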