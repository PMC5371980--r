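---
title: "Methods: combinatorial marker-panel selection and ROC evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial marker-panel selection and ROC evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combipanel)
```

## The model

`combipanel` addresses a two-class diagnostic problem: given per-sample
signals for N candidate markers (fluorescence intensities, normalized
expression, ...) and a binary case/control label, find small marker subsets
("combinations") that classify well, and quantify how well.

The classification rule is deliberately assay-like rather than model-based.
A *stringency* `D = {thr, minf}` declares a sample positive for a subset C
when at least `minf` of C's markers exceed `thr`. Sensitivity and
specificity of every one of the 2^N − 1 non-empty subsets are then simple
call frequencies (*recognition frequencies*) in the case and control groups.
This has two consequences worth being explicit about:

* SE/SP depend on `thr` in the data's own units. Choosing `thr` is the
  user's responsibility and should reflect the platform's detection limit
  (e.g. mean negative-control signal + 3 SD for a fluorescence array). No
  default is hard-coded.
* With `minf = 1` the positivity events of a growing subset are nested
  unions: adding a marker can only increase SE and only decrease SP. This
  monotone trade-off is a property of the rule, not of the data, and the
  test suite asserts it.

A subset is **gold** when SE ≥ `se_min` and SP ≥ `sp_min`, both inclusive
("at least equal to"). Raising either minimum can only shrink the gold set.

## Assumptions

* Exactly two classes, each non-empty; the positive (case) class is declared
  explicitly or, as a logged fallback, taken as the lexicographically second
  label.
* Markers are numeric on a common meaningful scale for thresholding. If the
  data are log/autoscale/Pareto transformed first, `thr` must be re-chosen
  on the transformed scale — the package fixes the order of operations
  (log, then scaling, with pooled-sample mean/SD and the n − 1 denominator)
  but cannot make a raw-unit threshold meaningful after scaling.
* Samples are independent; no repeated measures, batch or covariate
  structure is modelled.
* Missing marker values carry no information: samples with any missing cell
  are excluded listwise before combinatorial or ROC analysis, with a logged
  count. Imputation was deliberately not implemented, because a positivity
  rule over a subset needs every member defined and silent imputation would
  move SE/SP.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `thr` | data units | none (required) | detection cutoff; platform-specific by design |
| `minf` | count ≥ 1 | 1 | any-member-positive rule; applies to all subsets, so a singleton under `minf > 1` scores SE = 0 (warned) |
| `se_min`, `sp_min` | percent | none (required) | gold filter; inclusive |
| `score` | — | `"glm"` | combination ROC score (see below); `"count"` gives the threshold-rule score |
| `k` | folds | 10 | standard CV granularity; each class must have ≥ k samples |
| `n_perm` | count | 1000 | permutation resolution; the smallest reportable p is 1/(n_perm + 1) |
| `max_markers` | count | 20 | soft cap: enumeration is exhaustive (2^20 ≈ 10^6 subsets); an override flag exists, but panels past ~20 markers belong in a feature-reduction step, not here |

## Numerical and design choices

**Strict exceedance.** "Exceeds the cutoff" is `value > thr` everywhere — a
value exactly at the threshold is negative. The same strictness is used for
ROC thresholds and prediction cutoffs, so the combinatorial stage and the
count-score ROC agree exactly: for `minf = 1`, the ROC point of the count
score at threshold 0 *is* the combinatorial SE/SP pair (tested to 1e−12).

**Combination score for ROC.** A subset has no natural one-dimensional
score, and different constructions give different AUCs. The default is the
predicted case-probability of a binomial (logit) GLM on the member markers,
fitted to the data being scored (or, under cross-validation, to the training
fold only) — the standard way to combine a handful of continuous markers.
The alternative `count` score is the number of members above `thr`, which
stays on the assay's own terms but is coarse (at most |C| + 1 distinct
values). The choice is isolated behind one argument, and reported AUCs are
therefore tied to the declared score construction — only gold-set
*membership*, which never uses the score, is construction-free. If the GLM
does not converge (e.g. complete separation), the linear predictor at the
last iterate is used with a warning: ROC analysis needs only the ordering,
which the linear predictor preserves.

**ROC construction.** Thresholds are the unique score values plus sentinels
above the maximum and below the minimum, so every curve runs from (0, 0) to
(1, 1); the AUC is the trapezoidal integral, which the suite checks against
an independently coded tie-corrected concordance count (and against pROC).
Constant scores give the degenerate diagonal with AUC 0.5. The optimal
cutoff maximizes Youden's J = SE + SP − 1; ties are broken by higher SP,
then by the lower cutoff value. J and SP are compared after rounding at the
10th decimal, because equal rational operating points (e.g. 1/3 + 1 vs
2/3 + 2/3) otherwise differ by float noise and the tie-break would be
decided by rounding error rather than by the stated rule.

**Enumeration order and naming.** Subsets are ordered by size, then
lexicographically by member names, and numbered "Combo I", "Combo II", ...
in that order. The numbering is assigned to the *full* enumeration (and is
therefore stable under any later filtering); the gold table carries the same
IDs, so membership is always traceable. Numbering only the filtered list
would make IDs depend on the filter settings.

**Cross-validation.** Folds are class-stratified (within each class, shuffled
round-robin assignment): with unbalanced designs such as 23 vs 30, plain
random folds can contain a single class, leaving AUC undefined. Performance
is the unweighted mean of per-fold AUCs, not the AUC of pooled scores. A
single k-fold pass is performed per call; repeated CV can be had by calling
with different seeds.

**Permutation test.** Labels are permuted, the score model refit and the
AUC recomputed — so the null distribution includes the refitting optimism,
which is exactly the overfitting the test is meant to expose (its mean sits
above 0.5 for flexible scores on small n; this is correct behaviour, not
bias in the test). The p-value uses the add-one estimator
(1 + #{null ≥ observed}) / (1 + n_perm), which is never zero and is
super-uniform under the null — a property the suite verifies empirically
over 100 replicate null datasets.

**Determinism.** Every stochastic routine (fold assignment, permutations,
simulation) takes an explicit integer seed and restores the caller's RNG
state afterwards; identical seeds give identical results to the byte.

## The synthetic-data generator

`simulate_marker_data()` emulates a serological screen: a tight log-normal
background for controls (location `log(300)`, scale 0.35 on the log scale —
so a cutoff of 450 units, the "mean background + 3 SD" convention, is rarely
exceeded) and a higher, much more dispersed case signal (location
`log(700)`, scale 0.9, reflecting heterogeneous patient responses), with
equicorrelation 0.2 between markers and a detection floor of 50 units
clipping the left tail. Default dimensions are 40 cases vs 130 controls and
5 markers. These defaults were fixed once, from the threshold convention and
typical screening-cohort shapes, and give the workflow realistic behaviour:
single markers pass a specificity filter easily but lack sensitivity, larger
combinations gain sensitivity at a specificity cost, and a minority of the
31 subsets end up gold at a 40%/80% filter.

What the generator does **not** emulate: assay saturation at the top of the
dynamic range, plate/batch effects, heavy-tailed outliers beyond the
log-normal, class-dependent correlation structure, or RT-qPCR Ct error
structure. Tests passing on this generator therefore demonstrate the
correctness of the *computations* (counts, frequencies, integrals,
partitions, p-value calibration) — they do not certify performance claims on
any real assay.

## Problem sizes used by the test and acceptance runs

The suite exercises panels of 1–12 markers (oracle comparisons use 6),
cohorts of 20–200 samples for statistical properties, one 10^4-per-class
run for the generator's law-of-large-numbers check, and 100 replicate null
datasets with 59 permutations each for p-value calibration. The acceptance
script uses the default 170-sample, 5-marker simulated screen with a
200-permutation test. These sizes keep the full suite fast while leaving
every property's Monte-Carlo error well inside its asserted tolerance.

## Known limitations

* Exhaustive enumeration is exponential by design; the tool is for
  pre-screened candidate panels, not profiling data.
* Only two-class problems; multi-class subtyping needs a different design.
* Reported combination AUCs depend on the declared score construction (see
  above); gold-set membership does not.
* No partial AUC, no confidence bands on ROC curves, no bootstrap
  validation, no nested CV for tuning — the GLM score has nothing to tune.
* Listwise exclusion of incomplete samples can shrink small cohorts
  noticeably; the exclusion count is always logged.
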