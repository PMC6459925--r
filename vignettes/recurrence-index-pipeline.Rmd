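---
title: "Building serum miRNA recurrence-predictive indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building serum miRNA recurrence-predictive indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRecur)
```

## The problem

After radical surgery for biliary tract cancer (bile duct, gallbladder and
ampullary carcinomas), roughly half of patients relapse, and the established
serum tumour markers (CEA, CA19-9) discriminate future relapsers poorly at
the pre-operative draw. Circulating microRNAs measured on serum miRNA
microarrays are candidate noninvasive predictors: a panel of ~2565 miRNA
probes can be profiled from a few hundred microlitres of serum at several
clinical time points — before surgery, after surgery, and at recurrence (or
the last observation for patients who do not relapse).

miRecur implements, as reusable and tested components, the complete analysis
chain that turns such raw probe intensities into a *recurrence-predictive
index*: a small linear score over a handful of miRNAs with a decision
cut-off, validated against recurrence-free survival (RFS) and overall
survival (OS).

## Normalization chain

Serum arrays need aggressive normalization because the biological signal is
multiplicative while scanners add background and per-array scale. The chain
(`normalize_signals()`) applies, in order:

1. **Presence calls and background subtraction** (`background_correct()`).
   Each array's detection floor is the mean of its negative-control probes
   after removing the top and bottom 5% ranked by intensity
   (`negctrl_floor()`; `ceiling(trim * n)` probes per tail, ties broken by
   probe order). A miRNA is called *present* only if its signal strictly
   exceeds the floor ("more than", not "at least"); present signals have the
   floor subtracted, absent ones are set to 0 and masked undetected.
2. **Quantile normalization** (`quantile_normalize()`, backed by
   `limma::normalizeQuantiles(ties = TRUE)`). All arrays are forced onto the
   across-array mean of sorted value vectors; ties within an array receive
   the mean of the quantile values they span. Undetected cells enter the
   ranking as zeros — excluding them would leave arrays with unequal vector
   lengths — and are re-floored to 0 afterwards so the container invariant
   *undetected ⇒ value 0* holds. Note that with ties (and differing numbers
   of zeros per array) the tie-averaging rule makes exact idempotence and
   the exact equal-sorted-vector postcondition unattainable; both hold to
   1e-12 on tie-free, fully detected arrays, which is how the test suite
   checks them.
3. **Internal-control scaling** (`internal_control_scale()`). Each array is
   divided by the ratio of its mean internal-control signal (47 preselected
   serum-stable miRNAs in the default design) to a *preset value*. The
   vendor pipelines never disclose their preset constant, so the default is
   the grand mean of the per-array internal-control means — this makes a
   batch self-normalizing while `preset_value` can be fixed for cross-batch
   comparability.
4. **log2 transform** (`log2_transform()`, pseudo-count 1). The downstream
   t-tests and discriminant fits operate on log2 values by default
   (`normalize_signals(..., log2 = FALSE)` gives the linear scale). The
   scale the original analyses used is not documented; log2 was chosen
   because coefficient magnitudes around 0.2–0.5, as in the published
   indices, are natural for log-scale serum data with a dynamic range of a
   few units, and because paired differences are closer to Gaussian there.

## The candidate-selection funnel

`run_funnel()` applies four successive filters, each configurable via
`funnel_config()`:

1. **Detection** (`filter_detected()`): keep miRNAs present (value > 0) in
   "most" pre-operative samples. *Most* is formalized as a fraction
   ≥ `detection_fraction`, default 0.5 — the weakest majority reading —
   and exposed as a knob; at the boundary (11 of 22) a miRNA is kept.
2. **Paired pre/post change** (`paired_prepost_test()`): two-sided paired
   t-test on per-patient (pre − post) log2 differences, split by sign into a
   *pre-high* pool (higher before surgery) and *pre-low* pool. The default
   α = 0.05 is applied per test with **no multiple-testing correction**,
   matching funnels that report raw significant counts; a Benjamini–
   Hochberg option (`p_adjust = "BH"`) is available but off by default.
   Zero-variance difference vectors have no defined p-value; they are
   flagged degenerate and treated as non-significant rather than dropped
   silently.
3. **Prognostic relevance** (`median_split_logrank()`): patients are split
   at the median of the miRNA's pre-operative values — values **equal to
   the median go to the high group**, a convention fixed so even cohorts
   split 50/50 reproducibly — and the two RFS curves are compared by
   log-rank at α = 0.05.
4. **Trajectory classification** (`classify_trajectory()`): the qualitative
   recurrence pattern (up-markers fall after surgery and re-rise at
   recurrence; down-markers mirrored) is formalized as a three-part rule:
   (a) relapsers' medians fall then rise by more than `trajectory_margin`
   (default 0); (b) at least `trajectory_majority` (default 0.5) of
   relapsers individually show the pattern; (c) that fraction exceeds the
   non-relapser fraction. The published description is qualitative, so this
   rule is a reconstruction and every constant is configurable.

Each stage returns a subset of the previous stage's survivors; the
`funnel_report` records sets, counts and p-values so the funnel diagram can
be reconstructed from a run.

## Fisher discriminant indices

`fit_flda()` computes the Fisher direction \(w = S_w^{-1}(\mu_{rec} -
\mu_{non})\) from the pooled within-class covariance. Because Fisher
directions are defined only up to positive scaling, a reporting convention
is required: \(w\) is scaled to unit Euclidean norm, oriented so relapsers
score higher, the intercept anchors the projected grand mean at a reference
score (default 0), and the decision cut-off \(\tau\) is the midpoint of the
projected class means. Scores at or above \(\tau\) predict recurrence — the
published indices use the same ≥ rule. Published index formulas use their
own (undocumented) scaling, so numeric coefficient equality is not expected;
member identity, sign pattern, and classification behaviour are the
meaningful comparisons. The printed formulas themselves ship as
`published_indices()` and arbitrary formulas can be built with
`index_model()` and applied with `apply_index()`.

Near-singular within-class covariances (condition number above 1e12) get a
ridge \(\lambda I\), \(\lambda = 10^{-6}\,\mathrm{tr}(S_w)/p\); with
`ridge = FALSE` such fits abort naming the offending members.

`exhaustive_search()` fits every nonempty candidate subset up to
`max_size`, refusing more than 20 candidates (2^20 subsets is where
exhaustive stops being sensible). Ranking is training accuracy, ties broken
by higher AUC, then fewer members, then lexicographic names — fully
deterministic and invariant to candidate order. Evaluation is apparent
(training-set) performance, matching the original small-cohort analysis;
`roc_auc()` is the Mann-Whitney pair-counting AUC with ties counting ½.
Clinical comparator covariates are dichotomized by `dichotomize_covariate()`
(Youden-optimal scan over midpoints, ties toward the lower cut-off, or a
fixed clinical threshold such as 37 U/mL CA19-9 / 5 ng/mL CEA).

## Survival analyses

Kaplan-Meier estimation, the log-rank test and Cox proportional-hazards
models are delegated to the `survival` package behind thin, validating
wrappers (`km_fit()`, `logrank()`, `cox_fit()`), with Efron handling of
tied event days (day-resolution data tie often; Efron is the less biased
standard). RFS is days from surgery to recurrence or censoring at last
observation; OS to death or censoring. The multivariate Cox model admits
covariates whose univariate hazard ratio is ≥ 2 (`multivariate_select()`,
threshold configurable). Perfect separation (a covariate that splits
events completely, common at n = 22 with a strong index) is flagged and its
confidence interval reported unbounded rather than pretending the Wald CI
is meaningful.

## The synthetic cohort

Because the deposited array series cannot ship with a package and
per-patient survival may not be deposited at all, `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes, with
exported ground truth for parameter-recovery testing. Defaults mirror the
study design: 22 patients × 3 time points = 66 arrays, 13 relapsers, 2565
miRNA probes including 47 internal controls, 100 negative controls, four
planted up-markers and two down-markers carrying the published miRNA names.

Signals are built on the log2 scale — per-probe baselines N(4.5, 2.5²) for
ordinary probes, N(8, 0.5²) for internal controls, N(7, 0.5²) for planted
markers, N(0, 0.5²) measurement noise — then exponentiated, multiplied by a
per-array log-normal scale factor (sdlog 0.3) and given additive
right-skewed (log-normal) background with mean 30 and sd 15, the
multiplicative-plus-background structure the normalization chain assumes.
Negative controls carry background only; internal controls receive no group
or time effect, which is what makes ratio standardization valid.

Planted effects: up-markers add 1.5 log2 units to relapsers at all time
points (the pre-operative group difference), drop by 1.0 after surgery and
re-rise at the final draw for a `trajectory_concordance = 0.9` fraction of
relapsers; non-relapsers re-elevate spuriously with probability 0.1,
reproducing the observation that some non-relapsers re-elevate without
relapse. Down-markers are mirror-imaged. No effect-size estimates were
published for the six miRNAs (the original figures are graphical), so 1.5 /
1.0 log2 were chosen once as effects a serum qPCR validation could
plausibly confirm and are **not** tuned; at the 22-patient design they give
a strong but not always perfect funnel, and at n ≥ 100 recovery is
essentially certain, which is what the test suite asserts.

Survival: relapsers draw RFS from an exponential with mean 365 days
(hazard `rfs_rate = 1/365`), inverse-CDF-truncated to the 1454-day
follow-up horizon, all observed; non-relapsers are censored at the horizon
±15%. OS adds an independent exponential post-recurrence survival (mean
500 days) for relapsers, preserving RFS ≤ OS by construction. The paper
gives no OS model; this is the simplest structure consistent with the
cohort table's invariants.

What the simulator does **not** emulate: probe sequence content and
cross-hybridization, exosomal vs protein-bound miRNA compartments,
batch/chip spatial effects, non-exponential (e.g. cure-fraction) hazards,
and correlated miRNA co-expression modules. Passing parameter-recovery
tests therefore shows the pipeline correctly inverts its own generative
assumptions — not that real serum data satisfy them.

## Numerical conventions and degenerate inputs

* Presence calls are strict (`>` floor); scores classify with `>=` cut-off.
* Median splits send values equal to the median to the high group.
* Detection boundary is inclusive (`>=` detection_fraction).
* Zero-variance paired differences, unsplittable (constant) miRNAs,
  constant covariates, event-free log-rank inputs and Cox separation are
  all flagged and propagated, never silently dropped or imputed.
* Model files are versioned JSON written at 17 significant digits, enough
  for a bitwise double round trip.
* The pipeline seed feeds every stochastic stage through per-stage derived
  seeds (`stage_seed()`), so reruns are identical and stages are
  independently reproducible.

## Problem sizes used by the test suite

Unit tests run on reduced panels (100–400 probes, 10–100 patients); the
property suite uses 20-seed parameter-recovery runs at 200 patients with
the full 2565-probe panel, 10⁴-permutation log-rank oracles on 12-patient
toys, 3·10⁵ random directions for the Fisher-criterion brute force, and
n = 500 exponential cohorts for hazard-ratio recovery. These sizes were
chosen so the whole suite exercises every statistical claim in minutes on a
single CPU while keeping Monte-Carlo error well below the asserted margins.

## Known limitations

* Training-set (apparent) performance only by default, as in the original
  analysis; with 22 patients and an exhaustive search over 63 subsets the
  reported accuracies are optimistic. Honest error estimates need external
  validation or cross-validation on top of this pipeline.
* The trajectory stage is one admissible formalization of a qualitative
  description; the exact criterion that took the original 29
  RFS-significant miRNAs to 6 candidates is not recoverable from the
  publication.
* The GEO reader handles the series-matrix text format only (no CEL files,
  no supplementary raw archives) and does not download; time-point wording
  must be mapped through an editable vocabulary table
  (`geo_time_point_map()`), and deposited series may lack the per-patient
  survival columns the later funnel stages need.
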