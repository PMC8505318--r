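---
title: "Methods: salivary small-RNA prognosis of persistent post-concussion symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salivary small-RNA prognosis of persistent post-concussion symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

After a mild traumatic brain injury (mTBI, concussion), most children and
young adults recover within three weeks, but roughly a quarter to a third
develop persistent post-concussion symptoms (PPCS): symptom burden that
remains above the range seen in non-injured peers at 21 or more days
post-injury. The best validated clinical prediction rule — the Zemek
12-point risk score — reaches an AUC of only about 0.68, so an objective
biologic adjunct is attractive. Salivary small non-coding RNAs (miRNA,
snoRNA, piRNA) change after brain injury and can be collected
non-invasively at the point of care.

`ppcsrna` implements, end to end and with synthetic data throughout, an
analysis pipeline for this setting: a longitudinal cohort and count-matrix
simulator, sequencing-count preprocessing, symptom-based outcome labeling,
clinical comparator scores, negative-binomial differential expression,
three-stream machine-learning feature selection, prognostic and recovery
classifiers with evaluation-set threshold tuning, and ROC inference
(DeLong comparisons, Hanley–McNeil AUC power). No real cohort data ship
with the package; every analysis runs on data the package itself
generates, which makes each stage testable against known ground truth.

# The synthetic cohort generator

`sim_config()` / `generate_cohort()` emulate the design of a longitudinal
mTBI biomarker study:

* **112 participants aged 8–24**, of whom 28.6% (32) are PPCS-designated.
  Allocation is *exact* by default (`round(n * prevalence)`), not
  binomial, so small-cohort accounting is stable; binomial allocation is
  available behind `exact_allocation = FALSE`.
* **About 4.5 samples per participant (~505 total)**: two guaranteed
  samples in the initial window (≤ 14 days post-injury), one guaranteed
  follow-up (≥ 21 days), and extras spread over days 3–60.
* **Symptom trajectories.** The expected 22-item PCSS total decays
  exponentially, `baseline * exp(-days / tau)`, with the time constant
  `tau` drawn around 7 days for non-PPCS and around 45 days for PPCS
  participants, and a higher expected baseline for the PPCS group. Any
  monotone decay family with a group-specific rate would serve; the
  exponential is the simplest that reproduces smooth group-divergent
  decay. Item scores are binomial(6) draws around item-weighted shares of
  the expected total; headache carries the largest weight, followed by
  difficulty concentrating and fatigue. Because item noise is binomial,
  realized labels near the threshold can flip: the symptom-derived PPCS
  label agrees with the latent designation for roughly 95–98% of
  participants, not 100%.
* **Functional scores.** Eight body-sway stances (TLEO … TSECFP) and four
  reaction-time tasks (SRT1, PRT, GNG, SRT2), all "lower = better".
  Initial scores are drawn from one distribution shared by both groups —
  no planted initial group effect, matching the observation that balance
  and cognition do not separate the groups acutely. From day 21 onward,
  non-PPCS participants improve by a per-test mean improvement that
  exceeds the test's minimal detectable change for TLEO, TLEC, SRT1, PRT
  and SRT2, while PPCS participants stay static in expectation.
* **Counts.** Per-feature baseline abundances are log-normal; counts are
  negative binomial with a single shared size parameter (default 5,
  i.e. dispersion 0.2 — typical for bulk small-RNA data) around
  `library_size × abundance`, with log-normal library-size variation
  (CV 0.2). Planted effects multiply the mean by `2^log2FC` for PPCS
  samples, by `2^(slope · days)` for time trends, or by
  `2^(log2FC · item/6)` for symptom-item effects. The default effect set
  plants 16 group-effect features (7 miRNA, 1 snoRNA, 8 piRNA at
  |log2FC| = 1.5) — the scale of the prognostic panel — plus 12 miRNAs
  with a −0.02/day trend, echoing the dominance of days-post-injury
  associations in the correlation scan.
* **What the generator does not emulate:** real miRNA sequence biology,
  participant-level expression random effects (samples are conditionally
  independent given the design), batch effects, and missing-data
  patterns. Passing tests therefore demonstrate correct machinery and
  calibrated statistics under the stated model, not performance on real
  saliva data.

Where the underlying study does not state a value (symptom item weights,
functional-test means and SDs, library size, control symptom
distribution), we fixed one realistic choice, documented above, and did
not revisit it.

# Preprocessing

The stage order is fixed: **cluster → filter → normalize → transform**,
and the pipeline refuses non-integer input so already-processed matrices
cannot be processed twice.

1. **piRNA clustering into wiRNAs.** Highly similar piRNA sequences are
   collapsed: pairwise global-alignment identity (matches / alignment
   length, unit-cost global alignment with end gaps penalized),
   hierarchical clustering on `1 - identity`, cut at `1 - threshold`.
   Defaults — single linkage at 0.90 identity — make clusters the
   connected components of the ≥ 0.90-identity graph; both knobs are
   exposed because the underlying method was described only as
   "hierarchical clustering". Counts within a cluster are summed
   (per-sample piRNA totals are conserved exactly) and renamed
   `wiRNA_k`; non-piRNA rows pass through untouched.
2. **Low-abundance filter.** A feature is removed iff its counts summed
   over all samples fall below 0.01% of the summed counts of its RNA
   category — aggregate, per-category filtering, reading "total reads
   per RNA category" as category-level totals.
3. **Total sum scaling.** Each sample's counts are divided by the
   sample's total over retained features, giving one compositional
   vector per sample (TSS over all categories jointly; a per-category
   variant would be a one-line change but is not the default).
4. **Inverse hyperbolic sine.** `asinh(x) = log(x + sqrt(x^2 + 1))`
   applied to the proportions directly, with no pre-scaling constant.
   Proportions are below 1, so the transform operates in its
   near-linear regime; it is kept because it is the stated transform,
   defined at zero, and monotone — downstream ranks and classifier
   margins are unaffected by the regime.

# Outcome labeling and data splitting

The PPCS threshold is the smallest integer strictly above the upper 95%
confidence limit of the mean control PCSS total,
`mean + 1.96 · sd / sqrt(n)` (normal quantile; at n = 170 the difference
from a t quantile is negligible). The reference control summary
(mean 3.5, sd 4, n 170) gives 4.101 → threshold 5. A participant is PPCS
iff the PCSS total of their *earliest* report ≥ 21 days post-injury
meets or exceeds the threshold ("score ≥ 5" — we resolve the
greater-than-versus-at-least ambiguity in favour of ≥, the Methods-style
statement); later reports never change the label. Participants with no
follow-up report are excluded with a reason code.

Samples are split 58% / 23% / 19% into training / evaluation / testing,
stratified by age bin (8–12, 13–18, 19–24 — the Zemek age bins plus an
adult extension), sex, and label, using largest-remainder rounding within
each stratum. At most five samples per participant may enter the training
set, and likewise the testing set; the excess moves to the evaluation
set. The split is performed once, under one seed.

# Clinical scores

* **PCSS**: total (0–132) plus per-category means (10 physical, 4
  cognitive, 4 emotional, 4 sleep items — the category map ships as an
  editable CSV), which normalizes for unequal item counts.
* **Modified Zemek 12-point risk score**: nine predictors, 0–2 points
  each, from an editable YAML table. Ages above the published 5–18 range
  score 0 on the age predictor (this cohort extends to 24); the
  tandem-stance predictor is replaced by the PCSS "balance problems"
  item; a PCSS-item predictor counts as present at item score ≥ 1 (no
  severity cut-off is published). Prior concussion scores only with
  prior symptom duration ≥ 1 week; missing optional fields score 0 with
  a warning.
* **Minimal detectable change**: `SEM = sd · sqrt(1 - ICC)`,
  `MDC95 = 1.96 · sqrt(2) · SEM`; a follow-up change within MDC95 is
  "unchanged", larger changes are "improved"/"worsened" under the
  lower-is-better convention.
* **Group comparisons**: Welch t, Mann–Whitney, or Yates-corrected
  chi-squared (`sum((|O-E|-0.5)^2 / E)`, df 1) for 2×2 nominal tables.

# Differential expression

Per-feature negative-binomial GLM with log link and log-total-count
offsets. The dispersion is a method-of-moments estimate on
library-size-scaled counts (with the Poisson component removed), averaged
with the category median as a simple shrinkage, floored at 1e-8, and held
fixed during the fit; the Wald statistic is the group coefficient over
its standard error with the family dispersion fixed at 1. This is
deliberately *not* a re-implementation of any specific DE package's
dispersion machinery (no Cox–Reid adjustment, no empirical-Bayes trend);
it is validated by simulation calibration — type-I error within 1.5
points of the 5% nominal over hundreds of null datasets — and by
agreement of fold-change estimates with an established NB Wald
implementation on shared simulated data (correlation > 0.95). Paired
(initial vs follow-up) analyses add participant fixed effects — the
smallest adequate model for within-person contrasts. Multiple testing
uses our own Benjamini–Hochberg step-up (tested against a brute-force
oracle); volcano classes combine FDR < 0.05 with linear-scale
|fold change| > 1.5 (strict inequalities).

The Pearson association scan reports per-feature `r`,
`t = r·sqrt(n-2)/sqrt(1-r^2)`, a two-sided t-distribution p-value, and
the feature's BH step-up cut-off `rank · alpha / m` at its p-value rank —
our reading of the per-row "adjusted significance threshold" column of
association tables in this literature.

# Feature selection

Three streams, all computed on training data only:

1. **Multifold consensus**: for each of 10 stratified folds, a random
   forest (impurity importance) and a single-hidden-layer neural network
   (permutation importance on the held-out part) are fit on the fold's
   training part; each records its top 20 features. A feature is kept
   iff it appears in *strictly* more than 50% of the fold × learner
   lists. The per-fold top-k and fold count are configuration; 20 and 10
   are the defaults.
2. **Numeric-response GLM stream**: features with unadjusted Pearson
   p < 0.05 against any numeric response (symptom totals, functional
   scores, days post-injury).
3. **Binary-response GLM stream**: a penalized logistic model
   (elastic net, mixing 0.5, lambda by internal cross-validation) per
   binary response; if its cross-validated Cohen's kappa is strictly
   above 0.20 ("fair" agreement), the response contributes its top three
   features by absolute standardized coefficient.

The union of the streams (plus DE features at FDR < 0.05) feeds
**recursive feature elimination**: at each step the cross-validated
balanced accuracy of the downstream radial SVM is evaluated for every
single-feature omission under one fixed fold assignment (so comparisons
are paired); the feature whose omission maximizes performance is removed;
elimination stops when no omission strictly improves on the best score
seen. A gradient-boosted tree model then ranks the final panel by total
split gain (ties break lexicographically), and age is always appended to
the final model after selection.

**A calibration caveat worth knowing.** Because cross-validation folds
share most of their samples, a noise feature whose chance correlation
with the outcome is large in the full training set tends to be
"important" in *every* fold. Consensus therefore bounds, but does not
eliminate, spurious pass-through: on pure-noise inputs we measure on the
order of one to three selected features out of 100–500, not zero. The
downstream RFE step and the naive testing set are what keep such
features from inflating reported performance.

# Models and ROC inference

The prognostic model is a radial-kernel SVM with Platt-style probability
calibration fit on training data (features standardized on training
statistics inside the fit); the recovery models are probability forests.
Hyperparameters default to the implementations' standard settings
(SVM cost 1, gamma 1/p; 500 trees) — unstated in the source literature
and deliberately not tuned per experiment. All fits are seed-controlled.

Repeated stratified 10×10-fold cross-validation collects out-of-fold
probabilities per repetition and averages them per sample across
repetitions; the reported AUC and its DeLong CI are both computed on the
averaged probabilities. (Reporting the mean of per-repetition AUCs next
to a CI from a single repetition's predictions can place the point
estimate outside its own interval; computing both quantities on the same
averaged predictions keeps `ci_low ≤ auc ≤ ci_high` by construction.
Per-repetition AUCs are also returned.) The DeLong CI on pooled CV
predictions ignores the correlation induced by shared training folds; we
measured its empirical null coverage at about 95% for n ≈ 120 and about
85% at n = 60, so interpret CV intervals cautiously below ~100 samples.

The probability threshold is tuned on the held-out evaluation set by
maximizing balanced accuracy over the midpoints of consecutive sorted
unique probabilities (ties resolve toward 0.5; Youden's J is available).
With imbalanced classes and calibrated probabilities the optimum falls
below 0.5, which is the point of the evaluation set: it absorbs the
class-imbalance correction without touching the naive testing set.

AUCs are Mann–Whitney estimators (half credit for ties). DeLong
variance/covariance uses placement values; the paired test and the CI
match an established implementation to machine precision and the SE
agrees with a 2000-resample bootstrap within 15%. AUC power uses
Hanley–McNeil standard errors at the null and alternative AUCs with both
rejection tails accumulated:
`power = Φ((A1-A0-z·SE0)/SE1) + Φ((A0-A1-z·SE0)/SE1)`. For the training
design (0.68 vs 0.856, 53/131) this gives 99.4% — the printed 99%. For
the testing design (0.68 vs 0.87, 18/44) it gives 73.4% against a
printed 74%; the 0.6-point gap presumably reflects an internal option of
the commercial power software the study used, which is not documented in
enough detail to reproduce exactly.

# The two experiments

`run_prognosis_experiment()` chains simulate → preprocess → label →
split → select (training only) → train rSVM → tune threshold
(evaluation) → evaluate (testing), and compares the ncRNA model, a
Zemek-feature model, and their combination by repeated CV with DeLong
tests. `run_recovery_experiment()` works on each participant's labeling
follow-up sample, excludes samples within 2 PCSS points of the threshold,
and compares three probability forests: balance + cognition + age,
ncRNA + age, and combined.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use these scales, chosen as
the smallest that exercise the claims at cohort-realistic dimensions:
end-to-end recovery runs 5 seeds at 500 features × 112 participants
(~150 training samples); null-calibration suites use 200 datasets of 60
features × 30 samples; DeLong-vs-bootstrap uses n = 200 with 2000
resamples; oracle-equivalence suites use 1000 random instances.
Degenerate inputs are handled explicitly: all-zero features are flagged
with p = 1 and log2FC = 0; zero-variance features or responses are
flagged and excluded from ranking; zero-total samples, single-class
labels, and empty panels raise errors naming the offender; the threshold
optimizer returns 0.5 when all probabilities tie.

# Known limitations

* Synthetic counts lack participant-level random effects, so repeated
  samples from one participant are easier to classify than real repeated
  swabs would be; cross-participant generalization is better probed with
  one sample per participant.
* The NB Wald test is slightly conservative at very small n (method-of-
  moments dispersion with median shrinkage over-estimates dispersion for
  low-variance features).
* RFE's strict-improvement stopping rule often stops early on flat
  performance plateaus, returning panels larger than the minimal
  sufficient set.
* The multifold consensus null pass-through described above.
* Absolute AUC values on synthetic cohorts depend on the planted effect
  sizes and should be read as ordering/recovery properties, not as
  predictions of real-data performance.
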