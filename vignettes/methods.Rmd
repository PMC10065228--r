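---
title: "Methods: profiling future ankylosing spondylitis diagnoses from coded records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling future ankylosing spondylitis diagnoses from coded records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspredict)
```

# The problem and the modelling approach

Ankylosing spondylitis (AS) presents years before it is diagnosed, mostly
as low back pain in people aged 15–35 — a symptom so common in primary care
that the prodromal signal is invisible to unaided clinical review.
`aspredict` implements a staged, fully deterministic pipeline that learns a
coded-record profile of patients who later receive an AS diagnosis, and —
just as importantly — quantifies why even a good profile has low positive
predictive value at population prevalence.

The pipeline's statistical core is a chain of deliberately simple,
auditable components rather than a single opaque learner:

1. matched case-control resampling (1 case : 100 control sets),
2. chi-squared **stability selection** of binary code flags,
3. a logistic-regression significance filter,
4. mean-centred PCA of the surviving flags,
5. per-cohort CART decision trees on component scores, selected by highest
   mean F value (harmonic mean of sensitivity and PPV),
6. prevalence-aware evaluation with a 90/90 "perfect model" comparator.

The assumptions this embeds: that binary *presence* of a code in a time
window carries the predictive signal (frequency is discarded by design);
that comparing one fixed case group against 100 resampled control groups
separates stable signal from control-sampling noise; and that a shallow
axis-aligned tree over a few principal components is an interpretable,
adequate classifier for subgroup narration.

# Cohort construction

**Case definition.** A patient is a case at the earliest AS code in any
source (primary-care analogue `N100`, hospital analogue `M45`, or the
rheumatology system). A *suspected* onset back-dates the index when an
anti-TNF prescription, an HLA-B27 test, or a spondyloarthropathy diagnosis
precedes the first explicit AS mention; the suspected date is the earliest
qualifying event. Eligibility is inclusive at its boundaries: diagnosis age
in [15, 35] (a case diagnosed the day before the 15th birthday is out; on
the 35th, in), diagnosis year ≥ 2000, and registration starting at least 3
years (1096 days) before diagnosis, with *exactly* 3 years qualifying.

**Matching.** Controls must carry no AS or axial-spondyloarthritis code
anywhere in their record, match the case's sex and week of birth within 26
weeks ("within 6 months" at week resolution), and hold 3 years of
registration on each side of the index date — hence at least 6 years of
data in total. The k-th match of every case forms control set k; within a
set controls are distinct, while a control may serve different cases in
different sets (cross-case exclusivity is nowhere implied by the design and
enforcing it would shrink feasible pools sharply).

**The index-date convention.** A matched control's index date defaults to
its case's diagnosis date (`index_mode = "case_date"`). The alternative —
drawing each control's index uniformly from its feasible registration
interval (`index_mode = "random"`, also implemented) — seems innocuous but
systematically misaligns the arms: cases are, by construction, older at
index than a uniformly drawn control, so *every* background code acquires a
spurious case-control frequency difference and the stability screen's
type-I behaviour is destroyed. Tying the control's index to the matched
case's date (which the week-of-birth matching converts into age alignment)
is the only convention under which the null configuration of the generator
actually yields null features, so it is the default.

**Split.** 70/30 at the case level (so 543 cases would give 380/163 and 250
would give 175/75); each case's controls inherit its label, keeping matched
pairs intact.

# Feature construction

Each event stream becomes binary flags keyed by
(concept, truncation level, source, window):

* **Concepts and levels.** Codes are hierarchical 5-character strings;
  every truncation level 1–5 is expanded separately, with levels beyond a
  code's length collapsing to the full code. Aggregate concepts (a "pain"
  flag covering all specific pain prefixes, NSAIDs, analgesics, blood
  tests) are additional columns at level `AGG`.
* **Windows.** Two schemes, chosen per build: half-open 5-year age bands
  [15, 20), [20, 25), [25, 30), [30, 35) anchored at the week-of-birth
  midpoint (used by all the shipped defaults), or 1-year slices counting
  back from the index date. The narrative profile of the disease is age
  anchored, while the screening description counts tests per pre-diagnosis
  year; implementing both resolves the ambiguity explicitly. (The source
  description's "700 chi-squared tests" for 100 tests over 3 pre-index
  years is arithmetically inconsistent — possibly seven yearly slices; the
  window count is configurable and the discrepancy is documented rather
  than resolved.)
* **Hygiene.** Events on or after the index date are excluded before any
  flag is set, so post-index information cannot leak into pre-diagnosis
  features (a property test perturbs post-index events and asserts an
  unchanged matrix). Columns present in fewer than `min_count = 5`
  participants are dropped to avoid degenerate chi-squared tables.

# Selection

**Stability screen.** For each feature, a 2×2 table (cases with/without
vs set-k controls with/without) is tested against each of the 100 control
sets with the uncorrected Pearson statistic (1 df); a zero margin reports
p = 1 with a degeneracy flag, and expected counts below 5 are flagged but
tested. A feature passes at `alpha = 0.01` in at least
`stability_fraction × n_cohorts` tests — 0.90 by default, 0.75 for the
female-sized stratum. The threshold is a plain config value, not sex logic:
the stated reason for relaxing it is statistical power, a property of the
sample size. Direction is retained, so features *enriched in controls*
survive with direction −1 rather than being discarded.

Under the global null the pass probability is bounded by the
Binomial(n_cohorts, 0.01) upper tail at the threshold (≈ 10⁻¹⁶⁷ at 90/100).
The 100 tests share the case margin and are therefore positively
correlated; the exact pass probability is then governed by the case-arm
frequency excursion (a ≳ 4.5 σ event at the defaults), still vanishingly
small. The acceptance suite verifies both the analytic bound and the
realised zero selection rate over the generator's background features.

**Logistic filter.** Survivors enter one multivariable binomial GLM
("remain in the model" is read as joint fitting; a univariable mode is
available behind `lr_mode` since the description is ambiguous). Duplicated
and constant columns are removed first; features keep Wald p < 0.01.
Non-convergence or separation (|β| > 15 or SE > 100) triggers a
ridge-stabilised IRLS refit (λ = 0.01 on the slopes, intercept unpenalised)
with a warning, and separated features are flagged and *retained* — a
perfectly separating feature is maximal signal, not noise.

**PCA.** Mean-centred, unscaled (all features live on the same 0/1 scale;
variance scaling would inflate rare codes). Retention keeps the smallest
leading set explaining ≥ 80% of variance, overridable; retained components
are named A, B, C, … as in the tree narratives. Loadings are orthonormal to
1e-8 and full-component reconstruction is exact to 1e-8 (both tested).

# Trees and model selection

Per control cohort k, a greedy CART tree is fitted on the component scores
of cases + set-k controls: Gini impurity, splits at midpoints between
distinct observed values, depth ≤ 3, leaf size ≥ 10, split attempted only
with ≥ 20 participants. Tie-breaks are fully deterministic: equal-impurity
splits go to the lowest component index, then the lowest threshold; a leaf
with an exactly 0.5 case fraction predicts NON_AS. Published-style
thresholds (0.769 on component A and so on) are data-derived illustrations
that cannot be reproduced without the original records; the package asserts
tree *shape* and selection properties instead.

All 100 candidates are evaluated on all 100 pairings; the model with the
highest mean F wins, exact ties breaking to the lowest candidate index. A
pairing with no predicted positives has undefined F and contributes 0.
Each leaf exports its id (M1…/F1…-style), path conditions, and training
composition; the leaf's training case fraction doubles as the continuous
score for ROC analysis, since a hard-label tree has no native probability.

**Majority-class baseline.** The signal-recovery margin is measured against
the all-NON_AS predictor — the majority class at the cohort's 1-in-101
prevalence — whose F value (sensitivity 0) is taken as 0. The selected
tree's held-out mean F must exceed it by ≥ 0.2 absolute.

# Evaluation

Sensitivity, specificity, PPV, NPV, accuracy and F are percentages;
undefined metrics (zero denominator) are reported as undefined, never 0.
Stored values keep full precision; printing rounds half-up to 2 decimals to
match clinical table formatting. Prevalence-adjusted PPV/NPV follow Bayes'
rule and agree with the expected-count confusion-matrix route to 1e-12 at
any population size (tested). The flagged fraction — predicted positives
over the population — implements the published "percentage identified"
quantity: the only reading of that (typeset-mangled) expression consistent
with its printed values. The perfect-model comparator applies 90/90
sensitivity/specificity to the observed class totals (higher would suggest
overfitting). ROC curves sweep distinct score thresholds; tie groups are
traversed together so the trapezoid area equals the Mann–Whitney statistic
exactly (tested to 1e-12), and AUC is invariant under monotone score
transforms.

# The synthetic generator

The generator emulates the *structure* of linked routine data, not Welsh
code frequencies: three sources (GP/HOSP/RHEUM), four event kinds,
5-character hierarchical codes, registration windows wide enough for the
3/6-year rules, and 1% within-cohort vs ~0.09% population prevalence
regimes. Background events follow a homogeneous Poisson process
(`background_code_rate`, default 2 events/patient/year) over a background
dictionary shared identically by cases and controls. Signatures are
Bernoulli presence draws per (concept, age band): the shipped male set
plants teenage back pain and diclofenac, uveitis at 20–25, back disorders /
NSAIDs / blood tests at 20–25 and tests, pain and spinal radiology at
25–30; the female set plants an older, more medication- and
investigation-heavy profile and deliberately omits uveitis (a male-only
feature). Case penetrances 0.25–0.8 against control penetrances 0.02–0.25
were chosen once as plausible prodromal contrasts; the source quantifies
neither background rates nor per-code penetrances, so these defaults are
stated in config and claimed only to be realistic, not calibrated.

What the generator does *not* emulate: laboratory result values, free
text, deprivation or geography, mortality, migration, coding-practice
drift, or correlated comorbidity structure. Passing tests therefore show
that the pipeline recovers the signals it was told to plant under clean
sampling assumptions — they do not show that the real records contain such
signals, and real-data performance claims cannot be transported from them.

A detail that matters for realism of the *screen*: signature penetrance is
applied to any patient whose usable window (registration, truncated at
diagnosis for cases) intersects the band, and the event date is uniform in
that intersection. Presence probability is therefore not duration-scaled —
acceptable because the downstream pipeline consumes presence only.

# Determinism and numerics

Every stochastic step draws from a seed derived from the single run seed by
a fixed linear rule (kept below 2³¹), so identical config + seed gives
byte-identical artifacts, verified by hash in the manifest. Numerical
tolerances: chi-squared agrees with the reference implementation to 1e-10;
PCA orthonormality, eigenvalue agreement and reconstruction to 1e-8;
Bayes-vs-confusion PPV and AUC-vs-U to 1e-12; tree splits match an
exhaustive-search minimiser exactly. Degenerate inputs have defined
behaviour throughout: empty event tables give empty matrices, single-class
tree inputs give constant depth-0 trees, zero-margin tables are flagged,
and train fractions outside (0, 1) are rejected.

# Problem sizes

The shipped demo uses 40 cases with 20 control sets (seconds on one CPU);
the parameter-recovery analysis uses the study-sized male stratum — 380
training-scale cases, 100 control sets, a ~20,000-patient control pool —
which completes in about a minute. Both sizes are package choices made to
keep the full analysis interactive while preserving the study's matched
geometry at full scale.

# Known limitations

* The published fitted artefacts (PC loadings, tree thresholds, real-data
  AUCs of 0.87/0.86) are functions of protected data and are reproduced in
  spirit (shape, selection behaviour), not numerically.
* The logistic filter's joint-vs-univariable reading, control cross-case
  exclusivity, and PCA refit-per-cohort vs fit-once (the package fits once,
  on cases + control set 1, switchable via `pca_pooled`) are genuinely
  underdetermined by the source description; each choice is exposed as
  configuration and documented here.
* The interface is R functions plus `run_pipeline()`; there is no shell
  CLI. Stage contracts are file-based (CSV dialects documented on each
  writer), so stages remain independently runnable.
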