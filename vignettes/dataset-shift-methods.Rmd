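---
title: "Methods: simulating and measuring dataset shift for ICU prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring dataset shift for ICU prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package measures

Clinical prediction models are usually validated on a random split of the
cohort they were developed on. Deployed models face a harder problem: the
record system changes (temporal drift), a new device adds features the
model never saw, the receiving hospital has little data, or its patient
population differs from the development population. `icushift` turns each
of these four deployment barriers into a reproducible experiment: generate
an ICU cohort whose ground truth is fully known, realize the barrier as a
train/test split (or a feature toggle, or a training-set subsample), and
measure the AUROC cost.

Everything runs on synthetic cohorts, so the package needs no access to a
credentialed clinical database and every expected behaviour is checkable
against ground truth. The price is that the cohorts are caricatures; the
last section lists what they do and do not capture.

# The synthetic cohort generator

## Latent risk model

Each ICU stay carries a latent severity vector
$x = (x_1, \dots, x_5) \sim \mathcal N(0, I_5)$, expanded into the basis

$$\tilde x = (x_1, x_2, x_3, x_4, x_5,\; x_1 x_2,\; x_3^2),$$

and the probability of developing acute kidney injury (AKI) within 7 days
is

$$p = \operatorname{logistic}\big(\beta^\top \tilde x
  + \delta\,\mathbf 1[\text{post-epoch}]\,\gamma^\top \tilde x
  + \eta\,\mathbf 1[\text{non-White}]\,\kappa^\top \tilde x + c\big).$$

The two interaction terms plant genuine nonlinearity in the
feature-to-label map, which is what lets a multilayer perceptron beat a
linear scorer on this task (a property the test suite checks). The
intercept $c$ is calibrated by root finding on the realized sample so the
marginal AKI prevalence matches the configured stage mixture exactly in
expectation; the stage (1--3) of an AKI stay is then drawn from the
renormalized stage mixture.

The shift directions $\gamma = \beta_{\text{rot}} - \beta$ and
$\kappa = \beta_{\text{pop}} - \beta$ are differences to same-norm,
permuted/sign-flipped copies of $\beta$. Moving along these lines rotates
the risk coefficients without changing their scale: at $\delta = 1$ the
post-epoch coefficient vector is orthogonal to the pre-epoch one, and the
angle grows monotonically with $\delta$. Two consequences matter for the
experiments. First, a model transported across the shift degrades
monotonically in the shift magnitude. Second, because the shift is a
rotation and not a mean offset, it cannot be absorbed by feature
normalization — a model retrained on post-epoch data recovers full
performance, which is what makes the drift scenario informative rather
than trivially null. The defaults $\delta = 0.6$ and $\eta = 0.5$ were
fixed once so that the default drift experiment loses roughly 0.1 AUROC
and the population experiment a smaller amount, echoing the relative
severity of the two effects in published ICU drift analyses; the test
machinery never depends on these defaults (it sets explicit magnitudes
per experiment).

Latent severity reaches the observable record through the channels:
$x_1, \dots, x_4$ load on vitals and labs (heart rate, blood pressures,
respiration rate, oxygen saturation, temperature; BUN, hemoglobin, white
cells, sodium, potassium, glucose) with per-channel observation noise,
while $x_5$ is expressed **only** through the urine-output channel. That
single design choice is what gives the urine feature group independent
predictive value: a model without urine features cannot see $x_5$ at all,
so adding the channel raises the achievable AUROC — the structure the
change-of-features scenario measures. For the same reason the first-day
prodromal AKI signal (depressed urine output before any staging threshold
is crossed) appears only in urine, never in the labs.

## From stage to trajectory

The generator inverts the KDIGO labeler: given an intended stage it
constructs creatinine and urine series that the labeler maps back to that
stage, with explicit safety margins rather than borderline noise.

* Creatinine is charted every 12 h (±20 % jitter) for 7 days. Pre-onset
  values sit in $[b, b + 0.1]$ mg/dL above the latent baseline $b \sim
  U(0.6, 1.1)$. AKI stays ramp from the *observed* first-24 h minimum
  (exactly the labeler's baseline) to a peak at a ratio drawn inside the
  stage's band — (1.62, 1.85) for stage 1, (2.15, 2.80) for stage 2,
  (3.30, 3.80) for stage 3 — hold a 24 h plateau so the 12 h cadence is
  guaranteed to chart the peak band, then decay. Onset always lies after
  hour 30, so generated AKI is never excluded as admission AKI.
* Urine output is charted hourly (jitter ±0.2 h, so inter-observation gaps
  never reach the labeler's 2 h span-breaking tolerance). The baseline
  rate encodes $x_5$ and the intended stage; it is clamped at
  0.70 mL/kg/h for stage-0 stays and 0.55 for AKI stays, keeping every
  off-window value clear of the 0.5 mL/kg/h threshold. The oliguric
  window (start hour 26--40) realizes the stage's urine criterion with
  margins on both depth and duration: e.g. stage 1 uses a rate in
  (0.31, 0.45) for 6.5--9.5 h — long enough to sustain 6 h after edge
  losses, short enough never to reach the 12 h stage-2 span.
* Because both label-bearing series use bounded construction noise, the
  `noise_sd` knob scales only the nuisance vitals/labs channels; label
  fidelity survives any `noise_sd`. The round-trip (generate, then label)
  is therefore exact by construction, and the test suite verifies 100 %
  agreement across the configuration matrix.

Cadences (creatinine 12 h, urine 1 h, vitals 1 h, labs daily) follow modal
ICU charting coarsely; vitals are generated for the first 48 h only, since
the feature window closes at hour 24 and nothing downstream reads later
vitals. Configured cadences are validated against the label-fidelity
margins (urine ≤ 1.6 h, creatinine ≤ 16 h).

## Cohort composition

Default category mixtures are anchored to the composition of a large
single-centre critical-care cohort: AKI stages 0--3 in proportions
0.3985 / 0.1789 / 0.3203 / 0.1023, EMR epochs pre/post/cross-over at
0.500 / 0.386 / 0.114, 71.6 % White ethnicity, and a 6.5 % 72-hour ICU
readmission rate. An alternative `hospital_wide` preset (6 % total AKI)
reflects hospital-wide rather than ICU prevalence. Cross-over stays —
patients charted in both record systems — are generated as a 50/50 mixture
of the two coefficient regimes; only their existence matters, since every
drift split excludes them.

Weight is fixed per patient (uniform 60--110 kg; the urine criterion is
weight-normalized), ages are uniform 18--90, and each stay belongs to its
own patient. Readmission gaps come from a two-component log-normal mixture
(early bounce-back, median 30 h; late return, median 300 h) whose
readmitted fraction is calibrated by root finding so the 72 h rate matches
the configuration; the readmission indicator itself is risk-dependent
through its own coefficient vector, so the readmission models have signal
to find. About 3 % of patients carry a chronic-kidney-disease flag and are
excluded downstream, exercising the extraction path.

# KDIGO labeling

The labeler evaluates the first 7 days from ICU admission.

* **Baseline creatinine** is the minimum value charted in the first 24 h.
  The cohort excludes admission AKI, so early values approximate the
  pre-injury baseline; stays with no first-day creatinine are dropped
  (`missing_baseline`), never silently staged.
* **Creatinine arm**: stage 1 at 1.5--1.9× baseline or a rise ≥ 0.3 mg/dL
  within any 48 h window; stage 2 at 2.0--2.9×; stage 3 at ≥ 3.0× or an
  absolute value ≥ 4.0 mg/dL.
* **Urine arm**: each charted value covers the interval back to the
  previous observation; the rate is value/weight in mL/kg/h. Stage 1 at
  < 0.5 sustained ≥ 6 h, stage 2 at < 0.5 sustained ≥ 12 h, stage 3 at
  < 0.3 sustained ≥ 24 h or anuria ≥ 12 h. Spans are maximal runs of
  below-threshold intervals; an inter-observation gap longer than 2 h
  breaks the span (sustained oliguria cannot be asserted across a
  charting hole). The qualification time is span start + required
  duration.
* The stay's stage is the maximum over arms; onset is the earliest onset
  among arms attaining that stage; at exactly equal onsets the creatinine
  criterion is reported. Renal replacement therapy (an alternative
  stage-3 trigger in the guideline) is not modelled because the schema
  has no such channel; this is an extension point.

An independent brute-force implementation — nested loops over every
observation pair and every interval run, no short-circuiting shared with
the production path — lives in the test helpers and must agree with the
labeler on stage, criterion and onset for 1,000 trajectories, 600 of which
are adversarial series drawn to straddle every threshold.

# Features and exclusions

Extraction removes stays aged under 18, chronic kidney disease, AKI
attributable to the first 24 h (onset ≤ 24 h), and stays whose KDIGO
inputs are incomputable, each with a logged reason.

The feature matrix has a fixed, documented 83-column layout: 4
demographics, 10 comorbidity flags, 13 vitals/labs channels × 4 summaries
(mean, min, max, last) over the first 24 h, 3 urine features (mean rate,
minimum rate, hours below 0.5 mL/kg/h), minimum eGFR, and 13
creatinine/eGFR-derived summaries. Toggling the urine group off removes
exactly those 3 columns. The prediction-time window is the first 24 h of
the stay so that features precede almost all onsets; labels cover days
0--7. eGFR uses the MDRD-4 formula
($175 \cdot \text{SCr}^{-1.154} \cdot \text{age}^{-0.203} \cdot
0.742^{[\text{female}]} \cdot 1.212^{[\text{Black}]}$), the standard
formula in the era of the emulated cohort; CKD-EPI would be an equally
defensible choice.

Raw summaries never depend on the train/test flagging. Standardization
(mean, sd) and median imputation are fitted on training rows only, per
split; constant training columns get sd 1 so they standardize to zero
rather than exploding. Readmission labels for the seven windows (24 h,
48 h, 72 h, 24--72 h, 7 d, 30 d, bounce-back) all derive from the single
gap between ICU discharge and readmission; bounce-back means readmission
before hospital discharge.

# Models

The predictors are multilayer perceptrons written directly on R's matrix
algebra: rectifier hidden layers, a logistic (or softmax) output,
class-weighted cross-entropy, L2 penalty, Adam updates, mini-batches, and
early stopping on a stratified validation split with best-epoch restore.
Initialization, the validation split, and batch order all derive from the
model seed, so training is bit-reproducible. Class imbalance is handled by
the loss weights, not resampling, keeping AUROC estimation on the natural
prevalence.

The scenario experiments default to a compact architecture (hidden widths
32--16, learning rate 5e-3, batch 256, ≤ 60 epochs, patience 8), which
reaches the same held-out AUROC on this task as much deeper variants at a
fraction of the cost. The tuned deep preset `aki_deep_spec()` — 15
tapering hidden layers — is provided for users who want the full-depth
architecture; depth beyond a few layers buys nothing on an 83-feature
tabular task, which is itself a finding the hyperparameter search can
reproduce.

Transfer learning follows the layer-freezing recipe: the input layer is
widened to accept the new (urine) features with the old input weights
copied and the new rows initialized to zero — so with zero fine-tuning
epochs the widened model reproduces the old model exactly — and hidden
layers 2 through depth−1 are frozen by default while the input and output
layers adapt. Frozen parameters are held bitwise fixed; the test suite
asserts exact equality after fine-tuning.

# Scenarios

* **Baseline**: stratified random 80/20 split.
* **Drift**: train on all pre-epoch stays, test on all post-epoch stays,
  cross-over stays excluded from both sides. The test side is reported at
  its natural size by default; `size_match_test` subsamples it to the
  baseline test size for size-matched comparison.
* **Change of features**: a fixed stratified 80/20 split; three arms over
  the training-fraction grid — without urine, with urine from scratch,
  and with urine via transfer from the full-data no-urine model. The
  crossover fraction is the smallest grid fraction whose mean AUROC
  reaches the no-urine full-data reference.
* **Scarcity**: train on a random sub-sample of the eligible cohort, test
  on the remainder (so the test side shrinks as the fraction grows).
* **Population**: train on White stays, test on one minority group at a
  time (Black, Latinx); the comparator baseline includes all groups on
  both sides.

Within one replicate seed, the fraction grids use *nested* sub-samples —
one permutation, growing prefixes — modelling the accrual of a data
collection. This makes adjacent fractions directly comparable and keeps
learning curves from jittering through independent resampling noise;
across seeds the permutations are independent. Every stochastic scenario
runs several seeds and reports mean ± sd; single-number results hide the
replicate noise that dominates small-fraction AUROCs.

Split soundness is enforced structurally: a split assigns every stay
exactly one of train/test/excluded, train ∩ test = ∅ is asserted before
any data is touched, and normalization/imputation parameters are
recomputed per split from training rows only (perturbing test rows
provably leaves them unchanged).

The confounding diagnostic cross-tabulates two stay partitions
(e.g. ethnicity × EMR epoch) as the percentage of each column level within
each row level, plus a whole-cohort row; omitted column levels (the
cross-over phase) absorb the remainder, so listed cells may sum below
100 %. Because the generator draws epoch and ethnicity independently,
every row matches the whole-cohort row up to sampling noise — the
uncorrelated-splits situation in which scenario attributions are clean.

# Numerical choices

* Proportion vectors must sum to 1 within 1e-9; intercept calibration
  solves to 1e-10 by `uniroot` on a bracket of ±40.
* AUROC uses the rank formulation of the Mann–Whitney statistic with 0.5
  credit for ties, and refuses single-class inputs rather than returning
  0.5. The suite requires agreement with exhaustive pair counting to
  1e-12 including heavily tied scores.
* Early stopping requires a loss improvement of at least 1e-6; sd floors
  of 1e-12 guard constant features.
* Sub-seeds for pipeline stages are derived as
  `(seed * 7919 + offset) mod (2^31 - 1)` so every stage has an
  independent stream while remaining a pure function of the user seed.

# Study sizes used by the checks

The test suite and the acceptance script size their runs to desk scale:
mixture convergence at 20,000 stays; null-shift calibration at 8,000
stays × 5 replicate cohorts; dose-response at 3,000 stays × 5 seeds × 3
magnitudes per shift; change-of-features and scarcity at 4,000 stays × 5
seeds (scarcity fractions 0.05--0.80, keeping at least 20 % of the cohort
on the evaluation side; at larger fractions the shrinking remainder makes
the curve's tail an artifact of tiny test sets rather than of learning).
These sizes give sub-0.02 standard errors on the headline AUROCs while
keeping any single check in the minutes range.

# Limitations

The generator emulates the *statistical structure* the experiments need —
relational schema, irregular charting, label-recoverable physiology,
controllable shifts — not physiology itself: no pharmacokinetics, no
organ-system coupling, no treatment feedback, no missing-not-at-random
charting, no repeat patients, and marginal distributions matched only in
the anchored category mixtures. Passing tests therefore demonstrate that
the *pipeline* behaves correctly and that the *directional* phenomena
(drift hurts transported models, new informative features add headroom,
transfer learning shortens the data-collection gap, minority-group
transport degrades with subgroup effect size) emerge as designed; they do
not quantify how large those effects are in any real ICU. Statistical
tests comparing AUROCs across scenarios are deliberately out of scope, as
is model explainability.
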