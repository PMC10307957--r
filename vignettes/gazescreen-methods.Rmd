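---
title: "Models and methods behind gazescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gazescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gazescreen` implements, end to end, an analysis design for screening mild
cognitive impairment (MCI) from saccade behaviour: two interleaved
eye-tracking sessions — prosaccade/antisaccade (PS/AS) and Go/No-go — are
scored into trial outcomes, aggregated into per-subject eye-movement (EM)
metrics, and analysed two ways: logistic odds ratios per metric, and a
multi-algorithm classification benchmark against demographic and MMSE
baselines. Because raw clinical gaze recordings of this design are not
generally available, the package ships a generative counterpart of the
scoring rules: a simulator that produces cohorts, sessions and 300 Hz gaze
traces with known ground-truth outcomes. The simulator is first-class,
tested code — it is both the package's test harness and a tool for power
and sensitivity studies of the design itself.

This vignette records the models, the defaults and the reasoning behind
the choices the design leaves open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The paradigm and the trial timeline

Each session has 30 blocks of 3 trials: two standard trials (PS, or Go)
and one deviant trial (AS, or No-go) in random order, with targets at
±10° in the horizontal plane, sides randomly interleaved with equal
frequency. The design fixes that structure but not the trial
timeline, so the package adopts one default: 1000 ms of central fixation,
target onset at t = 1000 ms, and 1500 ms of post-onset recording. The
post-onset window must accommodate the 500 ms omission rule, the slowest
admissible first saccade (up to 500 ms), and the 400 ms correction window
after that saccade's offset; 1500 ms leaves margin for a corrective
saccade and its ensuing fixation. These are configurable
(`build_session_schedule()` arguments), not facts about any particular
laboratory.

## The generative model of a trial

`simulate_trial_trace()` first samples a *latent outcome*, then renders a
trace realizing it, so every simulated trial carries its own ground-truth
label (`truth`):

* **Anticipation** with probability `p_anticipation`; the saccade launches
  uniformly between 150 ms before and 70 ms after target onset. Movements
  launched shortly *before* onset are anticipatory by definition, so the
  scorer admits saccades from 200 ms pre-onset; the simulator stays 50 ms
  inside that bound so detection jitter cannot move a label across it.
* **Omission** with probability `p_omission` (PS/AS/Go only); the gaze
  simply stays at the centre.
* **Inhibition error** with probability `p_inhibition` on deviant trials
  (AS: a reflexive saccade captured by the target; No-go: any saccade to
  the target). With probability `p_correction` the error is *corrected*:
  a corrective saccade into the correct region starts 60–300 ms after the
  erroneous saccade's offset. Otherwise it is *uncorrected*: either no
  corrective saccade at all, or one starting 450–650 ms later — clearly
  outside the 400 ms rule. PS and Go trials can also produce
  wrong-direction errors, at 0.35 × `p_inhibition`; the error taxonomy
  lists corrected ("self-corrected") and uncorrected errors for the
  standard conditions too, so generating none at all would make those
  features degenerate (constant zero columns).
* **Correct** otherwise. PS/Go: saccade to the target; AS: to the mirror
  location; No-go: the centre fixation is held for a subject-specific
  time (truncated normal, `hold_mu`/`hold_sigma`, bounded to
  [600, 1450] ms) and then released. The hold must exceed the 500 ms
  window for the trial to remain correct; releasing it later in the trial
  gives the fixation-duration features realistic between-trial spread,
  without which their SD — a key discriminative metric — would be zero.

Saccade latencies follow a shifted lognormal (shift 70 ms) parameterized
by the subject's latency mean and SD — the standard right-skewed shape of
saccadic reaction times — truncated to (100, 470) ms so that sampling
noise alone cannot push a correct trial across the 80 ms anticipation or
500 ms omission boundary. Saccades are rendered as raised-cosine
displacements with main-sequence duration `21 + 2.2 ms/deg`; fixational
noise is white Gaussian with SD `fixation_noise_sd` per axis (defaults
0.15° CN, 0.22° MCI, in the range of tower-mounted 300 Hz trackers once
drift and small instability are included). The vertical channel carries
only noise: the targets are horizontal. Positions are clamped to ±15°.

## Cohort defaults

Demographics and MMSE are sampled from the published cohort moments (CN:
age 71.17 (6.22), education 13.1 (4.4), MMSE 27.77 (1.75), 56% female;
MCI: 73.45 (6.63), 12.9 (4.5), 26.16 (2.64), 50% female; 428 CN / 166 MCI
by default), clipped to valid ranges, MMSE rounded to an integer in 0–30.

The oculomotor group parameters are not published as raw moments, so the
package calibrates them once against the only anchor the design provides:
the standardized adjusted odds ratios of the affected EM metrics should
fall in roughly the 1.2–1.6 band (and their mirror 0.6–0.8 for
correct-rate and fixation-duration metrics) at a cohort of about 600.
The shipped defaults (`group_defaults()`) — e.g. latency SD 46 vs 51 ms,
`p_inhibition` 0.22 vs 0.26, `p_correction` 0.52 vs 0.46, hold time
1120 (155) vs 1090 (175) ms for CN vs MCI, with subject-level scatter of
the error probabilities on the logit scale (SD 0.45) — achieve that.
They are conditions of the simulated study, not tuning knobs: analyses in
the package's tests run against these fixed defaults.

## Event scoring

Detection is classic velocity-threshold (I-VT) at 300 Hz: positions are
smoothed with a 5-sample moving average, differentiated by central
differences, and runs of speed above 30 deg/s become saccades; runs
separated by less than 10 ms merge; events below 1° horizontal amplitude
are discarded (this also removes one-sample noise crossings). Invalid
samples are bridged by linear interpolation when the gap is under 50 ms —
about the shortest blink — and longer gaps split events. Fixations are the
inter-saccadic intervals of at least 60 ms; dispersion is the maximum
pairwise distance of the smoothed positions.

Classification applies the outcome rules in a fixed order so that every
trial receives exactly one category:

1. first saccade (admitted from 200 ms pre-onset) with onset < 80 ms
   after target onset → **anticipation**;
2. no saccade with onset in (80, 500] ms → **omission**, except on No-go
   where a centre fixation held through the window is **correct**, with
   `fixation_duration` = time until gaze leaves the 2.5° centre region;
3. otherwise the first saccade's direction and landing decide: PS/Go
   correct iff toward the target with a subsequent fixation centroid in
   the 2.5° target AOI; AS correct iff away from the target with a
   fixation in the mirror AOI;
4. anything else is an **inhibition error**, *corrected* iff a corrective
   saccade re-establishes the correct region within 400 ms of the
   erroneous saccade's offset and the ensuing fixation is stable.

Open points and how the package resolves them:

* *AOI geometry* is unspecified upstream; a circular AOI of radius 2.5°
  around ±10° (and the same radius for the centre region) covers typical
  saccadic undershoot without overlapping the centre.
* *"Gaze variation ≤ 1°"* in the correction rule is read as the
  dispersion of the post-correction fixation, assessed over its first
  150 ms on smoothed positions. A bounded window keeps the criterion a
  test of post-correction stability rather than of slow drift over an
  arbitrarily long remainder of the trial.
* *Anticipation vs omission overlap*: the omission rule is
  operationalized as "no saccade with onset in (80, 500]", keeping the
  two categories disjoint by construction.
* *Wrong-direction PS/Go saccades* are scored through the same
  inhibition-error machinery (with the target AOI as the correct region),
  since the error taxonomy lists corrected/uncorrected errors for the
  standard conditions.

The simulator and scorer are deliberately coupled through their margins:
each generated latency, gap and hold stays far enough from every decision
boundary that a noise-free trace must be scored identically to its latent
label. The test suite exploits this as a round-trip oracle — 100%
agreement on noise-free traces, ≥ 95% under default noise — which tests
the detector, the rules and the renderer jointly. What this does *not*
show is robustness to the pathologies of real recordings (head motion,
blink artefacts beyond linear bridging, calibration drift, smooth
pursuit); the scoring parameters are exposed precisely so they can be
re-tuned on real data.

## Feature aggregation

Per condition: percentage correct; anticipation, omission and
corrected/uncorrected percentages (of that condition's trials); "all
errors" as anticipations + omissions + inhibition errors for PS/AS/Go and
inhibition errors alone for No-go; latency mean/SD over correct trials
(PS/AS/Go); fixation-duration mean/SD over correct No-go trials. That is
8 + 8 + 8 + 6 = 30 variables. Percentages rather than counts enter the
models, removing dependence on completed-trial counts. Latency statistics
use correct trials only — anticipations and omissions have no meaningful
stimulus-driven latency — and SDs are sample SDs, absent below two
contributing trials. "Self-corrected" (PS/Go) and "corrected error"
(AS/No-go) are treated as one construct under two labels.

`build_feature_table()` binarizes sex, requires both groups, and removes
features constant across all-but-one subject, which would otherwise be
uninformative at best and break standardization at worst.

## Odds ratios

The crude model regresses MCI status on one (z-scored) metric; the
adjusted model adds age, sex and education. Continuous predictors are
standardized on the full analysis sample, so the OR is per 1 SD: printed
ORs of 0.6–1.6 are implausible per raw unit (a millisecond, a percentage
point) and typical of per-SD reporting. Intervals are Wald
(`exp(β̂ ± 1.96 SE)`, the table-footnote convention), p-values from the
Wald z test, and no multiplicity adjustment is applied because none is
part of the design. Fits use iteratively reweighted least squares with a
tightened convergence tolerance; perfect or quasi-perfect separation
(diverging coefficients, degenerate fitted probabilities) is flagged on
the result rather than silently producing meaningless intervals.

## The classification benchmark

Four learners (L2-penalized logistic regression, random forest with 500
trees, RBF-kernel SVM, gradient boosting) cross six feature sets (Demo;
MMSE; Demo+MMSE; EM; Demo+EM; Demo+MMSE+EM). Design choices:

* **Shared split.** One stratified 80/20 train/test split per seed,
  identical across all 24 cells, so feature sets are compared on the same
  subjects.
* **Leakage control.** Standardization statistics always come from the
  fitting side (fold-train inside CV, full train for the final model);
  SMOTE synthesizes minority rows to class parity *inside each CV fold
  only* — synthetic rows never reach validation or test data. SMOTE uses
  k = 5 minority neighbours, interpolating uniformly along the segment to
  a random neighbour.
* **Model selection.** Stratified 5-fold cross-validation, 10 repeats by
  default (tests and the acceptance script use 1–2 repeats to keep their
  runtime proportionate; the geometry is a `cv_config()` argument).
  The grid point with the highest mean AUROC wins; grids are ordered
  least-to-most complex (larger ridge penalty, smaller mtry, smaller
  cost, shallower/shorter boosting first) so ties resolve toward the
  simpler model.
* **Evaluation.** AUROC by the rank statistic (exactly the
  pair-ordering probability, ties counting half); binomial deviance with
  probabilities clipped to `[1e-15, 1 − 1e-15]`, reported only for
  learners with calibrated probability outputs (logistic regression,
  boosting) and absent for random-forest vote shares and Platt-scaled SVM
  scores; sensitivity/specificity at the Youden-optimal threshold of the
  test ROC, since no operating threshold is prescribed. Both the
  cross-validated mean AUROC and the held-out test AUROC are reported —
  whether a published grid reports one or the other is ambiguous, and at
  a 20% test side of a few dozen subjects the test AUROC alone carries
  substantial sampling noise.
* **Importance.** Permutation importance on the test side: each feature
  permuted 100 times, mean AUROC drop, ranked.

## Problem sizes and numerical choices

The test suite and acceptance script choose sizes that make their checks
sharp but proportionate: scoring round-trips use six simulated subjects
(2160 trials, ≥ 1000 per noise arm); odds-ratio recovery uses 200
replicates at the reference n = 594 with the 428/166 split; benchmark
sanity uses cohorts of 300 (216/84) over 25–50 seeds for the
feature-set-ordering check and a label-permuted cohort for the null
control, judged on the cross-validated mean AUROC (its held-out
counterpart on ~60 test subjects has a null SE of ~0.08, too wide to
bound tightly at a single seed). Determinism is end-to-end: every
stochastic step derives its stream from one master seed, and identical
configuration plus seed reproduces every output byte-for-byte.

## Known limitations

The simulator emulates the statistical structure the analysis assumes,
not eye physiology: no microsaccades, pupil dynamics, smooth pursuit,
vergence, or calibration error; blinks only as bridgeable invalid gaps;
saccade kinematics as a fixed main-sequence shape. Passing the package's
tests therefore validates the *pipeline* — detector, rules, aggregation,
statistics, benchmark discipline — not any claim about real patients.
The printed odds-ratio band used for calibration anchors effect sizes
only loosely; real-data effect patterns (e.g. which specific metrics
reach significance) will differ. Finally, the benchmark's hyperparameter
grids are compact by design; serious model comparison on real data would
widen them and add nested-CV uncertainty estimates, which are out of
scope here.
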