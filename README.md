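# gazescreen

Oculomotor screening for mild cognitive impairment (MCI) from interleaved
prosaccade/antisaccade (PS/AS) and Go/No-go saccade tasks.

Eye movements degrade early in the progression toward dementia: patients
with MCI show more variable saccade latencies, shorter and more variable
fixations, and more frequent anticipations, omissions and uncorrected
inhibition errors than cognitively normal (CN) controls. Because an eye
tracker is non-invasive and needs little staff training, these metrics are
attractive screening candidates next to brief cognitive tests such as the
MMSE. `gazescreen` implements the full analysis chain for this design, for
methodologists who want to study or extend it:

1. **Simulation** (`simulate_cohort()`, `simulate_cohort_sessions()`,
   `simulate_cohort_outcomes()`) — cohorts of CN/MCI subject profiles with
   realistic demographic and oculomotor parameters, and 300 Hz gaze traces
   for two 30-block sessions (2 standard + 1 deviant trial per block,
   targets at ±10° horizontal) with known ground-truth trial outcomes.
2. **Event scoring** (`detect_saccades()`, `detect_fixations()`,
   `classify_trial()`, `score_session()`) — velocity-threshold (I-VT)
   saccade detection and the five-way outcome taxonomy: *correct*,
   *anticipation* (first saccade < 80 ms after target onset), *omission*
   (no saccade within 500 ms), and *corrected*/*uncorrected inhibition
   errors (corrective saccade within 400 ms with gaze variation ≤ 1°, or
   not).
3. **Feature aggregation** (`aggregate_cohort()`,
   `build_feature_table()`) — the 30 per-subject eye-movement variables
   (per condition: correct %, latency mean/SD or fixation-duration
   mean/SD, all-errors %, corrected/uncorrected %, anticipation %,
   omission %) plus demographics and MMSE.
4. **Association statistics** (`estimate_or()`, `table_one()`) — crude and
   age/sex/education-adjusted logistic odds ratios per 1 SD of each
   predictor with 95% Wald intervals, `OR = exp(β̂)`,
   `CI = exp(β̂ ± 1.96·SE)`, and Wilcoxon / chi-squared group comparisons.
5. **Classification benchmark** (`run_all()`) — logistic regression,
   random forest, RBF-kernel SVM and gradient boosting on six feature sets
   (Demo, MMSE, Demo+MMSE, EM, Demo+EM, Demo+MMSE+EM) with a shared
   stratified 80/20 split, SMOTE applied inside each cross-validation fold
   (never to validation or test rows), AUROC
   `= P(score_MCI > score_CN) + ½·P(tie)`, binomial deviance
   `−2·Σ[y log p + (1−y) log(1−p)]`, and permutation feature importance.

Everything is tidyverse-native: functions take a data frame first, return
tibbles, and compose with the pipe; results have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` visualisations.

## Worked example

```r
library(gazescreen)

# a small cohort: 80 controls, 40 MCI patients
cohort   <- simulate_cohort(cohort_spec(n_cn = 80, n_mci = 40), seed = 1)
outcomes <- simulate_cohort_outcomes(cohort, seed = 1)
features <- build_feature_table(aggregate_cohort(outcomes, cohort))

estimate_or(features, "ps_latency_sd", adjusted = TRUE)
#> # A tibble: 1 × 7
#>   variable      model       or ci_low ci_high     p separation
#>   <chr>         <chr>    <dbl>  <dbl>   <dbl> <dbl> <lgl>
#> 1 ps_latency_sd adjusted  1.39  0.934    2.08 0.104 FALSE
```

The odds of MCI rise by an estimated 39% per standard deviation of
prosaccade latency variability in this simulated cohort — the generative
effect direction, though at n = 120 the Wald interval is still wide; at
the default n = 594 the estimate concentrates in the 1.2–1.6 band the
generator is calibrated to. A compact benchmark:

```r
bench <- run_all(features, cv_config(seed = 1, n_repeats = 2,
                                     algorithms = c("LR", "XGB")))
glance(bench)[, c("feature_set", "algorithm", "auroc", "deviance")]
#> # A tibble: 6 × 4
#>   feature_set  algorithm auroc deviance
#>   <chr>        <chr>     <dbl>    <dbl>
#> 1 Demo         LR        0.430     33.6
#> 2 Demo+EM      XGB       0.773     23.9
#> 3 Demo+MMSE    XGB       0.637     28.4
#> 4 Demo+MMSE+EM LR        0.797     27.3
#> 5 EM           LR        0.789     27.5
#> 6 MMSE         XGB       0.738     24.7
```

Each row is the best algorithm per feature set on the held-out 20% test
side (here 24 subjects, hence the wide spread): demographics alone sit at
chance, MMSE and the eye-movement block each carry real signal, and the
combined set performs best — the ordering the method is designed to
surface. `autoplot(bench)` draws the full grid, `plot_roc(bench)` the ROC
curves.

Raw gaze traces can be rendered, written and re-scored explicitly:

```r
traces <- simulate_cohort_sessions(cohort[1:2, ], seed = 1)
write_gaze_csv(traces, "gaze.csv")
scored <- score_session(read_gaze_csv("gaze.csv"))
```

`run_pipeline(run_config(...), out_dir)` chains all five stages and writes
per-stage CSVs plus a JSON manifest.

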