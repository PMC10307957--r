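test_that("forced outcome probabilities yield the forced trace", {
  # certain omission: no saccade within the 500 ms window
  p_om <- test_profile(p_omission = 1)
  tr <- simulate_trial_trace(p_om, test_trial("PS"), seed = 2)
  expect_equal(tr$truth[1], "omission")
  sac <- detect_saccades(tr)
  expect_false(any(sac$onset > 1000 & sac$onset <= 1500))

  # error-free Go trial: correct, first saccade lands in the target AOI
  p_ok <- test_profile()
  tr2 <- simulate_trial_trace(p_ok, test_trial("Go", side = "left"), seed = 3)
  expect_equal(tr2$truth[1], "correct")
  out <- classify_trial(tr2)
  expect_equal(out$category, "correct")
  expect_lt(abs(out$first_saccade_amplitude - (-10)), 1.5)
})

test_that("trace samples respect rate, clamping and validity invariants", {
  tr <- simulate_trial_trace(test_profile(fixation_noise_sd = 0.3),
                             test_trial("AS"), seed = 7)
  expect_true(all(diff(tr$t_ms) > 0))
  expect_equal(unique(round(diff(tr$t_ms), 9)), round(1000 / 300, 9))
  expect_true(all(abs(tr$x_deg) <= 15))
  expect_true(all(abs(tr$y_deg) <= 15))
  expect_error(simulate_trial_trace(test_profile(),
                                    test_trial(target_onset = 2500,
                                               trial_duration = 2500)),
               "target_onset")
})

test_that("latent inhibition-error rate matches the configured probability", {
  profiles <- dplyr::bind_rows(lapply(1:12, function(i) {
    p <- test_profile(p_inhibition = 0.3, subject_id = sprintf("P%03d", i))
    p
  }))
  oc <- simulate_cohort_outcomes(profiles, seed = 123)
  as_trials <- oc[oc$condition == "AS", ]
  n <- nrow(as_trials) # 12 subjects x 30 AS trials
  frac <- mean(as_trials$category %in% c("corrected_inhibition",
                                         "uncorrected_inhibition"))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("cohort sessions give each subject 180 labelled trials, reproducibly", {
  co <- simulate_cohort(cohort_spec(n_cn = 1, n_mci = 1), seed = 4)
  tr <- simulate_cohort_sessions(co[1, ], seed = 21)
  trials <- truth_of(tr)
  expect_equal(nrow(trials), 180)
  expect_equal(sum(trials$session == "PA"), 90)
  expect_identical(tr, simulate_cohort_sessions(co[1, ], seed = 21))
  expect_error(simulate_cohort_sessions(co[0, ], seed = 1), "non-empty")
})

test_that("fast outcome route and trace route share the same ground truth", {
  co <- simulate_cohort(cohort_spec(n_cn = 1, n_mci = 1), seed = 8)
  tr <- simulate_cohort_sessions(co, seed = 99)
  oc <- simulate_cohort_outcomes(co, seed = 99)
  j <- dplyr::inner_join(truth_of(tr), oc,
                         by = c("subject_id", "session", "block", "trial"))
  expect_equal(nrow(j), 360)
  expect_identical(j$truth, j$category)
})
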