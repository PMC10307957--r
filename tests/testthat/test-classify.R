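test_that("the 80 ms rule forces an anticipation", {
  tr <- saccade_trace(tibble::tibble(start = 1060, to = 10),
                      condition = "AS", side = "right")
  out <- classify_trial(tr)
  expect_equal(out$category, "anticipation")
  expect_lt(out$latency_ms, 80)
})

test_that("a timely target-directed saccade with an AOI fixation is correct", {
  tr <- saccade_trace(tibble::tibble(start = 1220, to = 9.8),
                      condition = "PS", side = "right")
  out <- classify_trial(tr)
  expect_equal(out$category, "correct")
  expect_lt(abs(out$latency_ms - 220), 10)
})

test_that("a late corrective saccade leaves the error uncorrected", {
  # AS trial: reflexive saccade captured by the target at 250 ms; the
  # corrective saccade starts 450 ms after the error's offset (> 400 ms)
  err_end <- 1250 + 21 + 2.2 * 10
  tr <- saccade_trace(tibble::tibble(start = c(1250, err_end + 450), to = c(10, -10)),
                      condition = "AS", side = "right")
  out <- classify_trial(tr)
  expect_equal(out$category, "uncorrected_inhibition")

  # the same correction 200 ms after the error's offset is corrected
  tr2 <- saccade_trace(tibble::tibble(start = c(1250, err_end + 200), to = c(10, -10)),
                       condition = "AS", side = "right")
  expect_equal(classify_trial(tr2)$category, "corrected_inhibition")
})

test_that("absence of movement is an omission, or correct inhibition on No-go", {
  still <- flat_trace(2500, condition = "Go", side = "left")
  expect_equal(classify_trial(still)$category, "omission")

  held <- flat_trace(2500, condition = "NoGo", side = "left")
  out <- classify_trial(held)
  expect_equal(out$category, "correct")
  expect_equal(out$fixation_duration_ms, 1500) # held to the end of the trial

  # holding 1200 ms before looking away stays correct with that duration
  late_break <- saccade_trace(tibble::tibble(start = 2200, to = 10),
                              condition = "NoGo", side = "left")
  out2 <- classify_trial(late_break)
  expect_equal(out2$category, "correct")
  # the exit time includes the saccade's travel to the 2.5 deg boundary
  expect_lt(abs(out2$fixation_duration_ms - 1200), 25)

  expect_error(classify_trial(flat_trace(1500, condition = "XX")), "condition")
})

test_that("every simulated trial receives exactly one category", {
  co <- simulate_cohort(cohort_spec(n_cn = 1, n_mci = 1), seed = 13)
  tr <- simulate_session_traces(co[2, ], "PA", seed = 5)
  oc <- score_session(tr)
  expect_equal(nrow(oc), 90)
  expect_true(all(oc$category %in% c("correct", "anticipation", "omission",
                                     "corrected_inhibition",
                                     "uncorrected_inhibition")))
  expect_true(all(!is.na(oc$latency_ms) == (oc$category %in%
    c("anticipation", "correct", "corrected_inhibition", "uncorrected_inhibition") &
      !(oc$condition == "NoGo" & oc$category == "correct"))))
})

test_that("thresholds act monotonically on the category counts", {
  co <- simulate_cohort(cohort_spec(n_cn = 1, n_mci = 1), seed = 17)
  tr <- simulate_session_traces(co[2, ], "PA", seed = 29)
  base <- score_session(tr)
  wide_ant <- score_session(tr, scoring_params(anticipation_max = 160))
  expect_gte(sum(wide_ant$category == "anticipation"),
             sum(base$category == "anticipation"))
  narrow_corr <- score_session(tr, scoring_params(correction_window = 150))
  expect_lte(sum(narrow_corr$category == "corrected_inhibition"),
             sum(base$category == "corrected_inhibition"))
})

test_that("scoring reproduces the simulator's labels on noise-free traces", {
  co <- simulate_cohort(cohort_spec(n_cn = 1, n_mci = 1), seed = 23)
  co$fixation_noise_sd <- 0
  co$p_inhibition <- pmax(co$p_inhibition, 0.3) # make corrections frequent
  tr <- simulate_session_traces(co[2, ], "GN", seed = 31)
  oc <- score_session(tr)
  j <- dplyr::inner_join(truth_of(tr), oc, by = c("block", "trial"))
  expect_equal(nrow(j), 90)
  expect_identical(j$category, j$truth)
})

test_that("degenerate inputs are scored defensively", {
  expect_equal(nrow(score_session(flat_trace(100)[0, ])), 0)
  bad <- flat_trace(2500, condition = "PS")
  bad$valid <- FALSE
  out <- classify_trial(bad)
  expect_equal(out$category, "omission")
  expect_true(out$flagged)
})
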