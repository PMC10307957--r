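make_outcomes <- function(condition, categories, latency = NA_real_,
                          fixdur = NA_real_) {
  tibble::tibble(
    subject_id = "S1", session = "X", block = 1L,
    trial = seq_along(categories), condition = condition, side = "right",
    category = categories,
    latency_ms = rep_len(latency, length(categories)),
    fixation_duration_ms = rep_len(fixdur, length(categories))
  )
}

test_that("the error summation rules produce the expected percentages", {
  # 30 No-go trials: 24 correct, 4 uncorrected, 2 corrected
  oc <- make_outcomes("NoGo", c(rep("correct", 24),
                                rep("uncorrected_inhibition", 4),
                                rep("corrected_inhibition", 2)),
                      fixdur = 1000)
  f <- aggregate_subject(oc)
  expect_equal(f$nogo_all_errors_pct, 20)
  expect_equal(f$nogo_uncorrected_pct, 100 * 4 / 30)
  expect_equal(f$nogo_corrected_pct, 100 * 2 / 30)
  expect_equal(f$nogo_correct_pct + f$nogo_all_errors_pct, 100)

  # 60 PS trials all correct at a constant 200 ms latency
  oc2 <- make_outcomes("PS", rep("correct", 60), latency = 200)
  f2 <- aggregate_subject(oc2)
  expect_equal(f2$ps_correct_pct, 100)
  expect_equal(f2$ps_latency_mean, 200)
  expect_equal(f2$ps_latency_sd, 0)

  # 30 AS trials: 3 anticipations + 2 omissions + 5 inhibition errors
  oc3 <- make_outcomes("AS", c(rep("anticipation", 3), rep("omission", 2),
                               rep("uncorrected_inhibition", 3),
                               rep("corrected_inhibition", 2),
                               rep("correct", 20)), latency = 250)
  f3 <- aggregate_subject(oc3)
  expect_equal(f3$as_all_errors_pct, 100 * 10 / 30)
  expect_equal(f3$as_anticipations_pct + f3$as_omissions_pct +
                 f3$as_uncorrected_pct + f3$as_corrected_pct +
                 f3$as_correct_pct, 100)
})

test_that("aggregation is invariant to trial order and guards its inputs", {
  oc <- make_outcomes("Go", sample(c(rep("correct", 40), rep("omission", 10),
                                     rep("anticipation", 10))), latency = 230)
  shuffled <- oc[sample(nrow(oc)), ]
  expect_equal(aggregate_subject(oc), aggregate_subject(shuffled))
  expect_error(aggregate_subject(oc[0, ]), "non-empty")
  oc_bad <- oc
  oc_bad$condition <- "Saccade"
  expect_error(aggregate_subject(oc_bad), "Unknown condition")
})

test_that("SDs are absent with fewer than two contributing trials", {
  oc <- make_outcomes("PS", c("correct", "omission"), latency = c(210, NA))
  f <- aggregate_subject(oc)
  expect_equal(f$ps_latency_mean, 210)
  expect_true(is.na(f$ps_latency_sd))
})

test_that("cohort aggregation matches the per-subject path and the column dictionary", {
  co <- simulate_cohort(cohort_spec(n_cn = 4, n_mci = 3), seed = 19)
  oc <- simulate_cohort_outcomes(co, seed = 19)
  agg <- aggregate_cohort(oc, co)
  # 30 EM variables + id, group, 3 demographics, mmse
  expect_equal(ncol(agg), 36)
  expect_equal(nrow(agg), 7)
  one <- aggregate_subject(oc[oc$subject_id == co$subject_id[1], ], co[1, ])
  expect_equal(as.data.frame(agg[1, names(one)]), as.data.frame(one))
  # per-condition percentage decomposition
  expect_equal(agg$ps_correct_pct + agg$ps_anticipations_pct +
                 agg$ps_omissions_pct + agg$ps_uncorrected_pct +
                 agg$ps_self_corrected_pct, rep(100, 7))
  expect_equal(agg$nogo_correct_pct + agg$nogo_uncorrected_pct +
                 agg$nogo_corrected_pct, rep(100, 7))
})

test_that("near-constant features are dropped and groups are required", {
  tb <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:10),
    group = rep(c("CN", "MCI"), 5),
    sex = rep(c("male", "female"), 5),
    age = rnorm(10, 70), education = rnorm(10, 12), mmse = rnorm(10, 27),
    ps_correct_pct = rnorm(10, 90),
    as_all_errors_pct = c(rep(5, 9), 8) # identical in all but one subject
  )
  expect_message(ft <- build_feature_table(tb), "as_all_errors_pct")
  expect_false("as_all_errors_pct" %in% names(ft))
  expect_true("sex_male" %in% names(ft))
  expect_error(build_feature_table(tb[tb$group == "CN", ]), "Both groups")
  expect_error(build_feature_table(tb[1, ]), "two subjects")
})

test_that("standardization centres, scales, respects reference stats and is idempotent", {
  ft <- toy_feature_table(seed = 2)
  z <- standardize(ft)
  roles <- attr(z, "roles")
  cont <- setdiff(names(roles), "sex_male")
  for (col in cont) {
    expect_equal(mean(z[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(z[[col]]), 1, tolerance = 1e-12)
  }
  expect_identical(z$sex_male, ft$sex_male)
  # idempotence with own statistics
  z2 <- standardize(z)
  expect_equal(as.data.frame(z2[names(roles)]), as.data.frame(z[names(roles)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # held-out scaling: test columns are not exactly centred
  odd <- seq(1, 89, by = 2)
  train <- build_feature_table(ft[odd, ])
  test <- build_feature_table(ft[-odd, ])
  ztr <- standardize(train)
  zte <- standardize(test, reference_stats = attr(ztr, "scale_stats"))
  expect_gt(abs(mean(zte$ps_latency_sd)), 1e-6)
  # zero-SD columns are named in the error
  broken <- ft
  broken$age <- 70
  expect_error(standardize(broken), "age")
})
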