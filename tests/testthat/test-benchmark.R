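test_that("the benchmark grid covers every algorithm x feature-set cell", {
  ft <- toy_feature_table(n_cn = 60, n_mci = 30, em_shift = 6, mmse_shift = 1.5,
                          seed = 14)
  cv <- cv_config(seed = 14, n_repeats = 1)
  bench <- run_all(ft, cv)
  expect_s3_class(bench, "em_benchmark")
  expect_equal(nrow(bench), 24)
  expect_equal(dplyr::n_distinct(bench$algorithm), 4)
  expect_equal(dplyr::n_distinct(bench$feature_set), 6)
  expect_true(all(bench$auroc >= 0 & bench$auroc <= 1, na.rm = TRUE))
  # deviance only for probability-calibrated learners
  expect_true(all(is.na(bench$deviance[bench$algorithm %in% c("RF", "SVM_RBF")])))
  expect_true(all(!is.na(bench$deviance[bench$algorithm %in% c("LR", "XGB")])))
  # no leakage: the outer split is disjoint
  sp <- attr(bench, "split")
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  # glance picks one row per feature set
  best <- glance(bench)
  expect_equal(nrow(best), 6)
  expect_true(all(best$auroc == tapply(bench$auroc, bench$feature_set,
                                       max)[best$feature_set]))
})

test_that("benchmarks are reproducible to the last digit under a fixed seed", {
  ft <- toy_feature_table(n_cn = 40, n_mci = 20, em_shift = 5, seed = 6)
  cv <- cv_config(seed = 9, n_repeats = 1, algorithms = c("LR", "XGB"),
                  feature_sets = c("Demo", "EM"))
  b1 <- run_all(ft, cv)
  b2 <- run_all(ft, cv)
  expect_identical(tidy(b1), tidy(b2))
})

test_that("a strongly separable cohort is classified almost perfectly", {
  ft <- toy_feature_table(n_cn = 40, n_mci = 20, em_shift = 40, seed = 4)
  x <- as.matrix(ft[, c("ps_latency_sd", "as_all_errors_pct")])
  y <- factor(ft$group, levels = c("CN", "MCI"))
  for (alg in c("LR", "RF", "SVM_RBF", "XGB")) {
    sel <- cross_validate(alg, x, y, cv = cv_config(n_repeats = 1, seed = 2))
    expect_gt(sel$cv_auroc_mean, 0.9)
  }
})

test_that("permutation importance isolates informative features", {
  withr::with_seed(33, {
    n <- 400
    x <- cbind(signal = rnorm(n), noise = rnorm(n))
    y <- factor(ifelse(rbinom(n, 1, plogis(2 * x[, "signal"])) == 1, "MCI", "CN"),
                levels = c("CN", "MCI"))
  })
  fit <- gazescreen:::fit_algorithm("LR", x, y, tibble::tibble(lambda = 0.001),
                                    seed = 1)
  imp <- permutation_importance(fit, x, y, n_perm = 50, seed = 2)
  expect_setequal(imp$rank, 1:2)
  expect_equal(imp$feature[imp$rank == 1], "signal")
  expect_lt(abs(imp$mean_auroc_drop[imp$feature == "noise"]), 0.05)

  # sole informative feature: the drop approaches auroc - 0.5
  x1 <- x[, "signal", drop = FALSE]
  fit1 <- gazescreen:::fit_algorithm("LR", x1, y, tibble::tibble(lambda = 0.001),
                                     seed = 1)
  base <- auroc(y, gazescreen:::predict_scores(fit1, x1))
  imp1 <- permutation_importance(fit1, x1, y, n_perm = 100, seed = 3)
  expect_lt(abs(imp1$mean_auroc_drop[1] - (base - 0.5)), 0.05)
})

test_that("failed cells are recorded without aborting the grid", {
  ft <- toy_feature_table(n_cn = 40, n_mci = 20, em_shift = 5, seed = 6)
  cv <- cv_config(seed = 9, n_repeats = 1, algorithms = "LR",
                  feature_sets = c("Demo", "EM"))
  cv$grids$LR <- tibble::tibble(lambda = -1)
  suppressMessages(bench <- run_all(ft, cv))
  expect_equal(nrow(bench), 2)
  expect_true(all(is.na(bench$auroc)))
})
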