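big_table <- function(seed = 1) {
  withr::with_seed(seed, {
    n <- 594
    grp <- c(rep("CN", 428), rep("MCI", 166))
    tibble::tibble(
      subject_id = sprintf("S%04d", 1:n), group = grp,
      age = rnorm(n, 72, 6), sex = sample(c("male", "female"), n, TRUE),
      education = rnorm(n, 13, 4),
      mmse = rnorm(n, 27, 2) - 1.2 * (grp == "MCI"),
      ps_latency_sd = rnorm(n, 45, 10) + 4 * (grp == "MCI"),
      as_all_errors_pct = rnorm(n, 20, 8) + 4 * (grp == "MCI")
    ) |> build_feature_table()
  })
}

test_that("the outer split is stratified, shared, and sized by per-class rounding", {
  ft <- big_table()
  cv <- cv_config(seed = 4)
  sp <- split_train_test(ft, cv)
  expect_equal(nrow(sp$train), round(0.8 * 428) + round(0.8 * 166)) # 475
  expect_equal(nrow(sp$train) + nrow(sp$test), 594)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_equal(sum(sp$train$group == "MCI"), round(0.8 * 166))
  # the partition depends only on ids and seed, not on the columns used
  ft2 <- ft
  ft2$ps_latency_sd <- ft2$ps_latency_sd * 2
  sp2 <- split_train_test(ft2, cv)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  expect_false(identical(sp$train$subject_id,
                         split_train_test(ft, cv_config(seed = 5))$train$subject_id))
})

test_that("splits that lose a class are rejected", {
  tiny <- toy_feature_table(n_cn = 2, n_mci = 2, seed = 1)
  expect_error(split_train_test(tiny, cv_config(train_fraction = 0.8)), "class")
})

test_that("cross-validation folds partition the data and keep both classes", {
  y <- factor(c(rep("CN", 40), rep("MCI", 15)), levels = c("CN", "MCI"))
  folds <- gazescreen:::make_folds(y, n_folds = 5, n_repeats = 3, seed = 2)
  expect_length(folds, 15)
  for (r in 0:2) {
    rep_folds <- folds[(r * 5 + 1):(r * 5 + 5)]
    expect_setequal(unlist(rep_folds), seq_along(y))
    for (v in rep_folds) {
      expect_equal(dplyr::n_distinct(y[v]), 2)
      expect_equal(dplyr::n_distinct(y[-v]), 2)
    }
  }
})

test_that("a single grid point is returned as selected", {
  ft <- toy_feature_table(em_shift = 6, seed = 8)
  x <- as.matrix(ft[, c("ps_latency_sd", "as_all_errors_pct")])
  y <- factor(ft$group, levels = c("CN", "MCI"))
  sel <- cross_validate("LR", x, y, grid = tibble::tibble(lambda = 0.05),
                        cv = cv_config(n_repeats = 1, seed = 3))
  expect_equal(sel$best_params$lambda, 0.05)
  expect_true(sel$cv_auroc_mean > 0 && sel$cv_auroc_mean < 1)
  expect_error(cross_validate("LR", x, y, grid = tibble::tibble()[0, ],
                              cv = cv_config(n_repeats = 1)), "Empty")
})

test_that("configuration invariants are enforced", {
  expect_error(cv_config(train_fraction = 1.2), "strictly between")
  expect_error(cv_config(n_folds = 1), "at least 2")
  expect_error(cv_config(algorithms = "MLP"))
})
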