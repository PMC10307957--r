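test_that("logistic fits agree with closed forms", {
  # intercept-only: logit of the marginal frequency
  y <- c(rep(1, 166), rep(0, 428))
  fit <- fit_logistic(y)
  expect_equal(unname(fit$coefficients[1]), log(166 / 428), tolerance = 1e-8)

  # 2x2 design: the slope odds ratio is the cross-product ratio
  x <- c(rep(1, 40), rep(0, 40))
  y2 <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  fit2 <- fit_logistic(y2, data.frame(x = x))
  expect_equal(exp(unname(fit2$coefficients["x"])), 9, tolerance = 1e-6)
})

test_that("coefficients maximize the likelihood (generic-optimizer oracle)", {
  withr::with_seed(5, {
    X <- data.frame(a = rnorm(50), b = rnorm(50))
    eta <- -0.3 + 0.8 * X$a - 0.5 * X$b
    y <- rbinom(50, 1, plogis(eta))
  })
  fit <- fit_logistic(y, X)
  negll <- function(beta) {
    lp <- beta[1] + as.matrix(X) %*% beta[2:3]
    -sum(y * lp - log1p(exp(lp)))
  }
  opt <- optim(c(0, 0, 0), negll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-6)
})

test_that("perfect separation is flagged rather than silently reported", {
  ft <- toy_feature_table(n_cn = 20, n_mci = 10, seed = 3)
  ft$ps_latency_sd <- as.numeric(ft$group == "MCI") + rnorm(30, 0, 1e-6)
  res <- estimate_or(ft, "ps_latency_sd")
  expect_true(res$separation)
  expect_error(fit_logistic(rep(1, 10)), "both classes")
})

test_that("Wald intervals are log-symmetric and per-SD scaling is applied", {
  ft <- toy_feature_table(em_shift = 8, seed = 11)
  res <- estimate_or(ft, "ps_latency_sd", adjusted = TRUE)
  expect_equal(log(res$ci_low) + log(res$ci_high), 2 * log(res$or),
               tolerance = 1e-12)
  expect_gt(res$or, 1) # feature elevated in MCI
  # rescaling the raw variable must not change the per-SD odds ratio
  ft2 <- ft
  ft2$ps_latency_sd <- ft2$ps_latency_sd * 1000
  res2 <- estimate_or(ft2, "ps_latency_sd", adjusted = TRUE)
  expect_equal(res2$or, res$or, tolerance = 1e-10)
})

test_that("crude and adjusted odds ratios coincide for independent covariates", {
  withr::with_seed(21, {
    n <- 4000
    x <- rnorm(n)
    grp <- ifelse(rbinom(n, 1, plogis(-1 + 0.4 * x)) == 1, "MCI", "CN")
    tb <- tibble::tibble(
      subject_id = sprintf("S%04d", 1:n), group = grp,
      age = rnorm(n, 72, 6), sex = sample(c("male", "female"), n, TRUE),
      education = rnorm(n, 13, 4), mmse = rnorm(n, 27, 2),
      ps_latency_sd = x
    )
  })
  ft <- build_feature_table(tb)
  crude <- estimate_or(ft, "ps_latency_sd", adjusted = FALSE)
  adj <- estimate_or(ft, "ps_latency_sd", adjusted = TRUE)
  expect_lt(abs(log(crude$or) - log(adj$or)), 0.05)
})

test_that("group comparisons reproduce the printed sex contingency p-value", {
  # 83/83 female/male in MCI vs 238/190 in CN
  tb <- tibble::tibble(
    group = c(rep("MCI", 166), rep("CN", 428)),
    sex = c(rep("female", 83), rep("male", 83), rep("female", 238), rep("male", 190)),
    age = rnorm(594, 72), education = rnorm(594, 13), mmse = rnorm(594, 27)
  )
  t1 <- table_one(tb)
  p_sex <- t1$p[t1$statistic_kind == "chisq"]
  expect_equal(round(p_sex, 1), 0.2)
  expect_match(t1$mci_summary[t1$statistic_kind == "chisq"], "83 \\(50%\\)")
})

test_that("the Wilcoxon comparison is null for identical distributions and matches ranks", {
  vals <- c(rnorm(50, 70, 5))
  tb <- tibble::tibble(
    group = rep(c("MCI", "CN"), each = 50),
    age = rep(vals, 2), education = rnorm(100, 13), mmse = rnorm(100, 27),
    sex = rep(c("male", "female"), 50)
  )
  t1 <- table_one(tb, continuous = "age")
  expect_gt(t1$p[t1$variable == "age"], 0.95)

  # rank-sum statistic equals the brute-force pair count on toy samples
  a <- c(1.2, 3.4, 2.2, 5.9, 4.1, 0.7)
  b <- c(2.9, 1.1, 6.3, 3.8, 0.2, 4.4)
  w <- wilcox.test(a, b, exact = FALSE)$statistic
  brute_u <- sum(outer(a, b, ">"))
  expect_equal(unname(w), brute_u)
})
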