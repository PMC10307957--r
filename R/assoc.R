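#' Fit a binomial logistic regression
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()], convergence tolerance tightened to 1e-10, up to 100
#' iterations) with the covariance taken as the inverse observed
#' information. Perfect or quasi-perfect separation — diverging
#' coefficients or degenerate fitted probabilities — is detected and
#' flagged rather than silently returning meaningless Wald intervals.
#'
#' @param y Binary outcome vector (0/1, logical, or two-level factor).
#' @param X Numeric predictor matrix or data frame (an intercept is added).
#' @return An object of class `logit_fit`: list with `coefficients`,
#'   `vcov`, `converged`, `separation`, `n`, `deviance`.
#' @export
fit_logistic <- function(y, X = NULL) {
  if (is.factor(y)) y <- as.integer(y == levels(y)[2])
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("Outcome must contain both classes.", call. = FALSE)
  }
  df <- if (is.null(X) || NCOL(X) == 0L) {
    data.frame(.y = y)
  } else {
    X <- as.data.frame(X)
    if (qr(cbind(1, as.matrix(X)))$rank < ncol(X) + 1L) {
      stop("Predictor matrix has collinear columns.", call. = FALSE)
    }
    cbind(data.frame(.y = y), X)
  }
  fit <- suppressWarnings(stats::glm(
    .y ~ ., data = df, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  probs <- stats::fitted(fit)
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 15) ||
    any(probs < 1e-10) || any(probs > 1 - 1e-10)
  structure(
    list(
      coefficients = stats::coef(fit),
      vcov = stats::vcov(fit),
      converged = fit$converged,
      separation = separation,
      n = length(y),
      deviance = fit$deviance
    ),
    class = "logit_fit"
  )
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("<logit_fit> n =", x$n,
      if (x$separation) " [separation flagged]" else "", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.logit_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Estimate the odds ratio of one eye-movement variable
#'
#' Crude model: MCI status regressed on the (z-scored) variable alone.
#' Adjusted model: age, sex and education added as covariates. Continuous
#' predictors are standardized on the full analysis sample, so odds ratios
#' are per 1 SD of the predictor; the 95% interval is the Wald interval
#' `exp(beta +/- 1.96 SE)` and the p-value comes from the Wald z test.
#'
#' @param table A [build_feature_table()] tibble (raw, unstandardized).
#' @param variable Name of the predictor column.
#' @param adjusted Add age, sex and education as covariates?
#' @return One-row tibble of class `or_result`: `variable`, `model`,
#'   `or`, `ci_low`, `ci_high`, `p`, `separation`.
#' @export
estimate_or <- function(table, variable, adjusted = FALSE) {
  if (!variable %in% names(table)) {
    stop("Variable not found: ", variable, call. = FALSE)
  }
  y <- as.integer(table$group == "MCI")
  v <- table[[variable]]
  if (!all(v %in% c(0, 1, NA))) {
    v <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  X <- data.frame(v = v)
  names(X) <- variable
  if (adjusted) {
    X$age <- table$age
    X$sex_male <- table$sex_male
    X$education <- table$education
  }
  keep <- stats::complete.cases(X) & !is.na(y)
  fit <- fit_logistic(y[keep], X[keep, , drop = FALSE])
  row <- tidy.logit_fit(fit)[2, ]
  tibble::tibble(
    variable = variable,
    model = if (adjusted) "adjusted" else "crude",
    or = exp(row$estimate),
    ci_low = exp(row$conf.low),
    ci_high = exp(row$conf.high),
    p = row$p.value,
    separation = fit$separation
  )
}

#' Crude and adjusted odds ratios for all eye-movement variables
#'
#' @param table A [build_feature_table()] tibble.
#' @param variables Columns to analyse; defaults to every eye-movement
#'   variable present.
#' @return A tibble with one row per variable and model.
#' @export
estimate_all_ors <- function(table, variables = NULL) {
  roles <- feature_roles(table)
  variables <- variables %||% names(roles)[roles == "em"]
  purrr::map_dfr(variables, function(v) {
    dplyr::bind_rows(
      estimate_or(table, v, adjusted = FALSE),
      estimate_or(table, v, adjusted = TRUE)
    )
  })
}

#' Group comparisons of demographics and MMSE
#'
#' Continuous variables are compared with the Wilcoxon rank-sum test
#' (normal approximation with tie and continuity correction) and
#' summarized as mean (SD); categorical variables with Pearson's
#' chi-squared test without continuity correction, summarized as n (%)
#' with the percentage rounded to an integer.
#'
#' @param table A [build_feature_table()] tibble (or any tibble with
#'   `group`, `age`, `education`, `mmse` and `sex` or `sex_male`).
#' @param continuous,categorical Variable names to compare.
#' @return A tibble: `variable`, `statistic_kind`, per-group summaries,
#'   `p`.
#' @export
table_one <- function(table,
                      continuous = intersect(c("age", "education", "mmse"), names(table)),
                      categorical = intersect(c("sex_male", "sex"), names(table))[1]) {
  if (dplyr::n_distinct(table$group) < 2L) {
    stop("Both groups must be present.", call. = FALSE)
  }
  mci <- table[table$group == "MCI", ]
  cn <- table[table$group == "CN", ]
  cont <- purrr::map_dfr(continuous, function(v) {
    w <- stats::wilcox.test(mci[[v]], cn[[v]], exact = FALSE, correct = TRUE)
    tibble::tibble(
      variable = v, statistic_kind = "wilcoxon",
      mci_summary = sprintf("%.2f (%.2f)", mean(mci[[v]], na.rm = TRUE),
                            stats::sd(mci[[v]], na.rm = TRUE)),
      cn_summary = sprintf("%.2f (%.2f)", mean(cn[[v]], na.rm = TRUE),
                           stats::sd(cn[[v]], na.rm = TRUE)),
      p = w$p.value
    )
  })
  cat_rows <- purrr::map_dfr(stats::na.omit(categorical), function(v) {
    x <- table[[v]]
    if (identical(v, "sex_male")) x <- ifelse(x == 1, "male", "female")
    tab <- table(x, table$group)
    ch <- stats::chisq.test(tab, correct = FALSE)
    n_summary <- function(g) {
      nf <- sum(x == "female" & table$group == g, na.rm = TRUE)
      sprintf("%d (%d%%)", nf, round(100 * nf / sum(table$group == g)))
    }
    tibble::tibble(
      variable = "sex (female)", statistic_kind = "chisq",
      mci_summary = n_summary("MCI"), cn_summary = n_summary("CN"),
      p = ch$p.value
    )
  })
  dplyr::bind_rows(cat_rows, cont)
}
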