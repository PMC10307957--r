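#' Run the full classification benchmark
#'
#' Evaluates every algorithm x feature-set cell on a shared stratified
#' 80/20 split: hyperparameters are selected by repeated stratified
#' cross-validation on the training side (SMOTE inside each fold), the
#' winning configuration is refit on the SMOTE-augmented full training
#' side, and the untouched test side is scored by AUROC, binomial deviance
#' (algorithms with calibrated probabilities only), and
#' sensitivity/specificity at the Youden-optimal threshold. A failed cell
#' is recorded as `NA` rather than aborting the grid.
#'
#' @param table A [build_feature_table()] tibble (raw, unstandardized).
#' @param cv A [cv_config()].
#' @return A tibble of class `em_benchmark`, one row per cell:
#'   `algorithm`, `feature_set`, `cv_auroc_mean`, `auroc`, `deviance`,
#'   `sensitivity`, `specificity`, `n_train`, `n_test`, `best_params`
#'   (list-column). Fitted models, ROC curves and the split are kept in
#'   attributes (`fits`, `roc`, `split`).
#' @export
run_all <- function(table, cv = cv_config()) {
  split <- split_train_test(table, cv)
  train <- split$train
  test <- split$test
  y_train <- factor(train$group, levels = c("CN", "MCI"))
  y_test <- factor(test$group, levels = c("CN", "MCI"))

  fits <- list()
  rocs <- list()
  cells <- list()
  for (fs in cv$feature_sets) {
    cols <- feature_set_columns(table, fs)
    x_train_raw <- as.matrix(train[, cols, drop = FALSE])
    x_test_raw <- as.matrix(test[, cols, drop = FALSE])
    for (alg in cv$algorithms) {
      key <- paste(alg, fs, sep = "|")
      cell <- tryCatch({
        sel <- cross_validate(alg, x_train_raw, y_train,
                              grid = cv$grids[[alg]], cv = cv)
        scaler <- fit_scaler(x_train_raw)
        x_train <- apply_scaler(x_train_raw, scaler)
        x_test <- apply_scaler(x_test_raw, scaler)
        sm <- smote_oversample(x_train, y_train,
                               k = min(cv$smote_k, sum(y_train == "MCI") - 1L),
                               seed = derive_seed(cv$seed, 5000L))
        fit <- fit_algorithm(alg, sm$x, sm$y, sel$best_params,
                             seed = derive_seed(cv$seed, 6000L))
        scores <- predict_scores(fit, x_test)
        yd <- youden_point(y_test, scores)
        fits[[key]] <- fit
        rocs[[key]] <- roc_points(y_test, scores)
        tibble::tibble(
          algorithm = alg, feature_set = fs,
          cv_auroc_mean = sel$cv_auroc_mean,
          auroc = auroc(y_test, scores),
          deviance = if (has_probabilities(alg)) {
            binomial_deviance(y_test, scores)
          } else NA_real_,
          sensitivity = yd$sensitivity, specificity = yd$specificity,
          n_train = nrow(train), n_test = nrow(test),
          best_params = list(sel$best_params)
        )
      }, error = function(e) {
        message("Cell ", key, " failed: ", conditionMessage(e))
        tibble::tibble(
          algorithm = alg, feature_set = fs,
          cv_auroc_mean = NA_real_, auroc = NA_real_, deviance = NA_real_,
          sensitivity = NA_real_, specificity = NA_real_,
          n_train = nrow(train), n_test = nrow(test),
          best_params = list(NULL)
        )
      })
      cells[[key]] <- cell
    }
  }
  out <- dplyr::bind_rows(cells)
  attr(out, "fits") <- fits
  attr(out, "roc") <- rocs
  attr(out, "split") <- list(train_ids = train$subject_id, test_ids = test$subject_id)
  attr(out, "cv_config") <- cv
  class(out) <- c("em_benchmark", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.em_benchmark <- function(x, ...) {
  out <- x
  attributes(out)[c("fits", "roc", "split", "cv_config")] <- NULL
  class(out) <- setdiff(class(out), "em_benchmark")
  tibble::as_tibble(out)
}

#' Best model per feature set
#'
#' Selects, within each feature set, the algorithm with the highest test
#' AUROC, breaking ties toward the lowest binomial deviance.
#'
#' @param x An `em_benchmark` tibble from [run_all()].
#' @param ... Unused.
#' @return One row per feature set.
#' @exportS3Method generics::glance
glance.em_benchmark <- function(x, ...) {
  tidy.em_benchmark(x) |>
    dplyr::group_by(.data$feature_set) |>
    dplyr::arrange(dplyr::desc(.data$auroc),
                   dplyr::coalesce(.data$deviance, Inf), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Permutation feature importance
#'
#' Permutes each test-set feature `n_perm` times and reports the mean
#' drop in AUROC relative to the unpermuted score, ranked descending.
#'
#' @param fit A fitted model from a benchmark (attribute `fits` of
#'   [run_all()]) or from `fit_algorithm`.
#' @param x Standardized test feature matrix.
#' @param y Test labels.
#' @param n_perm Permutations per feature (default 100).
#' @param seed Integer seed.
#' @return Tibble: `feature`, `mean_auroc_drop`, `sd_auroc_drop`, `rank`.
#' @export
permutation_importance <- function(fit, x, y, n_perm = 100L, seed = 1L) {
  x <- as.matrix(x)
  base <- auroc(y, predict_scores(fit, x))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
    drops <- vapply(seq_len(n_perm), function(p) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      base - auroc(y, predict_scores(fit, xp))
    }, numeric(1))
    tibble::tibble(
      feature = colnames(x)[j],
      mean_auroc_drop = mean(drops),
      sd_auroc_drop = stats::sd(drops)
    )
  })
  out$rank <- rank(-out$mean_auroc_drop, ties.method = "first")
  dplyr::arrange(out, .data$rank)
}
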