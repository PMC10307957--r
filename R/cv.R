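#' Cross-validation configuration
#'
#' Geometry and hyperparameter grids of the classification benchmark:
#' stratified 80/20 outer train/test split shared across algorithms and
#' feature sets, stratified `n_folds`-fold cross-validation repeated
#' `n_repeats` times on the training side, SMOTE with `smote_k`
#' neighbours applied inside each fold, and per-algorithm grids ordered
#' from least to most complex (the tie-break order).
#'
#' @param train_fraction Outer training fraction (default 0.8).
#' @param n_folds,n_repeats Cross-validation geometry (default 5 x 10).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param seed Master seed for splitting, folds, SMOTE and model fits.
#' @param algorithms Algorithms to run: subset of `"LR"`, `"RF"`,
#'   `"SVM_RBF"`, `"XGB"`.
#' @param feature_sets Feature sets to run (default all six).
#' @param grids Named list of hyperparameter tibbles; see
#'   [default_grids()].
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(train_fraction = 0.8, n_folds = 5L, n_repeats = 10L,
                      smote_k = 5L, seed = 1L,
                      algorithms = c("LR", "RF", "SVM_RBF", "XGB"),
                      feature_sets = feature_set_names(),
                      grids = default_grids()) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (n_folds < 2L) stop("`n_folds` must be at least 2.", call. = FALSE)
  algorithms <- match.arg(algorithms, c("LR", "RF", "SVM_RBF", "XGB"),
                          several.ok = TRUE)
  structure(
    list(train_fraction = train_fraction, n_folds = as.integer(n_folds),
         n_repeats = as.integer(n_repeats), smote_k = as.integer(smote_k),
         seed = as.integer(seed), algorithms = algorithms,
         feature_sets = feature_sets, grids = grids),
    class = "cv_config"
  )
}

#' Default hyperparameter grids
#'
#' Each grid is ordered from least to most complex; ties in mean
#' cross-validated AUROC resolve toward the earlier (simpler) row.
#' LR: ridge penalty strength (larger lambda = simpler). RF: 500 trees,
#' grid over the fraction of variables tried per split. SVM (RBF kernel):
#' cost grid. XGB: tree depth x boosting rounds at learning rate 0.1.
#'
#' @return Named list of tibbles.
#' @export
default_grids <- function() {
  list(
    LR = tibble::tibble(lambda = c(1, 0.1, 0.01, 0.001)),
    RF = tibble::tibble(mtry_frac = c(0.2, 0.45, 0.8)),
    SVM_RBF = tibble::tibble(cost = c(0.25, 1, 4)),
    XGB = tibble::tibble(max_depth = c(1L, 1L, 3L, 3L),
                         nrounds = c(50L, 150L, 50L, 150L))
  )
}

#' Stratified outer train/test split
#'
#' Splits subjects into train and test sides, stratified by group, with
#' per-class rounding of `train_fraction`. The partition depends only on
#' the row order (subject ids) and the seed, so every feature set and
#' algorithm in a benchmark shares it.
#'
#' @param table A [build_feature_table()] tibble.
#' @param cv A [cv_config()] (or anything with `train_fraction` and
#'   `seed`).
#' @return List with `train` and `test` tibbles.
#' @export
split_train_test <- function(table, cv = cv_config()) {
  y <- table$group
  if (dplyr::n_distinct(y) < 2L) stop("Both classes must be present.", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cv$seed, 271L))
  train_idx <- unlist(lapply(unique(y), function(g) {
    idx <- which(y == g)
    sample(idx, round(cv$train_fraction * length(idx)))
  }))
  train <- table[sort(train_idx), ]
  test <- table[setdiff(seq_len(nrow(table)), train_idx), ]
  if (dplyr::n_distinct(train$group) < 2L || dplyr::n_distinct(test$group) < 2L) {
    stop("A class vanished from the train or test side; cohort too small ",
         "for the requested split.", call. = FALSE)
  }
  list(train = train, test = test)
}

# Stratified repeated k-fold validation indices. Stratification guarantees
# both classes in every training side whenever each class has >= n_folds
# members; degenerate folds are re-drawn with a shifted seed.
make_folds <- function(y, n_folds, n_repeats, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  draw <- function(s) {
    set.seed(s)
    fold_id <- integer(length(y))
    for (g in unique(y)) {
      idx <- sample(which(y == g))
      fold_id[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    lapply(seq_len(n_folds), function(f) which(fold_id == f))
  }
  folds <- list()
  for (r in seq_len(n_repeats)) {
    s <- derive_seed(seed, r)
    for (try in 0:19) {
      candidate <- draw(derive_seed(s, try))
      ok <- all(vapply(candidate, function(v) {
        dplyr::n_distinct(y[v]) == 2L && dplyr::n_distinct(y[-v]) == 2L
      }, logical(1)))
      if (ok) break
      message("Degenerate fold re-drawn (repeat ", r, ").")
    }
    folds <- c(folds, candidate)
  }
  folds
}

# Column means/SDs of the continuous columns of a training matrix, applied
# to any matrix; binary (0/1) columns pass through.
fit_scaler <- function(x) {
  cont <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    !all(v %in% c(0, 1) | is.na(v))
  }, logical(1))
  mu <- ifelse(cont, colMeans(x, na.rm = TRUE), 0)
  sd <- ifelse(cont, apply(x, 2, stats::sd, na.rm = TRUE), 1)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Select hyperparameters by repeated stratified cross-validation
#'
#' For every grid row: in each fold, standardize with fold-train
#' statistics, oversample the fold-train side with SMOTE, fit, and score
#' the untouched fold-validation rows by AUROC. The grid row with the
#' highest mean AUROC wins; ties break toward the earlier (simpler) row.
#'
#' @param algorithm `"LR"`, `"RF"`, `"SVM_RBF"` or `"XGB"`.
#' @param x Numeric feature matrix (unstandardized).
#' @param y Factor with levels `c("CN", "MCI")`.
#' @param grid Hyperparameter tibble (non-empty), ordered simple to
#'   complex.
#' @param cv A [cv_config()].
#' @return List: `best_params` (one-row tibble), `cv_auroc_mean`,
#'   `cv_table` (per-grid-row mean AUROC).
#' @export
cross_validate <- function(algorithm, x, y, grid = NULL, cv = cv_config()) {
  grid <- grid %||% cv$grids[[algorithm]]
  if (is.null(grid) || nrow(grid) == 0L) stop("Empty hyperparameter grid.", call. = FALSE)
  folds <- make_folds(y, cv$n_folds, cv$n_repeats, derive_seed(cv$seed, 733L))
  means <- vapply(seq_len(nrow(grid)), function(gi) {
    aucs <- vapply(seq_along(folds), function(fi) {
      val <- folds[[fi]]
      xtr <- x[-val, , drop = FALSE]; ytr <- y[-val]
      xva <- x[val, , drop = FALSE]; yva <- y[val]
      scaler <- fit_scaler(xtr)
      xtr <- apply_scaler(xtr, scaler)
      xva <- apply_scaler(xva, scaler)
      sm <- smote_oversample(xtr, ytr, k = min(cv$smote_k, sum(ytr == "MCI") - 1L),
                             seed = derive_seed(cv$seed, 1000L + fi))
      fit <- fit_algorithm(algorithm, sm$x, sm$y, grid[gi, ],
                           seed = derive_seed(cv$seed, 2000L + fi))
      auroc(yva, predict_scores(fit, xva))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(means)
  list(
    best_params = grid[best, , drop = FALSE],
    cv_auroc_mean = means[best],
    cv_table = dplyr::bind_cols(grid, tibble::tibble(cv_auroc_mean = means))
  )
}
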