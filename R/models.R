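# Uniform fit/predict surface over the four benchmark learners. `x` is a
# standardized numeric matrix with column names; `y` a factor with levels
# c("CN", "MCI"). Scores returned by `predict_scores()` increase with the
# modelled probability of MCI.

fit_algorithm <- function(algorithm, x, y, params, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(y, levels = c("CN", "MCI"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  model <- switch(algorithm,
    LR = {
      if (ncol(x) >= 2L) {
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = params$lambda, standardize = FALSE)
      } else {
        df <- data.frame(.y = as.integer(y == "MCI"), x)
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      }
    },
    RF = ranger::ranger(
      x = as.data.frame(x), y = y, probability = TRUE, num.trees = 500L,
      mtry = max(1L, round(params$mtry_frac * ncol(x))),
      seed = as.integer(seed), num.threads = 1L
    ),
    SVM_RBF = e1071::svm(
      x = x, y = y, kernel = "radial", cost = params$cost,
      scale = FALSE, probability = TRUE
    ),
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = 0.1, nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == "MCI"), nthread = 1L),
      nrounds = params$nrounds
    ),
    stop("Unknown algorithm: ", algorithm, call. = FALSE)
  )
  structure(
    list(algorithm = algorithm, model = model, features = colnames(x),
         params = params),
    class = "gs_fit"
  )
}

predict_scores <- function(fit, x) {
  x <- as.matrix(x)
  colnames(x) <- fit$features
  switch(fit$algorithm,
    LR = {
      if (inherits(fit$model, "glmnet")) {
        as.numeric(stats::predict(fit$model, newx = x, type = "response"))
      } else {
        as.numeric(stats::predict(fit$model, newdata = as.data.frame(x),
                                  type = "response"))
      }
    },
    RF = stats::predict(fit$model, data = as.data.frame(x),
                        num.threads = 1L)$predictions[, "MCI"],
    SVM_RBF = {
      pr <- stats::predict(fit$model, newdata = x, probability = TRUE)
      attr(pr, "probabilities")[, "MCI"]
    },
    XGB = as.numeric(stats::predict(fit$model,
                                    newdata = xgboost::xgb.DMatrix(x, nthread = 1L)))
  )
}

# Whether a learner's scores are calibrated probabilities whose deviance is
# reported (logistic regression and boosting); random-forest vote shares
# and Platt-scaled SVM outputs are used for ranking only.
has_probabilities <- function(algorithm) algorithm %in% c("LR", "XGB")
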