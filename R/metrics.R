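as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) labels <- labels == "MCI"
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("Labels must be binary.", call. = FALSE)
  if (length(unique(y)) < 2L) stop("Both classes must be present.", call. = FALSE)
  y
}

#' Area under the ROC curve
#'
#' The rank (Mann-Whitney) statistic: the probability that a randomly
#' chosen case is scored above a randomly chosen control, with ties
#' counting one half. Invariant to strictly monotone transforms of the
#' scores.
#'
#' @param labels Binary labels (0/1, logical, or a CN/MCI factor where
#'   `"MCI"` is the case).
#' @param scores Numeric scores, higher meaning more case-like.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) stop("Length mismatch.", call. = FALSE)
  r <- rank(scores)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return Tibble `threshold`, `fpr`, `tpr`, one row per distinct score
#'   (plus the endpoints); a point's rates refer to calling scores
#'   `>= threshold` positive.
#' @export
roc_points <- function(labels, scores) {
  y <- as_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  purrr::map_dfr(thr, function(th) {
    pos <- scores >= th
    tibble::tibble(
      threshold = th,
      fpr = sum(pos & y == 0L) / sum(y == 0L),
      tpr = sum(pos & y == 1L) / sum(y == 1L)
    )
  })
}

#' Sensitivity and specificity at the Youden-optimal threshold
#'
#' @inheritParams auroc
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`.
#' @export
youden_point <- function(labels, scores) {
  pts <- roc_points(labels, scores)
  i <- which.max(pts$tpr - pts$fpr)
  tibble::tibble(
    threshold = pts$threshold[i],
    sensitivity = pts$tpr[i],
    specificity = 1 - pts$fpr[i]
  )
}

#' Binomial deviance
#'
#' `-2 * sum(y log p + (1 - y) log(1 - p))`, with probabilities clipped to
#' `[1e-15, 1 - 1e-15]`.
#'
#' @param labels Binary labels.
#' @param probabilities Predicted case probabilities in \[0, 1\].
#' @return Non-negative deviance.
#' @export
binomial_deviance <- function(labels, probabilities) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- (if (is.factor(labels)) as.character(labels) else labels) == "MCI"
  }
  y <- as.numeric(labels)
  if (length(y) != length(probabilities)) stop("Length mismatch.", call. = FALSE)
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("Probabilities must lie in [0, 1].", call. = FALSE)
  }
  p <- pmin(pmax(probabilities, 1e-15), 1 - 1e-15)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}
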