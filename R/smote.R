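#' SMOTE oversampling of the minority class
#'
#' Synthesizes minority-class rows until the classes reach parity. Each
#' synthetic row is `x + u * (nn - x)` for a randomly chosen minority row
#' `x`, one of its `k` nearest minority neighbours `nn` (Euclidean
#' distance on the supplied feature columns, which are expected to be
#' standardized), and `u ~ Uniform(0, 1)`. Intended for use inside
#' cross-validation folds only — never on validation rows or the outer
#' test set.
#'
#' @param x Numeric matrix (or data frame) of features.
#' @param y Binary labels aligned with the rows of `x`.
#' @param k Number of nearest neighbours (reduced with a warning when the
#'   minority class has fewer than `k + 1` rows).
#' @param seed Integer seed.
#' @param u Optional fixed interpolation weight (testing hook; `NULL`
#'   draws Uniform(0, 1) weights).
#' @return List with the augmented `x` matrix, `y` labels, and a logical
#'   `synthetic` marker for the appended rows.
#' @export
smote_oversample <- function(x, y, k = 5L, seed = 1L, u = NULL) {
  x <- as.matrix(x)
  y_bin <- as_binary_labels(y)
  counts <- table(y_bin)
  minority <- as.integer(names(counts)[which.min(counts)])
  n_min <- min(counts)
  n_needed <- max(counts) - n_min
  if (n_min < 2L) stop("Minority class must have at least two rows.", call. = FALSE)
  if (k < 1L) stop("`k` must be at least 1.", call. = FALSE)
  if (k > n_min - 1L) {
    warning("`k` reduced to ", n_min - 1L, " (minority size).", call. = FALSE)
    k <- n_min - 1L
  }
  if (n_needed == 0L) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  idx_min <- which(y_bin == minority)
  xm <- x[idx_min, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))

  base <- sample.int(n_min, n_needed, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, n_needed, replace = TRUE))]
  w <- if (is.null(u)) stats::runif(n_needed) else rep(u, n_needed)
  synth <- xm[base, , drop = FALSE] + w * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])

  min_label <- y[idx_min[1]]
  y_out <- if (is.factor(y)) {
    factor(c(as.character(y), rep(as.character(min_label), n_needed)),
           levels = levels(y))
  } else {
    c(y, rep(min_label, n_needed))
  }
  list(
    x = rbind(x, synth),
    y = y_out,
    synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_needed))
  )
}
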