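#' Scoring parameters
#'
#' Thresholds of the velocity-based saccade detector and the trial
#' classification rules. Outcome-rule constants follow the task
#' definitions: saccades launched less than `anticipation_max` (80) ms
#' after target onset are anticipations; absence of any saccade within
#' `omission_window` (500) ms is an omission (or, on No-go trials with the
#' centre fixation held, a correct inhibition); an inhibition error counts
#' as corrected when a corrective saccade re-establishes the correct gaze
#' region within `correction_window` (400) ms of the erroneous saccade's
#' offset with an ensuing fixation dispersion of at most
#' `correction_stability` (1) degree. Detector constants
#' (`velocity_threshold` 30 deg/s, `min_saccade_amplitude` 1 deg,
#' `min_saccade_duration` 10 ms, 5-sample smoothing) are standard
#' velocity-threshold (I-VT) practice at 300 Hz. `anticipation_prelude`
#' admits saccades launched up to 200 ms before onset as anticipations;
#' `stability_window` (150 ms) is the span over which the post-correction
#' fixation's dispersion is assessed.
#'
#' @param velocity_threshold Speed threshold, deg/s.
#' @param min_saccade_amplitude Minimum saccade amplitude, deg.
#' @param min_saccade_duration Merge gap / minimum duration, ms.
#' @param aoi_radius,center_radius Radii of the target and centre areas of
#'   interest, deg.
#' @param anticipation_max,omission_window,correction_window,correction_stability
#'   Outcome-rule constants (ms, ms, ms, deg).
#' @param smoothing_window Moving-average width, samples (odd).
#' @param anticipation_prelude Pre-onset window admitted as anticipation, ms.
#' @param stability_window Span for the correction-stability check, ms.
#' @param max_bridge_gap Longest invalid-sample gap bridged by linear
#'   interpolation, ms.
#' @param min_fixation_duration Shortest interval reported as fixation, ms.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(velocity_threshold = 30,
                           min_saccade_amplitude = 1,
                           min_saccade_duration = 10,
                           aoi_radius = 2.5,
                           center_radius = 2.5,
                           anticipation_max = 80,
                           omission_window = 500,
                           correction_window = 400,
                           correction_stability = 1.0,
                           smoothing_window = 5,
                           anticipation_prelude = 200,
                           stability_window = 150,
                           max_bridge_gap = 50,
                           min_fixation_duration = 60) {
  p <- as.list(environment())
  if (any(unlist(p) <= 0)) stop("All scoring parameters must be positive.", call. = FALSE)
  if (anticipation_max >= omission_window) {
    stop("`anticipation_max` must be smaller than `omission_window`.", call. = FALSE)
  }
  structure(p, class = "scoring_params")
}

# Linear interpolation across invalid samples; gaps at least `max_gap` ms
# long (or touching the trace edge) stay NA and split detected events.
bridge_gaps <- function(t, v, max_gap) {
  if (!anyNA(v)) return(v)
  na <- is.na(v)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    if (i0 == 1L || i1 == length(v)) next
    gap <- t[i1 + 1L] - t[i0 - 1L]
    if (gap < max_gap) {
      v[i0:i1] <- v[i0 - 1L] + (v[i1 + 1L] - v[i0 - 1L]) *
        (t[i0:i1] - t[i0 - 1L]) / gap
    }
  }
  v
}

moving_average <- function(v, w) {
  if (w <= 1L) return(v)
  as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
}

# Smoothed positions and point-to-point speed for one trial's samples.
trace_kinematics <- function(trace, params) {
  t <- trace$t_ms
  x <- ifelse(trace$valid, trace$x_deg, NA_real_)
  y <- ifelse(trace$valid, trace$y_deg, NA_real_)
  x <- bridge_gaps(t, x, params$max_bridge_gap)
  y <- bridge_gaps(t, y, params$max_bridge_gap)
  sx <- moving_average(x, params$smoothing_window)
  sy <- moving_average(y, params$smoothing_window)
  n <- length(t)
  speed <- rep(NA_real_, n)
  if (n >= 3L) {
    dt2 <- t[3:n] - t[1:(n - 2)]
    vx <- (sx[3:n] - sx[1:(n - 2)]) / dt2 * 1000
    vy <- (sy[3:n] - sy[1:(n - 2)]) / dt2 * 1000
    speed[2:(n - 1)] <- sqrt(vx^2 + vy^2)
  }
  list(t = t, sx = sx, sy = sy, speed = speed)
}

#' Detect saccades in a gaze trace
#'
#' Velocity-threshold (I-VT) detection: positions are smoothed with a
#' moving average, differentiated to speed by central differences, and
#' runs of samples above `velocity_threshold` become candidate saccades.
#' Runs separated by less than `min_saccade_duration` ms are merged, and
#' events with horizontal amplitude below `min_saccade_amplitude` are
#' discarded. Invalid samples are bridged by linear interpolation when the
#' gap is shorter than `max_bridge_gap` ms; longer gaps split events.
#'
#' @param trace Tibble of one trial's samples with columns `t_ms`,
#'   `x_deg`, `y_deg`, `valid`.
#' @param params A [scoring_params()] list.
#' @return A tibble of events ordered by onset: `onset`, `offset` (ms, in
#'   trace time), `amplitude` (deg, signed horizontal), `peak_velocity`
#'   (deg/s). An all-invalid trace yields zero rows with attribute
#'   `flagged = TRUE` and a warning.
#' @export
detect_saccades <- function(trace, params = scoring_params()) {
  if (nrow(trace) < 2L) stop("Trace must contain at least two samples.", call. = FALSE)
  empty <- tibble::tibble(onset = numeric(), offset = numeric(),
                          amplitude = numeric(), peak_velocity = numeric())
  if (!any(trace$valid)) {
    warning("Trace has no valid samples; no events detected.", call. = FALSE)
    attr(empty, "flagged") <- TRUE
    return(empty)
  }
  k <- trace_kinematics(trace, params)
  above <- !is.na(k$speed) & k$speed > params$velocity_threshold
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  # merge runs separated by less than min_saccade_duration ms of clean signal
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      between <- (merged$end[last] + 1L):(runs$start[i] - 1L)
      gap_ms <- k$t[runs$start[i]] - k$t[merged$end[last]]
      if (gap_ms < params$min_saccade_duration && !anyNA(k$speed[between])) {
        merged$end[last] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }

  n <- length(k$t)
  events <- purrr::map_dfr(seq_len(nrow(merged)), function(i) {
    s <- merged$start[i]; e <- merged$end[i]
    pre <- max(s - 1L, 1L); post <- min(e + 1L, n)
    tibble::tibble(
      onset = k$t[s],
      offset = k$t[post],
      amplitude = k$sx[post] - k$sx[pre],
      peak_velocity = max(k$speed[s:e], na.rm = TRUE)
    )
  })
  events <- events[!is.na(events$amplitude) &
                     abs(events$amplitude) >= params$min_saccade_amplitude, ]
  events[order(events$onset), ]
}

max_pairwise_distance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(0)
  max(stats::dist(cbind(x, y)))
}

#' Detect fixations in a gaze trace
#'
#' Inter-saccadic intervals become fixations when they last at least
#' `min_fixation_duration` ms. Dispersion is the maximum pairwise distance
#' between (smoothed) positions within the interval; the centroid is their
#' mean.
#'
#' @inheritParams detect_saccades
#' @param .saccades,.k Precomputed [detect_saccades()] output and
#'   kinematics, reused by the trial classifier; leave `NULL` otherwise.
#' @return A tibble: `start`, `end` (ms), `centroid_x`, `centroid_y`
#'   (deg), `dispersion` (deg).
#' @export
detect_fixations <- function(trace, params = scoring_params(),
                             .saccades = NULL, .k = NULL) {
  saccades <- .saccades %||% detect_saccades(trace, params)
  if (isTRUE(attr(saccades, "flagged"))) {
    out <- tibble::tibble(start = numeric(), end = numeric(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          dispersion = numeric())
    attr(out, "flagged") <- TRUE
    return(out)
  }
  k <- .k %||% trace_kinematics(trace, params)
  bounds <- c(min(k$t), rbind(saccades$onset, saccades$offset), max(k$t))
  starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  purrr::map_dfr(seq_along(starts), function(i) {
    if (ends[i] - starts[i] < params$min_fixation_duration) return(NULL)
    idx <- k$t >= starts[i] & k$t <= ends[i] & !is.na(k$sx)
    if (sum(idx) < 2L) return(NULL)
    tibble::tibble(
      start = starts[i], end = ends[i],
      centroid_x = mean(k$sx[idx]), centroid_y = mean(k$sy[idx]),
      dispersion = max_pairwise_distance(k$sx[idx], k$sy[idx])
    )
  })
}
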