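# Is a fixation centroid inside a circular AOI?
in_aoi <- function(fix, cx, cy, radius) {
  sqrt((fix$centroid_x - cx)^2 + (fix$centroid_y - cy)^2) <= radius
}

# Dispersion of the first `window` ms of a fixation, on smoothed positions.
stability_dispersion <- function(k, start, window) {
  idx <- k$t >= start & k$t <= start + window & !is.na(k$sx)
  if (sum(idx) < 2L) return(0)
  max_pairwise_distance(k$sx[idx], k$sy[idx])
}

# Time (ms after target onset) at which gaze first leaves the centre region.
center_exit_time <- function(k, target_onset, trial_end, radius) {
  idx <- which(k$t >= target_onset & !is.na(k$sx))
  if (length(idx) == 0L) return(trial_end - target_onset)
  outside <- sqrt(k$sx[idx]^2 + k$sy[idx]^2) > radius
  if (!any(outside)) return(trial_end - target_onset)
  k$t[idx[which(outside)[1]]] - target_onset
}

outcome_row <- function(condition, side, category,
                        latency = NA_real_, fixation_duration = NA_real_,
                        first_onset = NA_real_, first_amplitude = NA_real_,
                        flagged = FALSE) {
  tibble::tibble(
    condition = condition, side = side, category = category,
    latency_ms = latency, fixation_duration_ms = fixation_duration,
    first_saccade_onset = first_onset, first_saccade_amplitude = first_amplitude,
    flagged = flagged
  )
}

#' Classify a single trial
#'
#' Applies the outcome taxonomy to one trial's gaze trace. Decision order:
#' (1) a first saccade launched between `anticipation_prelude` ms before
#' and `anticipation_max` ms after target onset is an anticipation;
#' (2) if no saccade starts within `omission_window` ms of onset, the trial
#' is an omission — except on No-go trials, where a maintained central
#' fixation is a correct inhibition and the fixation duration is the time
#' gaze remains within the centre region after onset; (3) otherwise the
#' first saccade's direction is evaluated: PS/Go trials are correct when it
#' heads toward the target side and a subsequent fixation lands in the
#' target AOI, AS trials when it heads away with a fixation in the mirror
#' AOI; (4) a wrong-direction first saccade (or any saccade on No-go) is an
#' inhibition error, corrected when a corrective saccade re-establishes the
#' correct gaze region within `correction_window` ms of the erroneous
#' saccade's offset with a stable (dispersion <= `correction_stability`
#' deg) ensuing fixation, else uncorrected. Latency is the first saccade's
#' onset minus target onset.
#'
#' @param trace One trial's samples: columns `t_ms`, `x_deg`, `y_deg`,
#'   `valid`, plus `condition` and `side` (or pass them explicitly).
#' @param params A [scoring_params()] list.
#' @param target_onset Target onset, ms from trace start.
#' @param condition,side Trial metadata; defaults come from the trace.
#' @return One-row tibble: `condition`, `side`, `category`, `latency_ms`,
#'   `fixation_duration_ms` (correct No-go only), first-saccade onset and
#'   amplitude, and a `flagged` indicator for traces without valid samples.
#' @export
classify_trial <- function(trace, params = scoring_params(), target_onset = 1000,
                           condition = NULL, side = NULL) {
  condition <- condition %||% trace$condition[1]
  side <- side %||% trace$side[1]
  if (is.null(condition) || !condition %in% c("PS", "AS", "Go", "NoGo")) {
    stop("Unknown trial condition: ", format(condition), call. = FALSE)
  }
  trial_end <- max(trace$t_ms)
  target_x <- if (identical(side, "right")) 10 else -10

  saccades <- withCallingHandlers(
    detect_saccades(trace, params),
    warning = function(w) invokeRestart("muffleWarning")
  )
  flagged <- isTRUE(attr(saccades, "flagged"))
  k <- trace_kinematics(trace, params)

  rel <- saccades$onset - target_onset
  cand <- saccades[rel >= -params$anticipation_prelude, , drop = FALSE]
  rel <- rel[rel >= -params$anticipation_prelude]

  # (1) anticipation
  if (nrow(cand) > 0L && rel[1] < params$anticipation_max) {
    return(outcome_row(condition, side, "anticipation",
                       latency = rel[1], first_onset = rel[1],
                       first_amplitude = cand$amplitude[1]))
  }

  # (2) no saccade within the omission window
  responded <- nrow(cand) > 0L && rel[1] <= params$omission_window
  if (!responded) {
    if (condition == "NoGo") {
      if (flagged) {
        return(outcome_row(condition, side, "correct", flagged = TRUE))
      }
      idx <- k$t >= target_onset & k$t <= target_onset + params$omission_window &
        !is.na(k$sx)
      held <- all(sqrt(k$sx[idx]^2 + k$sy[idx]^2) <= params$center_radius)
      if (held) {
        dur <- center_exit_time(k, target_onset, trial_end, params$center_radius)
        return(outcome_row(condition, side, "correct", fixation_duration = dur))
      }
      return(outcome_row(condition, side, "uncorrected_inhibition"))
    }
    return(outcome_row(condition, side, "omission", flagged = flagged))
  }

  # (3) evaluate the first responding saccade
  f <- cand[1, ]
  latency <- rel[1]
  toward <- sign(f$amplitude) == sign(target_x)
  fixations <- detect_fixations(trace, params, .saccades = saccades, .k = k)
  fix_after <- function(t0) {
    fx <- fixations[fixations$start >= t0 - 1e-9, , drop = FALSE]
    if (nrow(fx) == 0L) NULL else fx[1, ]
  }
  goal_x <- switch(condition, PS = target_x, Go = target_x, AS = -target_x, NoGo = 0)
  goal_radius <- if (condition == "NoGo") params$center_radius else params$aoi_radius

  if (condition %in% c("PS", "Go", "AS")) {
    right_direction <- if (condition == "AS") !toward else toward
    fx <- fix_after(f$offset)
    if (right_direction && !is.null(fx) &&
        in_aoi(fx, goal_x, 0, params$aoi_radius)) {
      return(outcome_row(condition, side, "correct",
                         latency = latency, first_onset = latency,
                         first_amplitude = f$amplitude))
    }
  }

  # (4) inhibition error: look for a corrective saccade into the correct
  # region within the correction window, with a stable ensuing fixation
  later <- saccades[saccades$onset > f$offset - 1e-9, , drop = FALSE]
  corrected <- FALSE
  if (nrow(later) > 0L) {
    for (i in seq_len(nrow(later))) {
      gap <- later$onset[i] - f$offset
      if (gap > params$correction_window) break
      fx <- fix_after(later$offset[i])
      if (is.null(fx)) next
      if (in_aoi(fx, goal_x, 0, goal_radius) &&
          stability_dispersion(k, fx$start, params$stability_window) <=
            params$correction_stability) {
        corrected <- TRUE
        break
      }
    }
  }
  outcome_row(condition, side,
              if (corrected) "corrected_inhibition" else "uncorrected_inhibition",
              latency = latency, first_onset = latency,
              first_amplitude = f$amplitude)
}

#' Score a set of gaze traces
#'
#' Classifies every trial in a long gaze tibble (as produced by
#' [simulate_cohort_sessions()] or read with [read_gaze_csv()]), preserving
#' trial order within each subject and session.
#'
#' @param traces Gaze samples with identifier columns (`subject_id` and/or
#'   `session`, `block`, `trial`) plus `condition`, `side`, `t_ms`,
#'   `x_deg`, `y_deg`, `valid`.
#' @param params A [scoring_params()] list.
#' @param target_onset Target onset, ms from trial start.
#' @return An outcomes tibble, one row per trial, with the identifier
#'   columns followed by the columns of [classify_trial()].
#' @export
score_session <- function(traces, params = scoring_params(), target_onset = 1000) {
  id_cols <- intersect(c("subject_id", "session", "block", "trial"), names(traces))
  if (nrow(traces) == 0L) {
    return(tibble::tibble(condition = character(), side = character(),
                          category = character()))
  }
  if (length(id_cols) == 0L) {
    return(classify_trial(traces, params, target_onset))
  }
  nested <- traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    tidyr::nest() |>
    dplyr::ungroup()
  outcomes <- purrr::map2(nested$data, seq_len(nrow(nested)), function(d, i) {
    tryCatch(
      classify_trial(d, params, target_onset),
      error = function(e) {
        ids <- paste(id_cols, unlist(nested[i, id_cols]), sep = "=", collapse = ", ")
        stop("Failed to score trial (", ids, "): ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  dplyr::bind_cols(nested[id_cols], dplyr::bind_rows(outcomes))
}
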