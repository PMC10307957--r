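#' @keywords internal
"_PACKAGE"

# Saccade latencies are drawn from a shifted lognormal (shift 70 ms) with the
# subject's mean/SD moments, truncated to (100, 470) ms so that a correct
# trial cannot cross the 80 ms anticipation or 500 ms omission boundary
# through sampling alone.
r_latency <- function(n, mu, sigma, lo = 100, hi = 470, shift = 70) {
  m <- pmax(mu - shift, 5)
  sdlog <- sqrt(log(1 + (sigma / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  p <- stats::runif(n, stats::plnorm(lo - shift, meanlog, sdlog),
                    stats::plnorm(hi - shift, meanlog, sdlog))
  shift + stats::qlnorm(p, meanlog, sdlog)
}

# Sample the latent outcome of every trial in a schedule for one subject.
# PS/Go trials can also produce (rare) wrong-direction inhibition errors,
# at `direction_error_scale` times the subject's inhibition probability.
sample_trial_latents <- function(profile, schedule, direction_error_scale = 0.35) {
  n <- nrow(schedule)
  u <- stats::runif(n)
  u_corr <- stats::runif(n)
  is_nogo <- schedule$condition == "NoGo"
  is_as <- schedule$condition == "AS"
  p_dir <- ifelse(is_as, profile$p_inhibition,
                  ifelse(is_nogo, 0, direction_error_scale * profile$p_inhibition))

  category <- character(n)
  # No-go: inhibition error or correct hold
  nogo_inh <- is_nogo & u < profile$p_inhibition
  category[is_nogo] <- "correct"
  category[nogo_inh] <- ifelse(u_corr[nogo_inh] < profile$p_correction,
                               "corrected_inhibition", "uncorrected_inhibition")
  # PS / AS / Go: anticipation, omission, inhibition, else correct
  resp <- !is_nogo
  p_ant <- profile$p_anticipation
  p_om <- profile$p_omission
  cat_resp <- ifelse(u < p_ant, "anticipation",
               ifelse(u < p_ant + p_om, "omission",
                ifelse(u < p_ant + p_om + p_dir,
                       ifelse(u_corr < profile$p_correction,
                              "corrected_inhibition", "uncorrected_inhibition"),
                       "correct")))
  category[resp] <- cat_resp[resp]

  latency <- rep(NA_real_, n)
  needs_lat <- category %in% c("correct", "corrected_inhibition", "uncorrected_inhibition") &
    !(is_nogo & category == "correct")
  latency[needs_lat] <- r_latency(sum(needs_lat), profile$latency_mu, profile$latency_sigma)
  ant <- category == "anticipation"
  latency[ant] <- stats::runif(sum(ant), -150, 70)

  # Correct No-go trials hold central fixation for a subject-specific time,
  # then look away; the hold exceeds the 500 ms window by construction.
  hold <- rep(NA_real_, n)
  nogo_ok <- is_nogo & category == "correct"
  hold[nogo_ok] <- rtrunc_norm(sum(nogo_ok), profile$hold_mu, profile$hold_sigma,
                               lo = 600, hi = 1450)

  # Corrective-saccade gap after the erroneous saccade's offset: within the
  # 400 ms window for corrected errors; for uncorrected errors either no
  # corrective saccade at all or one clearly beyond the window.
  gap <- rep(NA_real_, n)
  corr <- category == "corrected_inhibition"
  gap[corr] <- stats::runif(sum(corr), 60, 300)
  unc <- category == "uncorrected_inhibition"
  late <- unc & stats::runif(n) < 0.5
  gap[late] <- stats::runif(sum(late), 450, 650)

  dplyr::mutate(schedule,
    truth = category,
    latent_latency = latency,
    latent_hold = hold,
    latent_gap = gap
  )
}

# Raised-cosine ("smoothstep") saccade profile; duration follows the main
# sequence duration_ms = 21 + 2.2 * amplitude_deg.
saccade_duration <- function(amplitude) 21 + 2.2 * abs(amplitude)

apply_saccade <- function(x, t, start, from, to) {
  d <- saccade_duration(to - from)
  u <- (t - start) / d
  moving <- u > 0 & u < 1
  x[moving] <- from + (to - from) * (0.5 - 0.5 * cos(pi * u[moving]))
  x[u >= 1] <- to
  x
}

# Render one trial's gaze trace from its latent outcome.
render_trial_trace <- function(profile, trial, rate = 300) {
  onset <- trial$target_onset
  duration <- trial$trial_duration
  if (onset >= duration) {
    stop("`target_onset` must be smaller than `trial_duration`.", call. = FALSE)
  }
  dt <- 1000 / rate
  t <- seq(0, duration, by = dt)
  x <- numeric(length(t))
  target_x <- if (trial$side == "right") 10 else -10
  noise_sd <- profile$fixation_noise_sd
  land <- function(goal) goal + stats::rnorm(1, 0, noise_sd)

  cat <- trial$truth
  if (cat == "correct" && trial$condition %in% c("PS", "Go")) {
    x <- apply_saccade(x, t, onset + trial$latent_latency, 0, land(target_x))
  } else if (cat == "correct" && trial$condition == "AS") {
    x <- apply_saccade(x, t, onset + trial$latent_latency, 0, land(-target_x))
  } else if (cat == "correct" && trial$condition == "NoGo") {
    away <- land(sample(c(-10, 10), 1L))
    x <- apply_saccade(x, t, onset + trial$latent_hold, 0, away)
  } else if (cat == "anticipation") {
    goal <- land(sample(c(-10, 10), 1L))
    x <- apply_saccade(x, t, onset + trial$latent_latency, 0, goal)
  } else if (cat %in% c("corrected_inhibition", "uncorrected_inhibition")) {
    wrong_x <- switch(trial$condition,
      AS = target_x, NoGo = target_x,
      PS = -target_x, Go = -target_x
    )
    right_x <- switch(trial$condition,
      AS = -target_x, NoGo = 0,
      PS = target_x, Go = target_x
    )
    err_start <- onset + trial$latent_latency
    err_goal <- land(wrong_x)
    x <- apply_saccade(x, t, err_start, 0, err_goal)
    if (!is.na(trial$latent_gap)) {
      corr_start <- err_start + saccade_duration(err_goal) + trial$latent_gap
      x <- apply_saccade(x, t, corr_start, err_goal, land(right_x))
    }
  } # omission: gaze stays at the centre

  x <- x + stats::rnorm(length(t), 0, noise_sd)
  y <- stats::rnorm(length(t), 0, noise_sd)
  meta <- trial
  tibble::tibble(
    block = meta$block, trial = meta$trial,
    condition = meta$condition, side = meta$side,
    t_ms = t,
    x_deg = pmin(pmax(x, -15), 15),
    y_deg = pmin(pmax(y, -15), 15),
    valid = TRUE,
    truth = cat
  )
}

#' Simulate one trial's gaze trace
#'
#' Samples a latent trial outcome from the subject's error probabilities
#' (anticipation, omission, inhibition error with or without correction,
#' else correct) and renders a 300 Hz gaze trace realizing it: Gaussian
#' fixation noise, saccades as raised-cosine displacements with
#' main-sequence duration (21 + 2.2 ms/deg), latency from a shifted
#' lognormal with the subject's moments. Anticipations launch between
#' 150 ms before and 70 ms after target onset; omissions show no saccade;
#' corrective saccades after an inhibition error start within (corrected)
#' or beyond (uncorrected) the 400 ms correction window.
#'
#' @param profile One row of a [simulate_cohort()] tibble (or any list with
#'   the same fields).
#' @param spec One row of a [build_session_schedule()] tibble.
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz (default 300).
#' @return A tibble of gaze samples with columns `block`, `trial`,
#'   `condition`, `side`, `t_ms`, `x_deg`, `y_deg`, `valid`, `truth`.
#' @export
simulate_trial_trace <- function(profile, spec, seed = 1L, rate = 300) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  latent <- sample_trial_latents(profile, tibble::as_tibble(spec))
  render_trial_trace(profile, latent[1, ], rate = rate)
}

#' Simulate a full session of gaze traces for one subject
#'
#' Builds the session schedule, samples a latent outcome per trial, and
#' renders all 90 traces.
#'
#' @inheritParams simulate_trial_trace
#' @param session `"PA"` or `"GN"`.
#' @return A tibble of gaze samples for all trials, with a `session` column.
#' @export
simulate_session_traces <- function(profile, session = c("PA", "GN"),
                                    seed = 1L, rate = 300) {
  session <- match.arg(session)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  schedule <- build_session_schedule(session, seed = derive_seed(seed, 1L))
  set.seed(derive_seed(seed, 2L))
  latents <- sample_trial_latents(profile, schedule)
  traces <- purrr::map(seq_len(nrow(latents)),
                       function(i) render_trial_trace(profile, latents[i, ], rate = rate))
  out <- dplyr::bind_rows(traces)
  dplyr::mutate(out, session = session, .before = 1L)
}

#' Simulate raw gaze traces for a whole cohort
#'
#' Each subject receives one prosaccade/antisaccade (PA) and one Go/No-go
#' (GN) session of 90 trials each, with ground-truth labels retained.
#' Per-subject sub-seeds are derived deterministically from the master
#' seed. At 300 Hz one subject contributes roughly 135,000 gaze samples;
#' for feature-level work at cohort scale use
#' [simulate_cohort_outcomes()], which skips trace rendering.
#'
#' @param profiles Tibble from [simulate_cohort()]; must be non-empty.
#' @param seed Master integer seed.
#' @param rate Sampling rate in Hz.
#' @return A tibble of gaze samples with `subject_id` and `session` columns.
#' @export
simulate_cohort_sessions <- function(profiles, seed = 1L, rate = 300) {
  if (nrow(profiles) == 0L) stop("`profiles` must be non-empty.", call. = FALSE)
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    sub_seed <- derive_seed(seed, i)
    dplyr::bind_rows(
      simulate_session_traces(p, "PA", seed = derive_seed(sub_seed, 11L), rate = rate),
      simulate_session_traces(p, "GN", seed = derive_seed(sub_seed, 12L), rate = rate)
    ) |>
      dplyr::mutate(subject_id = p$subject_id, .before = 1L)
  })
}

#' Simulate ground-truth trial outcomes for a whole cohort
#'
#' Fast path for cohort-scale studies: samples each trial's latent outcome,
#' latency and No-go fixation hold directly, without rendering or scoring
#' gaze traces. The latent sampler is the same one that drives
#' [simulate_cohort_sessions()], and the velocity-threshold scoring of
#' rendered traces recovers these labels (exactly on noise-free traces; see
#' the package vignette), so the two routes are interchangeable for
#' feature-level analyses.
#'
#' @inheritParams simulate_cohort_sessions
#' @return An outcomes tibble with columns `subject_id`, `session`,
#'   `block`, `trial`, `condition`, `side`, `category`, `latency_ms`,
#'   `fixation_duration_ms`.
#' @export
simulate_cohort_outcomes <- function(profiles, seed = 1L) {
  if (nrow(profiles) == 0L) stop("`profiles` must be non-empty.", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    sub_seed <- derive_seed(seed, i)
    purrr::map_dfr(c(PA = "PA", GN = "GN"), function(sess) {
      sess_seed <- derive_seed(sub_seed, if (sess == "PA") 11L else 12L)
      schedule <- build_session_schedule(sess, seed = derive_seed(sess_seed, 1L))
      set.seed(derive_seed(sess_seed, 2L))
      latents <- sample_trial_latents(p, schedule)
      tibble::tibble(
        subject_id = p$subject_id,
        session = sess,
        block = latents$block,
        trial = latents$trial,
        condition = latents$condition,
        side = latents$side,
        category = latents$truth,
        latency_ms = ifelse(latents$truth %in% c("omission") |
                              (latents$condition == "NoGo" & latents$truth == "correct"),
                            NA_real_, latents$latent_latency),
        fixation_duration_ms = latents$latent_hold
      )
    })
  })
}
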