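# Shared fixture builders: tiny profiles, trial specs, and hand-rendered
# traces with known kinematics.

test_profile <- function(group = "CN",
                         latency_mu = 240, latency_sigma = 45,
                         p_anticipation = 0, p_omission = 0,
                         p_inhibition = 0, p_correction = 0.5,
                         fixation_noise_sd = 0,
                         hold_mu = 1100, hold_sigma = 100,
                         subject_id = "T001",
                         age = 70, sex = "female", education = 12, mmse = 28) {
  tibble::tibble(
    subject_id = subject_id, group = group, age = age, sex = sex,
    education = education, mmse = mmse,
    latency_mu = latency_mu, latency_sigma = latency_sigma,
    p_anticipation = p_anticipation, p_omission = p_omission,
    p_inhibition = p_inhibition, p_correction = p_correction,
    hold_mu = hold_mu, hold_sigma = hold_sigma,
    fixation_noise_sd = fixation_noise_sd
  )
}

test_trial <- function(condition = "PS", side = "right",
                       target_onset = 1000, trial_duration = 2500,
                       block = 1L, trial = 1L) {
  tibble::tibble(block = block, trial = trial, condition = condition,
                 side = side, target_onset = target_onset,
                 trial_duration = trial_duration)
}

# Constant-position trace with optional Gaussian noise.
flat_trace <- function(duration = 2500, rate = 300, x = 0, y = 0,
                       noise_sd = 0, condition = "PS", side = "right") {
  t <- seq(0, duration, by = 1000 / rate)
  tibble::tibble(
    block = 1L, trial = 1L, condition = condition, side = side,
    t_ms = t,
    x_deg = x + stats::rnorm(length(t), 0, noise_sd),
    y_deg = y + stats::rnorm(length(t), 0, noise_sd),
    valid = TRUE
  )
}

# Trace with main-sequence saccades at specified times/targets, using the
# same raised-cosine kinematics as the simulator.
saccade_trace <- function(saccades, duration = 2500, rate = 300,
                          condition = "PS", side = "right", noise_sd = 0) {
  tr <- flat_trace(duration, rate, condition = condition, side = side,
                   noise_sd = noise_sd)
  x <- tr$x_deg
  pos <- 0
  for (i in seq_len(nrow(saccades))) {
    x <- gazescreen:::apply_saccade(x, tr$t_ms, saccades$start[i], pos,
                                    saccades$to[i])
    pos <- saccades$to[i]
  }
  tr$x_deg <- x
  tr
}

# Ground-truth labels of a simulated trace set, one row per trial.
truth_of <- function(traces) {
  dplyr::distinct(traces, dplyr::across(dplyr::any_of(
    c("subject_id", "session", "block", "trial", "truth"))))
}

# Minimal feature table for modelling tests: n subjects, configurable
# group-dependent signal in one EM column and in MMSE.
toy_feature_table <- function(n_cn = 60, n_mci = 30, em_shift = 0,
                              mmse_shift = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_cn + n_mci
    grp <- c(rep("CN", n_cn), rep("MCI", n_mci))
    tb <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = grp,
      age = stats::rnorm(n, 72, 6),
      sex = sample(c("male", "female"), n, replace = TRUE),
      education = stats::rnorm(n, 13, 4),
      mmse = round(stats::rnorm(n, 27, 2) - mmse_shift * (grp == "MCI")),
      ps_latency_sd = stats::rnorm(n, 45, 10) + em_shift * (grp == "MCI"),
      as_all_errors_pct = stats::rnorm(n, 20, 8) + em_shift * (grp == "MCI")
    )
    build_feature_table(tb)
  })
}
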