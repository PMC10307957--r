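#' Build a session schedule
#'
#' One session is 30 blocks of 3 trials. In the prosaccade/antisaccade
#' session (`"PA"`) each block holds two prosaccade (PS) and one antisaccade
#' (AS) trial; in the Go/No-go session (`"GN"`) two Go and one No-go trial.
#' The position of the deviant trial within each block and the target side
#' are randomly interleaved, with left/right balanced in expectation.
#'
#' The default trial timeline is 1000 ms of central fixation, target onset
#' at t = 1000 ms, and 1500 ms of post-onset recording (2500 ms total),
#' which accommodates the 500 ms omission window and the 400 ms correction
#' window with margin.
#'
#' @param session `"PA"` or `"GN"`.
#' @param seed Integer seed; schedules are deterministic given the seed.
#' @param n_blocks Number of blocks (default 30).
#' @param target_onset,trial_duration Trial timeline in ms.
#' @return A tibble with one row per trial: `block`, `trial` (1--3 within
#'   block), `condition` (PS/AS/Go/NoGo), `side` (left/right),
#'   `target_onset`, `trial_duration`.
#' @examples
#' build_session_schedule("PA", seed = 1)
#' @export
build_session_schedule <- function(session = c("PA", "GN"), seed = 1L,
                                   n_blocks = 30L,
                                   target_onset = 1000, trial_duration = 2500) {
  session <- match.arg(session)
  if (target_onset >= trial_duration) {
    stop("`target_onset` must be smaller than `trial_duration`.", call. = FALSE)
  }
  standard <- if (session == "PA") "PS" else "Go"
  deviant <- if (session == "PA") "AS" else "NoGo"
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # the two standard trials are interchangeable, so a block's order is fully
  # determined by the deviant trial's position
  deviant_pos <- sample.int(3L, n_blocks, replace = TRUE)
  condition <- matrix(standard, nrow = n_blocks, ncol = 3L)
  condition[cbind(seq_len(n_blocks), deviant_pos)] <- deviant
  tibble::tibble(
    block = rep(seq_len(n_blocks), each = 3L),
    trial = rep(1:3, n_blocks),
    condition = as.vector(t(condition)),
    side = sample(c("left", "right"), 3L * n_blocks, replace = TRUE),
    target_onset = target_onset,
    trial_duration = trial_duration
  )
}
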