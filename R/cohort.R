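#' Reference cohort counts and moments
#'
#' Published accounting and demographic moments of the motivating clinical
#' cohort: 679 older adults enrolled, 85 excluded (25 with dementia, 60 with
#' visual impairment or calibration/practice failure), leaving 594 analysed
#' subjects — 428 cognitively normal (CN) controls and 166 with mild
#' cognitive impairment (MCI). The `moments` element holds the group-wise
#' mean (SD) of age, education years and MMSE, and the female counts, used
#' as the default sampling moments of [cohort_spec()].
#'
#' @format A named list with elements `enrolled`, `excluded_dementia`,
#'   `excluded_visual`, `n_cn`, `n_mci`, `female_all`, `female_mci`,
#'   `female_cn`, and `moments` (a tibble with one row per group).
#' @export
reference_cohort <- list(
  enrolled          = 679L,
  excluded_dementia = 25L,
  excluded_visual   = 60L,
  n_cn              = 428L,
  n_mci             = 166L,
  female_all        = 321L,
  female_mci        = 83L,
  female_cn         = 238L,
  moments = tibble::tribble(
    ~group, ~age_mean, ~age_sd, ~edu_mean, ~edu_sd, ~mmse_mean, ~mmse_sd, ~p_female,
    "CN",       71.17,    6.22,      13.1,     4.4,      27.77,     1.75, 238 / 428,
    "MCI",      73.45,    6.63,      12.9,     4.5,      26.16,     2.64,  83 / 166
  )
)

#' Default oculomotor parameter block for one group
#'
#' Group-level distributions from which subject profiles are drawn.
#' Demographic and MMSE moments come from [reference_cohort]; the
#' oculomotor parameters (latency moments, error probabilities, fixation
#' hold time, gaze noise) are generator defaults calibrated so that, at a
#' cohort of roughly 600 subjects, standardized adjusted odds ratios of the
#' affected eye-movement metrics fall in the 1.2--1.6 range typical of
#' MCI-vs-CN contrasts. Probabilities are per deviant-relevant trial;
#' subject-level probabilities scatter around the group mean on the logit
#' scale with SD `p_logit_sd`.
#'
#' @param group `"CN"` or `"MCI"`.
#' @return Named list of distribution parameters.
#' @export
group_defaults <- function(group = c("CN", "MCI")) {
  group <- match.arg(group)
  m <- reference_cohort$moments[reference_cohort$moments$group == group, ]
  base <- list(
    age_mean = m$age_mean, age_sd = m$age_sd,
    edu_mean = m$edu_mean, edu_sd = m$edu_sd,
    mmse_mean = m$mmse_mean, mmse_sd = m$mmse_sd,
    p_female = m$p_female,
    p_logit_sd = 0.45
  )
  ocul <- if (group == "CN") {
    list(
      latency_mu_mean = 240, latency_mu_sd = 25,
      latency_sigma_mean = 46, latency_sigma_sd = 12,
      p_anticipation = 0.042, p_omission = 0.032,
      p_inhibition = 0.22, p_correction = 0.52,
      hold_mu = 1120, hold_sigma = 155,
      fixation_noise_sd = 0.15
    )
  } else {
    list(
      latency_mu_mean = 250, latency_mu_sd = 28,
      latency_sigma_mean = 51, latency_sigma_sd = 14,
      p_anticipation = 0.052, p_omission = 0.040,
      p_inhibition = 0.26, p_correction = 0.46,
      hold_mu = 1090, hold_sigma = 175,
      fixation_noise_sd = 0.22
    )
  }
  c(base, ocul)
}

#' Cohort specification
#'
#' Bundles group sizes, per-group parameter blocks and bookkeeping needed by
#' [simulate_cohort()]. Defaults reproduce the reference cohort's 428/166
#' CN/MCI composition and Table-style demographic moments.
#'
#' @param n_cn,n_mci Number of cognitively normal / MCI subjects (>= 0).
#' @param cn,mci Parameter blocks as returned by [group_defaults()]; pass a
#'   modified copy to change the generative conditions.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cn = reference_cohort$n_cn,
                        n_mci = reference_cohort$n_mci,
                        cn = group_defaults("CN"),
                        mci = group_defaults("MCI")) {
  if (length(n_cn) != 1L || length(n_mci) != 1L ||
      is.na(n_cn) || is.na(n_mci) || n_cn < 0 || n_mci < 0) {
    stop("`n_cn` and `n_mci` must be single non-negative counts.", call. = FALSE)
  }
  for (blk in list(cn, mci)) {
    sds <- unlist(blk[grepl("_sd$|sigma", names(blk))])
    if (any(sds < 0)) stop("All SD parameters must be >= 0.", call. = FALSE)
  }
  structure(
    list(n_cn = as.integer(n_cn), n_mci = as.integer(n_mci), cn = cn, mci = mci),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_cn, " CN + ", x$n_mci, " MCI subjects\n", sep = "")
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

sample_group_profiles <- function(n, group, blk) {
  if (n == 0L) return(NULL)
  p_jitter <- function(p) {
    stats::plogis(stats::qlogis(p) + stats::rnorm(n, 0, blk$p_logit_sd))
  }
  tibble::tibble(
    group = group,
    age = round(rtrunc_norm(n, blk$age_mean, blk$age_sd, lo = 45, hi = 95), 1),
    sex = ifelse(stats::runif(n) < blk$p_female, "female", "male"),
    education = round(rtrunc_norm(n, blk$edu_mean, blk$edu_sd, lo = 3, hi = 22)),
    mmse = pmin(30L, as.integer(round(rtrunc_norm(n, blk$mmse_mean, blk$mmse_sd,
                                                  lo = 0, hi = 30.49)))),
    latency_mu = rtrunc_norm(n, blk$latency_mu_mean, blk$latency_mu_sd, lo = 150, hi = 400),
    latency_sigma = rtrunc_norm(n, blk$latency_sigma_mean, blk$latency_sigma_sd, lo = 10, hi = 120),
    p_anticipation = p_jitter(blk$p_anticipation),
    p_omission = p_jitter(blk$p_omission),
    p_inhibition = p_jitter(blk$p_inhibition),
    p_correction = p_jitter(blk$p_correction),
    hold_mu = rtrunc_norm(n, blk$hold_mu, 60, lo = 700, hi = 1400),
    hold_sigma = rtrunc_norm(n, blk$hold_sigma, 30, lo = 40, hi = 350),
    fixation_noise_sd = rtrunc_norm(n, blk$fixation_noise_sd, 0.03, lo = 0.05, hi = 0.5)
  )
}

#' Simulate a cohort of subject profiles
#'
#' Draws `n_cn + n_mci` subject profiles from the group distributions in a
#' [cohort_spec()]. Demographics and MMSE are sampled from truncated normals
#' at the configured moments (MMSE rounded to an integer in 0--30); the
#' MCI defaults carry longer and more variable saccade latencies, higher
#' error probabilities, a lower correction probability and noisier fixation
#' than the CN defaults.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A tibble with one row per subject: identifiers, group,
#'   demographics, MMSE, and the latent oculomotor parameters
#'   (`latency_mu`, `latency_sigma`, error probabilities, `hold_mu`,
#'   `hold_sigma`, `fixation_noise_sd`).
#' @examples
#' simulate_cohort(cohort_spec(n_cn = 4, n_mci = 2), seed = 1)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cn + spec$n_mci
  if (n == 0L) {
    return(tibble::tibble(subject_id = character(), group = character()))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- dplyr::bind_rows(
    sample_group_profiles(spec$n_cn, "CN", spec$cn),
    sample_group_profiles(spec$n_mci, "MCI", spec$mci)
  )
  out <- dplyr::mutate(out,
    subject_id = sprintf("S%04d", dplyr::row_number()),
    .before = 1L
  )
  out
}

# Save/restore the global RNG state so that seeded helpers do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Deterministic per-subject sub-seed derived from a master seed; kept within
# 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 2654435761 + as.numeric(index) * 40503) %% 2147483647)
}
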