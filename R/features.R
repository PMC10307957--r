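# The 30 per-subject eye-movement variables, by condition prefix.
em_feature_names <- function() {
  c(
    paste0("ps_", c("correct_pct", "latency_mean", "latency_sd", "all_errors_pct",
                    "uncorrected_pct", "self_corrected_pct", "anticipations_pct",
                    "omissions_pct")),
    paste0("as_", c("correct_pct", "latency_mean", "latency_sd", "all_errors_pct",
                    "uncorrected_pct", "corrected_pct", "anticipations_pct",
                    "omissions_pct")),
    paste0("go_", c("correct_pct", "latency_mean", "latency_sd", "all_errors_pct",
                    "uncorrected_pct", "self_corrected_pct", "anticipations_pct",
                    "omissions_pct")),
    paste0("nogo_", c("correct_pct", "fixation_duration_mean", "fixation_duration_sd",
                      "all_errors_pct", "uncorrected_pct", "corrected_pct"))
  )
}

condition_prefix <- c(PS = "ps", AS = "as", Go = "go", NoGo = "nogo")

aggregate_condition <- function(oc, condition) {
  prefix <- condition_prefix[[condition]]
  n <- nrow(oc)
  pct <- function(x) 100 * sum(x) / n
  corrected_name <- if (condition %in% c("PS", "Go")) "self_corrected_pct" else "corrected_pct"
  out <- list()
  out[[paste0(prefix, "_correct_pct")]] <- pct(oc$category == "correct")
  out[[paste0(prefix, "_all_errors_pct")]] <- pct(oc$category != "correct")
  out[[paste0(prefix, "_uncorrected_pct")]] <- pct(oc$category == "uncorrected_inhibition")
  out[[paste0(prefix, "_", corrected_name)]] <- pct(oc$category == "corrected_inhibition")
  if (condition != "NoGo") {
    out[[paste0(prefix, "_anticipations_pct")]] <- pct(oc$category == "anticipation")
    out[[paste0(prefix, "_omissions_pct")]] <- pct(oc$category == "omission")
    lat <- oc$latency_ms[oc$category == "correct" & !is.na(oc$latency_ms)]
    out[[paste0(prefix, "_latency_mean")]] <- if (length(lat)) mean(lat) else NA_real_
    out[[paste0(prefix, "_latency_sd")]] <- if (length(lat) >= 2L) stats::sd(lat) else NA_real_
  } else {
    fd <- oc$fixation_duration_ms[oc$category == "correct" & !is.na(oc$fixation_duration_ms)]
    out[[paste0(prefix, "_fixation_duration_mean")]] <- if (length(fd)) mean(fd) else NA_real_
    out[[paste0(prefix, "_fixation_duration_sd")]] <- if (length(fd) >= 2L) stats::sd(fd) else NA_real_
  }
  tibble::as_tibble(out)
}

#' Aggregate one subject's trial outcomes into eye-movement metrics
#'
#' Computes, per condition, the percentage of correct trials,
#' anticipations, omissions and corrected/uncorrected inhibition errors
#' (percentages of that condition's trials), the all-errors percentage
#' (anticipations + omissions + inhibition errors for PS/AS/Go; inhibition
#' errors alone for No-go), latency mean and SD over correct trials
#' (PS/AS/Go), and fixation-duration mean and SD over correct No-go
#' trials. SDs are sample SDs (n - 1) and are absent when fewer than two
#' trials contribute.
#'
#' @param outcomes Outcomes tibble for one subject covering both sessions
#'   (from [score_session()] or [simulate_cohort_outcomes()]).
#' @param subject Optional one-row subject tibble whose identifier,
#'   group, demographics and MMSE are carried along.
#' @return A one-row tibble of the 30 eye-movement variables (plus
#'   subject columns when `subject` is given).
#' @export
aggregate_subject <- function(outcomes, subject = NULL) {
  if (nrow(outcomes) == 0L) stop("`outcomes` must be non-empty.", call. = FALSE)
  bad <- setdiff(unique(outcomes$condition), names(condition_prefix))
  if (length(bad)) stop("Unknown condition: ", paste(bad, collapse = ", "), call. = FALSE)
  parts <- purrr::map(
    intersect(names(condition_prefix), unique(outcomes$condition)),
    function(cc) aggregate_condition(outcomes[outcomes$condition == cc, ], cc)
  )
  em <- dplyr::bind_cols(parts)
  missing <- setdiff(em_feature_names(), names(em))
  for (m in missing) em[[m]] <- NA_real_
  em <- em[, em_feature_names()]
  if (!is.null(subject)) {
    keep <- intersect(c("subject_id", "group", "age", "sex", "education", "mmse"),
                      names(subject))
    em <- dplyr::bind_cols(tibble::as_tibble(subject)[, keep], em)
  }
  em
}

#' Aggregate a cohort's outcomes into a subject-level feature tibble
#'
#' Vectorized equivalent of mapping [aggregate_subject()] over subjects.
#'
#' @param outcomes Outcomes tibble with a `subject_id` column.
#' @param subjects Subject tibble from [simulate_cohort()] (or any table
#'   with `subject_id`, `group`, `age`, `sex`, `education`, `mmse`).
#' @return A tibble with one row per subject: identifier, group,
#'   demographics, MMSE and the 30 eye-movement variables.
#' @export
aggregate_cohort <- function(outcomes, subjects) {
  if (nrow(outcomes) == 0L) stop("`outcomes` must be non-empty.", call. = FALSE)
  bad <- setdiff(unique(outcomes$condition), names(condition_prefix))
  if (length(bad)) stop("Unknown condition: ", paste(bad, collapse = ", "), call. = FALSE)
  sd_or_na <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  long <- outcomes |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(
      correct_pct = 100 * mean(.data$category == "correct"),
      all_errors_pct = 100 * mean(.data$category != "correct"),
      uncorrected_pct = 100 * mean(.data$category == "uncorrected_inhibition"),
      corrected_pct = 100 * mean(.data$category == "corrected_inhibition"),
      anticipations_pct = 100 * mean(.data$category == "anticipation"),
      omissions_pct = 100 * mean(.data$category == "omission"),
      latency_mean = mean_or_na(.data$latency_ms[.data$category == "correct" &
                                                   !is.na(.data$latency_ms)]),
      latency_sd = sd_or_na(.data$latency_ms[.data$category == "correct" &
                                               !is.na(.data$latency_ms)]),
      fixation_duration_mean = mean_or_na(
        .data$fixation_duration_ms[.data$category == "correct" &
                                     !is.na(.data$fixation_duration_ms)]),
      fixation_duration_sd = sd_or_na(
        .data$fixation_duration_ms[.data$category == "correct" &
                                     !is.na(.data$fixation_duration_ms)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(prefix = condition_prefix[.data$condition]) |>
    dplyr::select(-"condition") |>
    tidyr::pivot_wider(names_from = "prefix",
                       values_from = -c("subject_id", "prefix"),
                       names_glue = "{prefix}_{.value}")
  nm <- names(long)
  nm[nm == "ps_corrected_pct"] <- "ps_self_corrected_pct"
  nm[nm == "go_corrected_pct"] <- "go_self_corrected_pct"
  names(long) <- nm
  keep <- intersect(em_feature_names(), names(long))
  wide <- long[, c("subject_id", keep)]
  for (m in setdiff(em_feature_names(), keep)) wide[[m]] <- NA_real_
  wide <- wide[, c("subject_id", em_feature_names())]
  wide |>
    dplyr::left_join(
      subjects[, intersect(c("subject_id", "group", "age", "sex", "education", "mmse"),
                           names(subjects))],
      by = "subject_id"
    ) |>
    dplyr::relocate(dplyr::any_of(c("subject_id", "group", "age", "sex",
                                    "education", "mmse")))
}

#' Build the modelling feature table
#'
#' Encodes sex as a binary `sex_male` column, verifies both groups are
#' present, and removes features that are constant across all, or all but
#' one, of the samples (near-constant columns carry no information and can
#' break downstream standardization). Column roles — demographic
#' (`age`, `sex_male`, `education`), `mmse`, and the eye-movement (`em`)
#' block — are recorded in the `"roles"` attribute and drive the six
#' feature sets of the classification benchmark.
#'
#' @param features Tibble from [aggregate_cohort()] (or one row per
#'   subject with the same columns).
#' @return A tibble of class `feature_table` with attribute `roles`.
#' @export
build_feature_table <- function(features) {
  if (nrow(features) < 2L) stop("Need at least two subjects.", call. = FALSE)
  if (dplyr::n_distinct(features$group) < 2L) {
    stop("Both groups (CN and MCI) must be present.", call. = FALSE)
  }
  out <- features
  if ("sex" %in% names(out)) {
    out$sex_male <- as.integer(out$sex == "male")
    out$sex <- NULL
    out <- dplyr::relocate(out, "sex_male", .after = "age")
  }
  feature_cols <- setdiff(names(out), c("subject_id", "group"))
  near_constant <- feature_cols[purrr::map_lgl(feature_cols, function(col) {
    v <- out[[col]]
    tab <- table(v[!is.na(v)])
    length(tab) == 0L || max(tab) >= (nrow(out) - 1L)
  })]
  if (length(near_constant)) {
    message("Dropping near-constant feature(s): ", paste(near_constant, collapse = ", "))
    out <- out[, setdiff(names(out), near_constant)]
  }
  roles <- c(
    stats::setNames(rep("demographic", 3), c("age", "sex_male", "education")),
    mmse = "mmse",
    stats::setNames(rep("em", length(em_feature_names())), em_feature_names())
  )
  roles <- roles[names(roles) %in% names(out)]
  attr(out, "roles") <- roles
  class(out) <- c("feature_table", class(out))
  out
}

feature_roles <- function(table) {
  roles <- attr(table, "roles")
  if (is.null(roles)) stop("Not a feature table; run `build_feature_table()` first.",
                           call. = FALSE)
  roles
}

#' Resolve a named feature set to its columns
#'
#' The six benchmark feature sets are `Demo` (age, sex, education),
#' `MMSE`, `Demo+MMSE`, `EM` (the eye-movement block), `Demo+EM` and
#' `Demo+MMSE+EM`.
#'
#' @param table A [build_feature_table()] tibble.
#' @param name Feature-set name.
#' @return Character vector of column names.
#' @export
feature_set_columns <- function(table, name) {
  roles <- feature_roles(table)
  sets <- list(
    "Demo" = "demographic",
    "MMSE" = "mmse",
    "Demo+MMSE" = c("demographic", "mmse"),
    "EM" = "em",
    "Demo+EM" = c("demographic", "em"),
    "Demo+MMSE+EM" = c("demographic", "mmse", "em")
  )
  if (!name %in% names(sets)) {
    stop("Unknown feature set: ", name, call. = FALSE)
  }
  names(roles)[roles %in% sets[[name]]]
}

#' Names of the six benchmark feature sets
#' @return Character vector.
#' @export
feature_set_names <- function() {
  c("Demo", "MMSE", "Demo+MMSE", "EM", "Demo+EM", "Demo+MMSE+EM")
}

#' Centre and scale the continuous feature columns
#'
#' Z-scores every continuous feature column (binary columns such as
#' `sex_male` are untouched). When `reference_stats` is supplied (the
#' `"scale_stats"` attribute of a previously standardized table), those
#' means and SDs are applied instead — the train-statistics-to-test-set
#' contract of the modelling pipeline.
#'
#' @param table A [build_feature_table()] tibble.
#' @param reference_stats Optional tibble with columns `column`, `mean`,
#'   `sd`.
#' @return The standardized table, with attribute `scale_stats`.
#' @export
standardize <- function(table, reference_stats = NULL) {
  roles <- feature_roles(table)
  cont <- names(roles)[purrr::map_lgl(names(roles), function(col) {
    !all(table[[col]] %in% c(0, 1, NA))
  })]
  if (is.null(reference_stats)) {
    reference_stats <- tibble::tibble(
      column = cont,
      mean = purrr::map_dbl(cont, ~ mean(table[[.x]], na.rm = TRUE)),
      sd = purrr::map_dbl(cont, ~ stats::sd(table[[.x]], na.rm = TRUE))
    )
    zero <- reference_stats$column[reference_stats$sd == 0 |
                                     is.na(reference_stats$sd)]
    if (length(zero)) {
      stop("Zero-SD column(s): ", paste(zero, collapse = ", "), call. = FALSE)
    }
  }
  out <- table
  for (i in seq_len(nrow(reference_stats))) {
    col <- reference_stats$column[i]
    if (col %in% names(out)) {
      out[[col]] <- (out[[col]] - reference_stats$mean[i]) / reference_stats$sd[i]
    }
  }
  attr(out, "scale_stats") <- reference_stats
  attr(out, "roles") <- roles
  class(out) <- class(table)
  out
}
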