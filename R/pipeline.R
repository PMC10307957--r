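gaze_csv_columns <- c("subject_id", "session", "block", "trial", "condition",
                      "side", "t_ms", "x_deg", "y_deg", "valid")

#' Write gaze traces to CSV
#'
#' The gaze dialect is a long UTF-8 CSV with a header row and dot
#' decimals: `subject_id, session, block, trial, condition, side, t_ms,
#' x_deg, y_deg, valid` plus an optional `truth` column for simulated
#' data.
#'
#' @param traces Gaze tibble from [simulate_cohort_sessions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(traces, path) {
  cols <- c(gaze_csv_columns, intersect("truth", names(traces)))
  readr::write_csv(traces[, cols], path)
  invisible(path)
}

#' Read gaze traces from CSV
#'
#' Validates the documented gaze dialect: the required columns must be
#' present (extra columns are ignored with a warning), the `valid` column
#' is parsed leniently (0/1, true/false, TRUE/FALSE), and timestamps must
#' increase strictly within each trial — the first offending line is
#' reported.
#'
#' @param path CSV file written by [write_gaze_csv()] (or an equivalent
#'   export).
#' @return A gaze tibble.
#' @export
read_gaze_csv <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) stop("Empty gaze file: ", path, call. = FALSE)
  missing <- setdiff(gaze_csv_columns, names(raw))
  if (length(missing)) {
    stop("Missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), c(gaze_csv_columns, "truth"))
  if (length(extra)) {
    warning("Ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), extra)]
  }
  raw$valid <- parse_valid(raw$valid)
  raw$block <- as.integer(raw$block)
  raw$trial <- as.integer(raw$trial)
  check <- raw |>
    dplyr::mutate(.line = dplyr::row_number() + 1L) |>
    dplyr::group_by(.data$subject_id, .data$session, .data$block, .data$trial) |>
    dplyr::mutate(.bad = .data$t_ms <= dplyr::lag(.data$t_ms)) |>
    dplyr::ungroup()
  bad <- which(check$.bad)
  if (length(bad)) {
    stop("Non-monotone timestamps; first offending line: ",
         check$.line[bad[1]], call. = FALSE)
  }
  raw
}

parse_valid <- function(v) {
  if (is.logical(v)) return(v)
  out <- tolower(trimws(as.character(v))) %in% c("1", "true", "t", "yes")
  out
}

#' Write a scored-outcomes CSV
#' @param outcomes Outcomes tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  readr::write_csv(outcomes, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' One structured configuration drives the end-to-end run. Unknown keys in
#' any block are rejected before any stage executes.
#'
#' @param cohort A [cohort_spec()].
#' @param scoring A [scoring_params()].
#' @param cv A [cv_config()].
#' @param seed Master seed for all stages.
#' @param trace_level Render and score raw gaze traces (`TRUE`) or sample
#'   trial outcomes directly at cohort scale (`FALSE`); both routes share
#'   the same latent generator.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), scoring = scoring_params(),
                       cv = cv_config(), seed = 1L, trace_level = FALSE) {
  if (!inherits(cohort, "cohort_spec")) stop("`cohort` must be a cohort_spec.", call. = FALSE)
  if (!inherits(scoring, "scoring_params")) stop("`scoring` must be scoring_params.", call. = FALSE)
  if (!inherits(cv, "cv_config")) stop("`cv` must be a cv_config.", call. = FALSE)
  structure(
    list(cohort = cohort, scoring = scoring, cv = cv,
         seed = as.integer(seed), trace_level = isTRUE(trace_level)),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' Executes simulate, score, features, stats and classify in order,
#' writing each stage's CSV output plus a JSON manifest (configuration,
#' seeds, stage timings, package version) to `out_dir`. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of output paths, invisibly; the stage results are
#'   returned in the `results` attribute.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config object.", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    res
  }

  subjects <- clock("simulate_cohort", simulate_cohort(config$cohort, seed = config$seed))
  paths <- list(subjects = file.path(out_dir, "subjects.csv"))
  readr::write_csv(subjects, paths$subjects)

  if (config$trace_level) {
    traces <- clock("simulate_traces",
                    simulate_cohort_sessions(subjects, seed = derive_seed(config$seed, 2L)))
    paths$gaze <- file.path(out_dir, "gaze.csv")
    write_gaze_csv(traces, paths$gaze)
    outcomes <- clock("score", score_session(traces, config$scoring))
  } else {
    outcomes <- clock("simulate_outcomes",
                      simulate_cohort_outcomes(subjects, seed = derive_seed(config$seed, 2L)))
  }
  paths$outcomes <- file.path(out_dir, "outcomes.csv")
  write_outcomes_csv(outcomes, paths$outcomes)

  features <- clock("features", {
    aggregate_cohort(outcomes, subjects) |> build_feature_table()
  })
  paths$features <- file.path(out_dir, "features.csv")
  readr::write_csv(features, paths$features)

  stats_out <- clock("stats", list(
    table_one = table_one(features),
    odds_ratios = estimate_all_ors(features)
  ))
  paths$table_one <- file.path(out_dir, "table_one.csv")
  paths$odds_ratios <- file.path(out_dir, "odds_ratios.csv")
  readr::write_csv(stats_out$table_one, paths$table_one)
  readr::write_csv(stats_out$odds_ratios, paths$odds_ratios)

  benchmark <- clock("classify", run_all(features, config$cv))
  paths$benchmark <- file.path(out_dir, "benchmark.csv")
  readr::write_csv(tidy.em_benchmark(benchmark) |>
                     dplyr::select(-"best_params"), paths$benchmark)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gazescreen")),
    seed = config$seed,
    trace_level = config$trace_level,
    cohort = list(n_cn = config$cohort$n_cn, n_mci = config$cohort$n_mci,
                  cn = config$cohort$cn, mci = config$cohort$mci),
    scoring = unclass(config$scoring),
    cv = list(train_fraction = config$cv$train_fraction,
              n_folds = config$cv$n_folds, n_repeats = config$cv$n_repeats,
              smote_k = config$cv$smote_k, seed = config$cv$seed,
              algorithms = config$cv$algorithms,
              feature_sets = config$cv$feature_sets,
              grids = lapply(config$cv$grids, as.data.frame)),
    timings_sec = timings,
    outputs = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  attr(paths, "results") <- list(subjects = subjects, outcomes = outcomes,
                                 features = features, stats = stats_out,
                                 benchmark = benchmark)
  invisible(paths)
}
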