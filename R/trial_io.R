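TRIAL_LOG_COLUMNS <- c("participant_id", "condition", "block", "trial_index",
                       "stimulus_index", "response", "correct",
                       "feedback_text", "points_awarded")

#' Read a session/generator configuration file
#'
#' Accepts YAML or JSON (decided by extension) mirroring the
#' [session_config()] field names, with optional `agents`, `mood` and
#' `analysis` blocks. Unknown keys are rejected so that typos surface as
#' validation errors rather than silently falling back to defaults; all
#' type invariants are enforced on read.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `session` (a `gcbm_config`) plus any `agents`,
#'   `mood`, `analysis` blocks verbatim.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("validation error: config must be a mapping", call. = FALSE)
  session_keys <- c("condition", "n_levels", "reps_per_stimulus_baseline",
                    "baseline_trials", "training_blocks",
                    "training_frequency_map", "shift", "fixation_ms",
                    "stimulus_ms", "scoring", "rng_seed")
  block_keys <- c("agents", "mood", "analysis")
  unknown <- setdiff(names(raw), c(session_keys, block_keys))
  if (length(unknown)) {
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- raw[intersect(names(raw), session_keys)]
  if (!is.null(args$training_frequency_map)) {
    fm <- unlist(args$training_frequency_map)
    args$training_frequency_map <- stats::setNames(as.integer(fm), names(fm))
  }
  if (!is.null(args$scoring)) {
    args$scoring <- do.call(scoring_params, args$scoring)
  }
  session <- do.call(session_config, args)
  c(list(session = session), raw[intersect(names(raw), block_keys)])
}

#' Write a session configuration file
#'
#' @param config A [session_config()].
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @param extra Optional named list of additional blocks (`agents`,
#'   `mood`, `analysis`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, extra = list()) {
  validate_session_config(config)
  x <- unclass(config)
  x$training_frequency_map <- as.list(x$training_frequency_map)
  x$scoring <- unclass(x$scoring)
  x <- c(x, extra)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

validate_trial_log <- function(log) {
  missing_cols <- setdiff(TRIAL_LOG_COLUMNS, names(log))
  if (length(missing_cols)) {
    stop("validation error: trial log missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_block <- !log$block %in% BLOCKS
  if (any(bad_block)) {
    stop("validation error in row(s) ", paste(which(bad_block)[1:min(3, sum(bad_block))], collapse = ","),
         ": unknown block label", call. = FALSE)
  }
  training <- grepl("^training", log$block)
  offenders <- which(!training & (!is.na(log$feedback_text) | !is.na(log$points_awarded)))
  if (length(offenders)) {
    stop("validation error in row(s) ", paste(utils::head(offenders, 3), collapse = ","),
         ": feedback/points are only defined in training blocks", call. = FALSE)
  }
  bad_resp <- which(!log$response %in% c("happy", "sad"))
  if (length(bad_resp)) {
    stop("validation error in row(s) ", paste(utils::head(bad_resp, 3), collapse = ","),
         ": response must be happy or sad", call. = FALSE)
  }
  invisible(log)
}

#' Write / read trial logs
#'
#' Comma-separated UTF-8 with a header row and a stable column order
#' (`participant_id, condition, block, trial_index, stimulus_index,
#' response, correct, feedback_text, points_awarded`). Optional fields
#' (feedback outside training blocks, points outside gamified sessions)
#' are empty; booleans serialize as `true`/`false`. Round-trips are
#' lossless on valid data.
#'
#' @param log Data frame of trial records (see [run_session()]; the
#'   cohort generator prepends `participant_id` and `condition`).
#' @param path CSV path.
#' @return `write_trial_log`: `path` invisibly; `read_trial_log`: the
#'   validated data frame.
#' @export
write_trial_log <- function(log, path) {
  if (nrow(log)) validate_trial_log(log)
  out <- log[, TRIAL_LOG_COLUMNS, drop = FALSE]
  out$correct <- ifelse(is.na(out$correct), "",
                        ifelse(out$correct, "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character",
                                        condition = "character",
                                        block = "character",
                                        response = "character",
                                        feedback_text = "character",
                                        correct = "character"),
                         fileEncoding = "UTF-8")
  if (nrow(log) == 0L) {
    log$correct <- logical(0)
    log$points_awarded <- integer(0)
    return(validate_trial_log(log))
  }
  bad <- which(!log$correct %in% c("", "true", "false") & !is.na(log$correct))
  if (length(bad)) {
    stop("parse error in row(s) ", paste(utils::head(bad, 3), collapse = ","),
         ": correct must be true/false or empty", call. = FALSE)
  }
  log$correct <- ifelse(is.na(log$correct) | log$correct == "", NA,
                        log$correct == "true")
  log$feedback_text[!is.na(log$feedback_text) & log$feedback_text == ""] <- NA
  log$points_awarded <- as.integer(log$points_awarded)
  validate_trial_log(log)
  log
}

#' Write / read a cohort outcome table
#'
#' One row per participant with the outcome fields
#' (`participant_id, condition, age, gender, ims_pre, ims_post, bp_pre,
#' bp_post`), CSV, lossless round-trip.
#'
#' @param outcomes Cohort data frame (see [simulate_cohort()]).
#' @param path CSV path.
#' @export
write_cohort <- function(outcomes, path) {
  needed <- c("participant_id", "condition", "age", "gender",
              "ims_pre", "ims_post", "bp_pre", "bp_post")
  missing_cols <- setdiff(needed, names(outcomes))
  if (length(missing_cols)) {
    stop("validation error: cohort missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(outcomes[, needed, drop = FALSE], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                       colClasses = c(participant_id = "character",
                                      condition = "character",
                                      gender = "character"))
  bad <- setdiff(unique(x$condition), CONDITIONS)
  if (length(bad)) {
    stop("validation error: unknown condition label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "gcbm_report")) x <- unclass(x)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(report)
}

#' Write / read an analysis report
#'
#' Serializes the [run_full_analysis()] result (descriptives, ANOVA and
#' regression tables, outlier-filter audit) to machine-readable JSON.
#'
#' @param report A `gcbm_report`.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, root seed, artifact paths, schema
#' version, and a creation timestamp next to generated artifacts, so a
#' simulation run can be reproduced exactly.
#'
#' @param config A [session_config()].
#' @param root_seed Integer seed of the run.
#' @param artifacts Named character vector of artifact paths; each must
#'   exist at write time.
#' @param path JSON destination.
#' @export
write_manifest <- function(config, root_seed, artifacts, path) {
  missing_files <- artifacts[!file.exists(artifacts)]
  if (length(missing_files)) {
    stop("validation error: artifact(s) do not exist: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  cfg <- unclass(config)
  cfg$training_frequency_map <- as.list(cfg$training_frequency_map)
  cfg$scoring <- unclass(cfg$scoring)
  jsonlite::write_json(
    list(schema_version = "1.0",
         package_version = as.character(utils::packageVersion("gcbm")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         root_seed = root_seed,
         config = cfg,
         artifacts = as.list(artifacts)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
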