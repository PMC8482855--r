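trial_schema <- c("participant_id", "block_id", "trial_index",
                  "difficulty", "response_type", "order", "target_angle",
                  "hint_angle", "endpoint_angle", "estimate_angle",
                  "confidence", "failed", "failure_reason")
calibration_schema <- c("participant_id", "block_id", "trial_index",
                        "response_type", "target_angle", "endpoint_angle",
                        "estimate_angle")

trial_col_types <- function() {
  readr::cols(
    participant_id = "i", block_id = "i", trial_index = "i",
    difficulty = "c", response_type = "c", order = "c",
    target_angle = "d", hint_angle = "d", endpoint_angle = "d",
    estimate_angle = "d", confidence = "i", failed = "l",
    failure_reason = "c", .default = readr::col_guess()
  )
}

calibration_col_types <- function() {
  readr::cols(
    participant_id = "i", block_id = "i", trial_index = "i",
    response_type = "c", target_angle = "d", endpoint_angle = "d",
    estimate_angle = "d", .default = readr::col_guess()
  )
}

read_table_checked <- function(path, schema, col_types) {
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  missing <- setdiff(schema, names(tbl))
  if (length(missing) > 0) {
    stop("File ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    warning("Rejected ", length(unique(probs$row)),
            " malformed row(s) in ", path, " (first at line ",
            probs$row[1] + 1L, ").", call. = FALSE)
    tbl <- tbl[-unique(probs$row), ]
  }
  extra <- setdiff(names(tbl), schema)
  if (length(extra) > 0) {
    warning("File ", path, " has extra column(s), preserved: ",
            paste(extra, collapse = ", "), ".", call. = FALSE)
  }
  tbl
}

#' Read / write trial and calibration tables
#'
#' CSV round-trip for the trial-record and calibration schemas. Reading
#' validates that the schema columns are present (extra columns are kept
#' with a warning) and rejects rows with malformed angles, reporting line
#' numbers. Angles are written at full double precision, so a write/read
#' round trip is lossless well past six decimals.
#'
#' @param path File path.
#' @param trials,calibration Tables to write.
#' @return The table (readers), or the path invisibly (writers).
#' @export
read_trials <- function(path) {
  read_table_checked(path, trial_schema, trial_col_types())
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_trials
#' @export
read_calibration <- function(path) {
  read_table_checked(path, calibration_schema, calibration_col_types())
}

#' @rdname read_trials
#' @export
write_calibration <- function(calibration, path) {
  readr::write_csv(calibration, path, progress = FALSE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' The JSON object may carry `design` (fields of [design_spec()]),
#' `agent` (fields of [agent_params()]), `seed`, and an `analysis` block
#' (`trial_range`, `single_trial_range`, `split`, `folds`,
#' `do_stepwise`, `correct_motor`). Omitted fields fall back to package
#' defaults, so `{}` is a valid config.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `spec` ([design_spec()]), `agent`
#'   ([agent_params()]), `seed`, `analysis`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(design_spec, as.list(cfg$design %||% list()))
  agent <- do.call(agent_params, as.list(cfg$agent %||% list()))
  analysis <- utils::modifyList(
    list(trial_range = 4:10, single_trial_range = 2:10, split = "pooled",
         folds = 10, do_stepwise = FALSE, correct_motor = TRUE),
    as.list(cfg$analysis %||% list())
  )
  list(spec = spec, agent = agent,
       seed = cfg$seed %||% spec$seed, analysis = analysis)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run the full pipeline on a simulated cohort
#'
#' Chains simulation, preprocessing, learning metrics, model comparison
#' and the transfer analysis, optionally writing tidy CSV tables and a
#' JSON summary. Deterministic given the config and seed.
#'
#' @param config A configuration list from [read_config()], or `NULL` for
#'   defaults.
#' @param out_dir Optional output directory for CSVs and `summary.json`.
#' @param seed Integer seed (default from config).
#' @return A list with `trials`, `errors`, `calibration`, `exclusions`,
#'   `curves`, `half`, `mdi`, `motor`, `bounds`, `model_comparison`,
#'   `single_predictor_comparison`, `stepwise` (if enabled),
#'   `switch`, `confidence_switch`, `time_resolved`, and `summary`
#'   (the JSON-ready list).
#' @export
run_all <- function(config = NULL, out_dir = NULL, seed = NULL) {
  if (is.null(config)) {
    config <- list(spec = design_spec(), agent = agent_params(),
                   seed = 1L,
                   analysis = list(trial_range = 4:10,
                                   single_trial_range = 2:10,
                                   split = "pooled", folds = 10,
                                   do_stepwise = FALSE,
                                   correct_motor = TRUE))
  }
  seed <- as.integer(seed %||% config$seed)
  spec <- config$spec
  an <- config$analysis

  message("simulate: ", spec$n_participants, " participants x ",
          spec$n_blocks, " blocks (seed ", seed, ")")
  cohort <- simulate_cohort(spec, config$agent, seed = seed)
  errors <- preprocess(cohort$trials)
  excl <- exclusion_summary(errors)
  message("preprocess: ", nrow(errors), " trials, ",
          sum(errors$failed), " flagged")

  curves <- learning_curve(errors,
                           group_by = c("difficulty", "response_type"))
  half <- half_comparison(errors)
  mdi <- modality_difference_index(errors)
  motor <- estimate_motor_error(cohort$calibration)
  bounds <- dplyr::bind_rows(lapply(c("easy", "hard"), function(dd) {
    gm <- mean(motor$gamma_motor)
    dplyr::mutate(lower_bound(gm, kappa_for(spec, dd),
                              t_max = spec$switch_trial),
                  difficulty = dd)
  }))
  curve10 <- learning_curve(errors)
  bound_gap <- mean(curve10$mean[curve10$trial_index <=
                                   spec$switch_trial]) -
    mean(tapply(bounds$gamma, bounds$trial_index, mean))

  preds <- build_predictors(errors)
  comp <- compare_models(preds, trial_range = an$trial_range,
                         split = an$split)
  single <- compare_models(preds, models = model_specs()[1:5, ],
                           trial_range = an$single_trial_range,
                           split = an$split)
  message("compare: best mean-weight model = ",
          comp$group$name[which.max(comp$group$mean_weight)])

  stepwise <- NULL
  if (isTRUE(an$do_stepwise)) {
    stepwise <- stepwise_forward_cv(errors,
                                    target_trial = spec$switch_trial,
                                    folds = an$folds, seed = seed)
  }

  motor_used <- if (isTRUE(an$correct_motor)) motor else NULL
  sw <- switch_contrast(errors, motor = motor_used)
  csw <- confidence_switch(errors)
  trw <- time_resolved_weights(errors)

  t10 <- sw$tests[sw$tests$pair == "trial11_vs_trial10", ]
  t1 <- sw$tests[sw$tests$pair == "trial11_vs_trial1", ]
  transfer_flag <- if (mean(abs(t1$mean_diff)) < mean(abs(t10$mean_diff)))
    "no" else "yes"

  summary <- list(
    seed = seed,
    n_participants = spec$n_participants,
    exclusions = excl,
    group_weights = comp$group,
    single_predictor_weights = single$group,
    bound_gap_deg = bound_gap,
    switch_tests = sw$tests,
    confidence_tests = csw$tests,
    transfer = transfer_flag
  )
  message("transfer: ", transfer_flag,
          " (trial 11 closer to trial ",
          if (transfer_flag == "no") "1" else "10", ")")

  out <- list(trials = cohort$trials, errors = errors,
              calibration = cohort$calibration, exclusions = excl,
              curves = curves, half = half, mdi = mdi, motor = motor,
              bounds = bounds, model_comparison = comp,
              single_predictor_comparison = single, stepwise = stepwise,
              switch = sw, confidence_switch = csw,
              time_resolved = trw, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
    write_calibration(cohort$calibration,
                      file.path(out_dir, "calibration.csv"))
    readr::write_csv(errors, file.path(out_dir, "errors.csv"),
                     progress = FALSE)
    readr::write_csv(curves, file.path(out_dir, "learning_curves.csv"),
                     progress = FALSE)
    readr::write_csv(comp$group, file.path(out_dir, "model_weights.csv"),
                     progress = FALSE)
    readr::write_csv(sw$tests, file.path(out_dir, "switch_tests.csv"),
                     progress = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
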