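#' Compute signed angular errors for a trial table
#'
#' Adds `error` (signed difference estimate - target, wrapped to
#' `(-180, 180]`), `abs_error`, and — when a `hint_angle` column is present
#' — `hint_error`/`abs_hint_error` computed identically for the hint. Rows
#' with a missing estimate or target are flagged as failed
#' (`timeout_or_tracking`); already-failed rows keep their reason. If
#' `estimate_angle` is absent it is inferred from the endpoint via
#' [infer_estimate()].
#'
#' @param trials A trial table (from the simulator or [read_trials()]).
#' @return The table with error columns added; failed rows are flagged,
#'   never dropped.
#' @export
compute_errors <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("target_angle", "response_type") %in% names(trials)))
  out <- tibble::as_tibble(trials)
  if (!"estimate_angle" %in% names(out)) {
    out$estimate_angle <- infer_estimate(out$endpoint_angle,
                                         out$response_type)
  }
  if (!"failed" %in% names(out)) out$failed <- FALSE
  if (!"failure_reason" %in% names(out)) out$failure_reason <- "none"
  missing <- is.na(out$estimate_angle) | is.na(out$target_angle)
  out$failed <- out$failed | missing
  out$failure_reason <- ifelse(missing & out$failure_reason == "none",
                               "timeout_or_tracking", out$failure_reason)
  out$error <- signed_angle_diff(out$estimate_angle, out$target_angle)
  out$abs_error <- abs(out$error)
  if ("hint_angle" %in% names(out)) {
    out$hint_error <- signed_angle_diff(out$hint_angle, out$target_angle)
    out$abs_hint_error <- abs(out$hint_error)
  }
  out
}

#' Flag wrong-response-type failures
#'
#' Trials whose absolute angular error exceeds the threshold (strictly)
#' are flagged as failed with reason `wrong_response_type`: executing a
#' pro-saccade when an anti-saccade was required (or vice versa) lands the
#' inferred estimate near 180 deg from the target, far above the threshold
#' separating the two modes of the error distribution. Rows already failed
#' keep their reason; the operation is idempotent.
#'
#' @param errors An error table from [compute_errors()].
#' @param threshold Threshold in degrees, strictly inside `(0, 180)`
#'   (default 100).
#' @return The table with updated `failed`/`failure_reason`.
#' @export
flag_failures <- function(errors, threshold = 100) {
  stopifnot(is.data.frame(errors), "abs_error" %in% names(errors))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 180) {
    stop("`threshold` must be a single value in (0, 180).", call. = FALSE)
  }
  hit <- !is.na(errors$abs_error) & errors$abs_error > threshold &
    errors$failure_reason == "none"
  errors$failed <- errors$failed | hit
  errors$failure_reason <- ifelse(hit, "wrong_response_type",
                                  errors$failure_reason)
  errors
}

#' Preprocess a raw trial table
#'
#' Convenience chain: [compute_errors()] then [flag_failures()].
#'
#' @inheritParams compute_errors
#' @inheritParams flag_failures
#' @return A flagged error table.
#' @export
preprocess <- function(trials, threshold = 100) {
  flag_failures(compute_errors(trials), threshold = threshold)
}

#' Exclusion accounting
#'
#' Counts rows per failure reason (including `none`) per response modality;
#' fractions are computed against the table's own per-modality row counts.
#'
#' @param errors A flagged error table.
#' @return A tibble with `response_type`, `failure_reason`, `n`, `total`,
#'   `fraction`.
#' @export
exclusion_summary <- function(errors) {
  stopifnot(is.data.frame(errors), "failure_reason" %in% names(errors))
  reasons <- c("none", "timeout_or_tracking", "wrong_response_type")
  errors |>
    dplyr::count(.data$response_type,
                 failure_reason = factor(.data$failure_reason,
                                         levels = reasons),
                 .drop = FALSE) |>
    dplyr::group_by(.data$response_type) |>
    dplyr::mutate(total = sum(.data$n),
                  fraction = .data$n / .data$total) |>
    dplyr::ungroup() |>
    dplyr::mutate(failure_reason = as.character(.data$failure_reason))
}

#' Keep only valid (non-failed) trials
#'
#' @param errors A flagged error table.
#' @return The subset of rows with `failed == FALSE`.
#' @export
valid_trials <- function(errors) {
  dplyr::filter(errors, !.data$failed)
}
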