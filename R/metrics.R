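#' Group learning curve
#'
#' Subject-level mean of a metric per trial index (and any further grouping
#' columns), then group mean and SEM across subjects. Only valid
#' (non-failed) trials contribute. The SEM is the SD of the per-subject
#' means divided by `sqrt(N subjects)`.
#'
#' @param errors A flagged error table ([preprocess()]).
#' @param metric Column to average, `"abs_error"` (default) or
#'   `"confidence"`.
#' @param group_by Character vector of extra grouping columns (e.g.
#'   `c("difficulty", "response_type")`); default none.
#' @return A tibble with the grouping columns, `trial_index`, `mean`,
#'   `sem`, `n_subjects`.
#' @export
learning_curve <- function(errors, metric = "abs_error",
                           group_by = character()) {
  stopifnot(metric %in% names(errors))
  valid_trials(errors) |>
    dplyr::filter(!is.na(.data[[metric]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("participant_id", group_by, "trial_index")
    ))) |>
    dplyr::summarise(subject_mean = mean(.data[[metric]]),
                     .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(group_by, "trial_index")
    ))) |>
    dplyr::summarise(
      mean = mean(.data$subject_mean),
      sem = stats::sd(.data$subject_mean) / sqrt(dplyr::n()),
      n_subjects = dplyr::n(),
      .groups = "drop"
    )
}

paired_t_safe <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) {
    stop("Paired comparison needs at least 2 subjects.", call. = FALSE)
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0))
    }
    stop("Zero-variance, non-zero paired differences: t statistic is ",
         "infinite (degenerate input).", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' First-half versus second-half learning contrast
#'
#' Per-subject mean of the metric over trials 1-5 versus trials 6-10
#' (configurable), compared by a paired two-sided t test. A drop from
#' first to second half in absolute error indicates learning within the
#' pre-switch trials.
#'
#' @param errors A flagged error table.
#' @param metric `"abs_error"` (default) or `"confidence"`.
#' @param first,second Trial-index sets defining the halves.
#' @return A list with `per_subject` (tibble: participant_id, first,
#'   second) and `t`, `p`, `df`, `mean_diff` (first minus second).
#' @export
half_comparison <- function(errors, metric = "abs_error",
                            first = 1:5, second = 6:10) {
  per <- valid_trials(errors) |>
    dplyr::filter(!is.na(.data[[metric]]),
                  .data$trial_index %in% c(first, second)) |>
    dplyr::mutate(half = ifelse(.data$trial_index %in% first,
                                "first", "second")) |>
    dplyr::group_by(.data$participant_id, .data$half) |>
    dplyr::summarise(m = mean(.data[[metric]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "half", values_from = "m")
  if (anyNA(per$first) || anyNA(per$second)) {
    stop("Both halves must be non-empty for every subject.", call. = FALSE)
  }
  c(list(per_subject = per), paired_t_safe(per$first, per$second))
}

#' Guess accuracy versus hint accuracy
#'
#' Per-subject mean absolute angular error of guesses versus hints over
#' the given trials, paired t test. Guesses beating the hints show that
#' information is integrated across trials rather than the current hint
#' merely being followed.
#'
#' @param errors A flagged error table (needs `abs_hint_error`).
#' @param trials Trial indices to include (default 1:10, the pre-switch
#'   half).
#' @return As [half_comparison()]: per-subject means plus paired t results
#'   (`mean_diff` is guess minus hint).
#' @export
guess_vs_hint_comparison <- function(errors, trials = 1:10) {
  stopifnot("abs_hint_error" %in% names(errors))
  per <- valid_trials(errors) |>
    dplyr::filter(.data$trial_index %in% trials) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(guess = mean(.data$abs_error),
                     hint = mean(.data$abs_hint_error),
                     .groups = "drop")
  c(list(per_subject = per), paired_t_safe(per$guess, per$hint))
}

#' Modality difference index
#'
#' Per-subject bounded asymmetry score between pro- and anti-saccade
#' accuracy: the difference of the two mean absolute errors divided by
#' their sum, in `[-1, 1]`. With `per_trial = TRUE` the index is computed
#' at each trial index.
#'
#' @param errors A flagged error table.
#' @param per_trial Logical; compute the index per trial index.
#' @return A tibble with `participant_id` (and `trial_index` if
#'   `per_trial`), `mean_pro`, `mean_anti`, `index`. A zero denominator
#'   yields `NA`.
#' @export
modality_difference_index <- function(errors, per_trial = FALSE) {
  keys <- c("participant_id", if (per_trial) "trial_index")
  wide <- valid_trials(errors) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(keys, "response_type")
    ))) |>
    dplyr::summarise(m = mean(.data$abs_error), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "response_type", values_from = "m",
                       names_prefix = "mean_")
  if (!all(c("mean_pro", "mean_anti") %in% names(wide))) {
    stop("Both modalities must be present to compute the index.",
         call. = FALSE)
  }
  wide |>
    dplyr::mutate(index = dplyr::if_else(
      .data$mean_pro + .data$mean_anti > 0,
      (.data$mean_pro - .data$mean_anti) / (.data$mean_pro + .data$mean_anti),
      NA_real_
    ))
}

#' Motor error from the calibration task
#'
#' Per subject and response modality, the mean absolute signed angular
#' error of the inferred estimate against the calibration target — the
#' motor-noise floor entering the performance lower bound and the
#' transfer correction.
#'
#' @param calibration A calibration trial table.
#' @return A tibble with `participant_id`, `response_type`, `gamma_motor`
#'   (degrees), `n_trials`.
#' @export
estimate_motor_error <- function(calibration) {
  stopifnot(all(c("participant_id", "response_type", "target_angle")
                %in% names(calibration)))
  est <- if ("estimate_angle" %in% names(calibration)) {
    calibration$estimate_angle
  } else {
    infer_estimate(calibration$endpoint_angle, calibration$response_type)
  }
  calibration |>
    dplyr::mutate(.err = abs(signed_angle_diff(est, .data$target_angle))) |>
    dplyr::filter(!is.na(.data$.err)) |>
    dplyr::group_by(.data$participant_id, .data$response_type) |>
    dplyr::summarise(gamma_motor = mean(.data$.err),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Ideal-observer lower bound on absolute angular error
#'
#' The best achievable mean absolute error at trial `t` combines, in
#' quadrature, the motor-noise floor and the sampling error of the
#' cumulative hint mean:
#' \deqn{\gamma(t) = \sqrt{\gamma_{Motor}^2 + \gamma_{Hint}(t)^2},}
#' with \eqn{\gamma_{Hint}(t) = \sqrt{2/\pi} \cdot \sigma_{dist} / \sqrt{t}}
#' and \eqn{\sigma_{dist} = \sqrt{1/\kappa}} (radians, converted to
#' degrees). Under the normal approximation, quadrature of mean absolute
#' errors and of SDs agree up to the common `sqrt(2/pi)` factor, so the
#' bound equals the mean absolute error of the joint estimate.
#'
#' @param gamma_motor Motor-noise floor as a mean absolute error, degrees,
#'   `>= 0`.
#' @param kappa von Mises concentration of the hint distribution, `> 0`.
#' @param t_max Number of trials (default 10).
#' @return A tibble with `trial_index`, `sigma_hint` (SD of the cumulative
#'   hint mean, degrees), `gamma_hint`, `gamma`.
#' @examples
#' lower_bound(gamma_motor = 3, kappa = 30, t_max = 5)
#' @export
lower_bound <- function(gamma_motor, kappa, t_max = 10) {
  if (!is.numeric(kappa) || kappa <= 0) {
    stop("`kappa` must be > 0.", call. = FALSE)
  }
  stopifnot(gamma_motor >= 0, t_max >= 1)
  t <- seq_len(t_max)
  sigma_hint <- kappa_to_sd(kappa) / sqrt(t)
  gamma_hint <- expected_abs_from_sd(sigma_hint)
  tibble::tibble(
    trial_index = t,
    sigma_hint = sigma_hint,
    gamma_hint = gamma_hint,
    gamma = sqrt(gamma_motor^2 + gamma_hint^2)
  )
}
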