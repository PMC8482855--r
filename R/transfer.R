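#' Motor-error-corrected per-trial means
#'
#' Per subject, condition (difficulty x order) and trial index, the mean
#' absolute angular error of valid trials minus the subject's calibration
#' motor error for the modality used at that trial. The subtraction makes
#' pro- and anti-saccade trials comparable across the response switch;
#' corrected values may be negative and are not clipped. Subjects without
#' calibration data for a needed modality are excluded with a warning.
#'
#' @param errors A flagged error table.
#' @param motor A motor-error table from [estimate_motor_error()], or
#'   `NULL` for no correction.
#' @param metric Column to average (default `"abs_error"`).
#' @return A tibble with `participant_id`, `difficulty`, `order`,
#'   `trial_index`, `response_type`, `raw_mean`, `gamma_motor`,
#'   `corrected` (equal to `raw_mean` when `motor` is `NULL`).
#' @export
motor_corrected_error <- function(errors, motor = NULL,
                                  metric = "abs_error") {
  means <- valid_trials(errors) |>
    dplyr::filter(!is.na(.data[[metric]])) |>
    dplyr::group_by(.data$participant_id, .data$difficulty, .data$order,
                    .data$trial_index, .data$response_type) |>
    dplyr::summarise(raw_mean = mean(.data[[metric]]), .groups = "drop")
  if (is.null(motor)) {
    means$gamma_motor <- 0
    means$corrected <- means$raw_mean
    return(means)
  }
  out <- dplyr::left_join(means, motor[, c("participant_id",
                                           "response_type",
                                           "gamma_motor")],
                          by = c("participant_id", "response_type"))
  bad <- unique(out$participant_id[is.na(out$gamma_motor)])
  if (length(bad) > 0) {
    warning("No calibration motor error for participant(s) ",
            paste(bad, collapse = ", "), "; excluded.", call. = FALSE)
    out <- dplyr::filter(out, !.data$participant_id %in% bad)
  }
  out$corrected <- out$raw_mean - out$gamma_motor
  out
}

#' Performance contrasts across the response switch
#'
#' Compares (motor-corrected) per-subject mean absolute error between
#' trial pairs straddling the modality switch — by default trial 10 versus
#' 11 (transfer probe: a drop at 11 means knowledge did not carry over)
#' and trial 1 versus 11 (naive baseline: equality means learning restarts
#' from scratch). Paired two-sided t tests are run per condition
#' (difficulty x order). No multiple-comparison correction is applied
#' (`p_adjust = "none"` recorded in the output).
#'
#' @param errors A flagged error table.
#' @param motor Optional motor-error table ([estimate_motor_error()]);
#'   when supplied, each trial's modality-specific motor error is
#'   subtracted first. Within-modality contrasts are invariant to this.
#' @param trial_pairs List of length-2 integer vectors (default
#'   `list(c(10, 11), c(1, 11))`).
#' @param metric Column to compare (default `"abs_error"`).
#' @return A list with `per_subject` (corrected means per trial of
#'   interest) and `tests` (tibble: difficulty, order, pair label,
#'   mean values, mean_diff second minus first, t, p, df, n), plus
#'   `p_adjust = "none"`.
#' @export
switch_contrast <- function(errors, motor = NULL,
                            trial_pairs = list(c(10, 11), c(1, 11)),
                            metric = "abs_error") {
  wanted <- unique(unlist(trial_pairs))
  means <- motor_corrected_error(errors, motor, metric = metric) |>
    dplyr::filter(.data$trial_index %in% wanted)
  tests <- purrr::map_dfr(trial_pairs, function(pair) {
    wide <- means |>
      dplyr::filter(.data$trial_index %in% pair) |>
      dplyr::select(dplyr::all_of(c("participant_id", "difficulty",
                                    "order", "trial_index",
                                    "corrected"))) |>
      tidyr::pivot_wider(names_from = "trial_index",
                         values_from = "corrected",
                         names_prefix = "t")
    a <- paste0("t", pair[1])
    b <- paste0("t", pair[2])
    wide |>
      dplyr::group_by(.data$difficulty, .data$order) |>
      dplyr::group_modify(function(g, key) {
        g <- g[stats::complete.cases(g[, c(a, b)]), ]
        res <- paired_t_safe(g[[b]], g[[a]])
        tibble::tibble(
          pair = paste0("trial", pair[2], "_vs_trial", pair[1]),
          mean_first = mean(g[[a]]), mean_second = mean(g[[b]]),
          mean_diff = res$mean_diff, t = res$t, p = res$p,
          df = res$df, n = nrow(g)
        )
      }) |>
      dplyr::ungroup()
  })
  list(per_subject = means, tests = tests, p_adjust = "none")
}

#' Confidence contrasts across the response switch
#'
#' The [switch_contrast()] machinery applied to the confidence rating (no
#' motor correction). Degenerate zero-variance differences (e.g. ratings
#' pinned at the scale ceiling) are an error, flagging the guard case.
#'
#' @inheritParams switch_contrast
#' @return As [switch_contrast()].
#' @export
confidence_switch <- function(errors,
                              trial_pairs = list(c(10, 11), c(1, 11))) {
  stopifnot("confidence" %in% names(errors))
  switch_contrast(errors, motor = NULL, trial_pairs = trial_pairs,
                  metric = "confidence")
}

#' Three-way repeated-measures ANOVA
#'
#' Within-subject F tests for three two-level (or more) factors and their
#' pairwise and three-way interactions, with subject as the random
#' blocking factor: each effect is tested against its own
#' subject-by-effect error stratum. Requires one observation per subject
#' per factor cell (a complete balanced within-subject design). Effects
#' with zero sum of squares report `F = 0`, `p = 1`.
#'
#' @param data A data frame with one value per subject per cell.
#' @param value Name of the dependent column.
#' @param factors Character vector of the three within-subject factor
#'   columns.
#' @param subject Name of the subject column (default
#'   `"participant_id"`).
#' @return A tibble with `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova3 <- function(data, value, factors,
                      subject = "participant_id") {
  stopifnot(length(factors) == 3,
            all(c(value, factors, subject) %in% names(data)))
  counts <- table(data[[subject]],
                  interaction(data[factors], drop = FALSE))
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)[1, ]
    stop("Unbalanced design: subject ", rownames(counts)[bad[1]],
         " has ", counts[bad[1], bad[2]], " observation(s) in cell ",
         colnames(counts)[bad[2]], " (need exactly 1).", call. = FALSE)
  }
  d <- data.frame(
    y = data[[value]],
    S = factor(data[[subject]]),
    A = factor(data[[factors[1]]]),
    B = factor(data[[factors[2]]]),
    C = factor(data[[factors[3]]])
  )
  effect_labels <- c(factors,
                     paste(factors[c(1, 1, 2)], factors[c(2, 3, 3)],
                           sep = ":"),
                     paste(factors, collapse = ":"))
  if (stats::var(d$y) == 0) { # fully degenerate: no variation at all
    la <- nlevels(d$A) - 1
    lb <- nlevels(d$B) - 1
    lc <- nlevels(d$C) - 1
    df1 <- c(la, lb, lc, la * lb, la * lc, lb * lc, la * lb * lc)
    return(tibble::tibble(
      effect = effect_labels,
      df1 = df1, df2 = df1 * (nlevels(d$S) - 1),
      F = rep(0, 7), p = rep(1, 7)
    ))
  }
  fml <- y ~ A * B * C + Error(S / (A * B * C))
  fit <- stats::aov(fml, data = d)
  smry <- summary(fit)
  effects <- c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")
  labels <- effect_labels
  out <- purrr::map_dfr(seq_along(effects), function(i) {
    eff <- effects[i]
    stratum <- smry[[paste0("Error: S:", gsub(":", ":", eff))]]
    tab <- stratum[[1]]
    row <- trimws(rownames(tab)) == eff
    ms_eff <- tab[row, "Mean Sq"]
    df1 <- tab[row, "Df"]
    res <- trimws(rownames(tab)) == "Residuals"
    df2 <- tab[res, "Df"]
    ms_err <- tab[res, "Mean Sq"]
    if (!is.finite(ms_eff) || ms_eff == 0) {
      f <- 0
      p <- 1
    } else if (ms_err == 0) {
      f <- Inf
      p <- 0
    } else {
      f <- ms_eff / ms_err
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    tibble::tibble(effect = labels[i], df1 = df1, df2 = df2, F = f, p = p)
  })
  out
}
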