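#' Generative agent parameters
#'
#' An agent produces its guess on trial `t` (expressed as a signed angular
#' error relative to the hidden target) as a weighted combination of lagged
#' guesses, current and lagged hints, and cumulative-average predictors,
#' plus modality-specific Gaussian motor noise:
#'
#' \deqn{g_t = b_0 + \sum_{j=1}^{3} w^{(g)}_j g_{t-j} +
#'   \sum_{j=0}^{3} w^{(h)}_j h_{t-j} +
#'   w_{ch} \, \overline{h}_{1..t} + w_{cg} \, \overline{g}_{1..t-1} +
#'   \epsilon_t}
#'
#' On early trials, lag terms without a predecessor are dropped and their
#' weight mass is added to the current-hint weight, so an agent whose
#' weights sum to one follows the hint (plus motor noise) on trial 1. If
#' `reset_on_switch` is `TRUE`, the switch acts as a memory boundary: all
#' lagged and cumulative terms restart after the modality switch, so the
#' first post-switch trial behaves like trial 1.
#'
#' @param w_guess Length-3 weights on guesses at lags 1..3.
#' @param w_hint Length-4 weights on hints at lags 0..3 (current first).
#' @param w_cumavg_hint Weight on the cumulative mean of hints seen so far
#'   (including the current trial's hint).
#' @param w_cumavg_guess Weight on the cumulative mean of all previous
#'   guesses (excluding the current trial).
#' @param intercept Constant bias, degrees.
#' @param motor_sd_pro,motor_sd_anti Motor noise SD, degrees, `>= 0`.
#' @param reset_on_switch Logical; discard pre-switch memory after the
#'   response-modality switch.
#' @param confidence_scale,confidence_offset Map from the agent's internal
#'   uncertainty (an SD in degrees) to the discrete 1..6 confidence rating,
#'   `round(offset - scale * sd)` clipped to `[1, 6]`.
#' @param confidence_noise_sd Trial-to-trial jitter (SD, degrees) on the
#'   internal uncertainty estimate before it is mapped to a rating; zero
#'   gives fully deterministic ratings.
#' @param p_timeout Per-trial probability of a timeout/tracking failure
#'   (trial recorded with missing endpoint).
#' @param p_wrong_type Per-trial probability of executing the wrong
#'   response type (endpoint rotated by 180 deg; detected downstream by the
#'   absolute-error threshold, not labelled at source).
#' @param seed Optional integer seed stored as metadata.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(w_guess = c(0, 0, 0),
                         w_hint = c(1, 0, 0, 0),
                         w_cumavg_hint = 0,
                         w_cumavg_guess = 0,
                         intercept = 0,
                         motor_sd_pro = 6.3,
                         motor_sd_anti = 9.5,
                         reset_on_switch = FALSE,
                         confidence_scale = 0.2,
                         confidence_offset = 6.2,
                         confidence_noise_sd = 3,
                         p_timeout = 0,
                         p_wrong_type = 0,
                         seed = NULL) {
  w_guess <- rep_len(as.numeric(w_guess), 3)
  w_hint <- rep_len(as.numeric(w_hint), 4)
  if (!all(is.finite(c(w_guess, w_hint, w_cumavg_hint, w_cumavg_guess,
                       intercept)))) {
    stop("Agent weights and intercept must be finite.", call. = FALSE)
  }
  if (motor_sd_pro < 0 || motor_sd_anti < 0) {
    stop("Motor noise SDs must be >= 0.", call. = FALSE)
  }
  stopifnot(p_timeout >= 0, p_timeout <= 1, p_wrong_type >= 0,
            p_wrong_type <= 1, confidence_noise_sd >= 0)
  structure(
    list(
      w_guess = w_guess,
      w_hint = w_hint,
      w_cumavg_hint = as.numeric(w_cumavg_hint),
      w_cumavg_guess = as.numeric(w_cumavg_guess),
      intercept = as.numeric(intercept),
      motor_sd_pro = as.numeric(motor_sd_pro),
      motor_sd_anti = as.numeric(motor_sd_anti),
      reset_on_switch = isTRUE(reset_on_switch),
      confidence_scale = as.numeric(confidence_scale),
      confidence_offset = as.numeric(confidence_offset),
      confidence_noise_sd = as.numeric(confidence_noise_sd),
      p_timeout = as.numeric(p_timeout),
      p_wrong_type = as.numeric(p_wrong_type),
      seed = seed
    ),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>\n")
  cat("  w_guess:", paste(signif(x$w_guess, 3), collapse = ", "), "\n")
  cat("  w_hint: ", paste(signif(x$w_hint, 3), collapse = ", "), "\n")
  cat("  w_cumavg_hint/guess:", signif(x$w_cumavg_hint, 3), "/",
      signif(x$w_cumavg_guess, 3), "\n")
  cat("  motor SD pro/anti:", x$motor_sd_pro, "/", x$motor_sd_anti,
      " reset_on_switch:", x$reset_on_switch, "\n")
  invisible(x)
}

#' The candidate regression models of trial-by-trial guessing
#'
#' The eleven-model space relating the current guess (signed angular error)
#' to current/lagged hints, lagged guesses and cumulative averages. Model 1
#' is a pure hint follower; model 3 the ideal observer (cumulative hint
#' mean); model 5 the cumulative mean of previous guesses; models 7-11 add
#' lagged terms up to three trials back.
#'
#' @return A tibble with `model_id`, `name`, and a list-column `predictors`
#'   of predictor names among `hint_0..hint_3`, `guess_1..guess_3`,
#'   `cumavg_hint`, `cumavg_guess`.
#' @export
model_specs <- function() {
  tibble::tibble(
    model_id = 1:11,
    name = c(
      "hint", "prev_hint", "cumavg_hint", "prev_guess", "cumavg_guess",
      "cumavg_hint_guess", "hint_lags", "guess_lags",
      "guess12_hint", "guess123_hint", "guess123_hint_lags"
    ),
    predictors = list(
      "hint_0",
      "hint_1",
      "cumavg_hint",
      "guess_1",
      "cumavg_guess",
      c("cumavg_hint", "cumavg_guess"),
      c("hint_0", "hint_1", "hint_2", "hint_3"),
      c("guess_1", "guess_2", "guess_3"),
      c("guess_1", "guess_2", "hint_0"),
      c("guess_1", "guess_2", "guess_3", "hint_0"),
      c("guess_1", "guess_2", "guess_3", "hint_0", "hint_1", "hint_2",
        "hint_3")
    )
  )
}

#' Agent implementing one of the candidate models
#'
#' Maps a model from [model_specs()] plus a coefficient vector onto
#' [agent_params()], so data can be generated from any model's dynamics
#' and fed back into the fitting machinery (parameter/model recovery).
#'
#' @param model_id Model id 1..11.
#' @param beta Coefficients for the model's predictors, in the order given
#'   by `model_specs()$predictors[[model_id]]`.
#' @param beta0 Intercept (default 0).
#' @param noise_sd Motor/residual noise SD in degrees, used for both
#'   modalities (default 3).
#' @param ... Passed on to [agent_params()].
#' @return An `agent_params` object.
#' @export
model_agent <- function(model_id, beta, beta0 = 0, noise_sd = 3, ...) {
  specs <- model_specs()
  stopifnot(model_id %in% specs$model_id)
  preds <- specs$predictors[[model_id]]
  if (length(beta) != length(preds)) {
    stop("`beta` must have one coefficient per predictor of model ",
         model_id, " (", length(preds), ").", call. = FALSE)
  }
  w_guess <- c(0, 0, 0)
  w_hint <- c(0, 0, 0, 0)
  w_ch <- 0
  w_cg <- 0
  for (i in seq_along(preds)) {
    p <- preds[i]
    if (grepl("^guess_", p)) {
      w_guess[as.integer(sub("guess_", "", p))] <- beta[i]
    } else if (grepl("^hint_", p)) {
      w_hint[as.integer(sub("hint_", "", p)) + 1L] <- beta[i]
    } else if (p == "cumavg_hint") {
      w_ch <- beta[i]
    } else {
      w_cg <- beta[i]
    }
  }
  agent_params(
    w_guess = w_guess, w_hint = w_hint,
    w_cumavg_hint = w_ch, w_cumavg_guess = w_cg,
    intercept = beta0,
    motor_sd_pro = noise_sd, motor_sd_anti = noise_sd,
    ...
  )
}

#' Ideal-observer agent
#'
#' Estimates the target with the cumulative circular mean of all hints seen
#' so far — the optimal way to combine samples — plus motor noise.
#'
#' @param motor_sd Motor noise SD in degrees for both modalities.
#' @param ... Passed on to [agent_params()].
#' @return An `agent_params` object.
#' @export
ideal_observer <- function(motor_sd = 3.5, ...) {
  agent_params(
    w_guess = c(0, 0, 0), w_hint = c(0, 0, 0, 0),
    w_cumavg_hint = 1, w_cumavg_guess = 0,
    motor_sd_pro = motor_sd, motor_sd_anti = motor_sd, ...
  )
}

#' Map internal uncertainty to a discrete confidence rating
#'
#' `round(confidence_offset - confidence_scale * internal_sd)` clipped to
#' the 1..6 scale; monotone non-increasing in `internal_sd`.
#'
#' @param internal_sd Internal uncertainty (SD, degrees), `>= 0`.
#' @param params An [agent_params()].
#' @return Integer rating(s) in 1..6.
#' @export
simulate_confidence <- function(internal_sd, params) {
  stopifnot(all(internal_sd >= 0))
  raw <- round(params$confidence_offset - params$confidence_scale * internal_sd)
  as.integer(pmin(pmax(raw, 1), 6))
}
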