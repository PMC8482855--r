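#' @importFrom stats rnorm runif
NULL

# Vectorised simulator core: one participant, all blocks at once.
# `blocks` is a design tibble (block_id, difficulty, order, kappa,
# target_angle); assumes the RNG state is already set by the caller.
sim_blocks_core <- function(blocks, spec, params, participant_id = 1L) {
  B <- nrow(blocks)
  TT <- spec$trials_per_block
  sw <- spec$switch_trial

  h <- matrix(0, B, TT) # signed hint errors (deg)
  for (k in unique(blocks$kappa)) {
    idx <- which(blocks$kappa == k)
    h[idx, ] <- signed_angle_diff(rvonmises(length(idx) * TT, 0, k), 0)
  }
  g <- matrix(NA_real_, B, TT)    # intended guess errors (deg)
  conf <- matrix(NA_integer_, B, TT)

  first_mod <- ifelse(blocks$order == "pro_first", "pro", "anti")
  other_mod <- ifelse(first_mod == "pro", "anti", "pro")
  sd_dist <- kappa_to_sd(blocks$kappa)

  wg <- params$w_guess
  wh <- params$w_hint
  s_full <- sum(wg) + sum(wh) + params$w_cumavg_hint + params$w_cumavg_guess

  sum_h <- numeric(B)
  sum_g <- numeric(B)
  cnt <- 0L
  for (t in seq_len(TT)) {
    b0 <- if (params$reset_on_switch && t > sw) sw else 0L
    if (t == b0 + 1L) { # memory boundary: block start or post-switch reset
      sum_h[] <- 0
      sum_g[] <- 0
      cnt <- 0L
    }
    sum_h <- sum_h + h[, t]
    cnt <- cnt + 1L
    cum_h <- sum_h / cnt
    cg_avail <- cnt >= 2L
    cum_g <- if (cg_avail) sum_g / (cnt - 1L) else NULL

    lag_avail <- seq_len(min(cnt - 1L, 3L))
    pred <- params$intercept + params$w_cumavg_hint * cum_h
    s_avail <- wh[1] + params$w_cumavg_hint
    for (j in lag_avail) {
      pred <- pred + wg[j] * g[, t - j] + wh[j + 1L] * h[, t - j]
      s_avail <- s_avail + wg[j] + wh[j + 1L]
    }
    if (cg_avail) {
      pred <- pred + params$w_cumavg_guess * cum_g
      s_avail <- s_avail + params$w_cumavg_guess
    }
    # weight mass of unavailable lag terms re-anchors on the current hint
    w0_eff <- wh[1] + (s_full - s_avail)
    pred <- pred + w0_eff * h[, t]

    mod_t <- if (t <= sw) first_mod else other_mod
    sd_t <- ifelse(mod_t == "pro", params$motor_sd_pro, params$motor_sd_anti)
    g[, t] <- pred + rnorm(B, 0, sd_t)
    sum_g <- sum_g + g[, t]

    internal_sd <- sqrt(sd_dist^2 / cnt + sd_t^2) +
      rnorm(B, 0, params$confidence_noise_sd)
    conf[, t] <- simulate_confidence(pmax(internal_sd, 0), params)
  }

  timeout <- matrix(runif(B * TT) < params$p_timeout, B, TT)
  wrong <- matrix(runif(B * TT) < params$p_wrong_type, B, TT) & !timeout

  sched <- trial_schedule(blocks, spec)
  ord <- order(match(sched$block_id, blocks$block_id), sched$trial_index)
  sched <- sched[ord, ]
  bi <- match(sched$block_id, blocks$block_id)
  ti <- sched$trial_index
  flat <- cbind(bi, ti)

  estimate_true <- wrap_angle(sched$target_angle + g[flat])
  endpoint <- ifelse(sched$response_type == "anti",
                     wrap_angle(estimate_true + 180), estimate_true)
  endpoint <- ifelse(wrong[flat], wrap_angle(endpoint + 180), endpoint)
  estimate <- infer_estimate(endpoint, sched$response_type)
  failed <- timeout[flat]
  endpoint[failed] <- NA_real_
  estimate[failed] <- NA_real_
  confidence <- conf[flat]
  confidence[failed] <- NA_integer_

  tibble::tibble(
    participant_id = as.integer(participant_id),
    block_id = sched$block_id,
    trial_index = ti,
    difficulty = sched$difficulty,
    response_type = sched$response_type,
    order = sched$order,
    target_angle = sched$target_angle,
    hint_angle = wrap_angle(sched$target_angle + h[flat]),
    endpoint_angle = endpoint,
    estimate_angle = estimate,
    confidence = confidence,
    failed = failed,
    failure_reason = ifelse(failed, "timeout_or_tracking", "none")
  )
}

#' Simulate one hidden-target block for an agent
#'
#' Runs the agent recurrence (see [agent_params()]) over the trials of a
#' single block: hints are von Mises samples around the block's target, the
#' guess is a weighted combination of lagged guesses/hints plus Gaussian
#' motor noise, and the saccade endpoint equals the estimate for pro trials
#' or its antipode for anti trials.
#'
#' @param block A one-row block descriptor as produced by
#'   [generate_design()] (columns `block_id`, `difficulty`, `order`,
#'   `kappa`, `target_angle`).
#' @param params An [agent_params()].
#' @param spec A [design_spec()].
#' @param seed Optional integer seed.
#' @param participant_id Participant label for the output rows.
#' @return A tibble of trial records (one row per trial).
#' @export
simulate_agent_block <- function(block, params, spec, seed = NULL,
                                 participant_id = 1L) {
  stopifnot(inherits(params, "agent_params"), inherits(spec, "design_spec"),
            nrow(block) == 1)
  run <- function() sim_blocks_core(block, spec, params, participant_id)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate the calibration task
#'
#' Visually guided pro- and anti-saccades to known targets, used to
#' quantify modality-specific motor error. Each block has 10 pro trials
#' followed by 10 anti trials; within each half every calibration location
#' is used once, in random order. Endpoints are the target (pro) or its
#' antipode (anti) plus Gaussian motor noise.
#'
#' @param spec A [design_spec()].
#' @param motor_sd_pro,motor_sd_anti Motor noise SDs in degrees, `>= 0`.
#' @param seed Optional integer seed.
#' @param participant_id Participant label.
#' @return A tibble with `participant_id`, `block_id`, `trial_index`,
#'   `response_type`, `target_angle`, `endpoint_angle`, `estimate_angle`.
#' @export
simulate_calibration <- function(spec, motor_sd_pro, motor_sd_anti,
                                 seed = NULL, participant_id = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  if (motor_sd_pro < 0 || motor_sd_anti < 0) {
    stop("Motor noise SDs must be >= 0.", call. = FALSE)
  }
  run <- function() {
    nloc <- length(spec$calibration_locations)
    blocks <- purrr::map_dfr(seq_len(spec$n_calibration_blocks), function(b) {
      targets <- c(sample(spec$calibration_locations, nloc),
                   sample(spec$calibration_locations, nloc))
      rt <- rep(c("pro", "anti"), each = nloc)
      noise <- rnorm(2 * nloc, 0,
                     ifelse(rt == "pro", motor_sd_pro, motor_sd_anti))
      endpoint <- wrap_angle(targets + ifelse(rt == "anti", 180, 0) + noise)
      tibble::tibble(
        participant_id = as.integer(participant_id),
        block_id = b,
        trial_index = seq_len(2 * nloc),
        response_type = rt,
        target_angle = targets,
        endpoint_angle = endpoint,
        estimate_angle = infer_estimate(endpoint, rt)
      )
    })
    blocks
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a cohort of participants
#'
#' Generates, for each participant, a counterbalanced block design, the
#' hidden-target trials of the given agent, and (optionally) calibration
#' data with the agent's motor noise.
#'
#' @param spec A [design_spec()].
#' @param params An [agent_params()], or a list of one per participant.
#' @param seed Optional integer seed governing everything.
#' @param calibration Logical; also simulate the calibration task.
#' @return A list with tibbles `trials` and (if requested) `calibration`.
#' @examples
#' cohort <- simulate_cohort(design_spec(n_participants = 2),
#'                           ideal_observer(), seed = 1)
#' @export
simulate_cohort <- function(spec, params, seed = NULL, calibration = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  if (inherits(params, "agent_params")) {
    params <- rep(list(params), spec$n_participants)
  }
  stopifnot(length(params) == spec$n_participants)
  run <- function() {
    trials <- vector("list", spec$n_participants)
    calib <- vector("list", spec$n_participants)
    for (p in seq_len(spec$n_participants)) {
      dseed <- sample.int(.Machine$integer.max, 1)
      design <- generate_design(spec, seed = dseed)
      trials[[p]] <- sim_blocks_core(design, spec, params[[p]], p)
      if (calibration) {
        calib[[p]] <- simulate_calibration(
          spec, params[[p]]$motor_sd_pro, params[[p]]$motor_sd_anti,
          participant_id = p
        )
      }
    }
    out <- list(trials = dplyr::bind_rows(trials))
    if (calibration) out$calibration <- dplyr::bind_rows(calib)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
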