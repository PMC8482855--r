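# Shared fixtures: small designs and reference agents, built in code.

small_spec <- function(n_participants = 4, n_blocks = 8, ...) {
  design_spec(n_participants = n_participants, n_blocks = n_blocks,
              location_set = seq(0, 315, by = 45), ...)
}

# Agent mirroring the empirical strategy: guesses follow the running mean
# of previous guesses plus the current hint, memory wiped at the switch.
reference_agent <- function(reset = TRUE, ...) {
  agent_params(w_cumavg_guess = 0.7, w_hint = c(0.3, 0, 0, 0),
               motor_sd_pro = 4, motor_sd_anti = 6,
               reset_on_switch = reset, ...)
}

make_errors <- function(spec = small_spec(), params = reference_agent(),
                        seed = 42) {
  co <- simulate_cohort(spec, params, seed = seed)
  list(errors = preprocess(co$trials), calibration = co$calibration)
}

# Exact von Mises dispersion/MAE by numerical integration (degrees):
# independent oracles for the sqrt(1/kappa) approximation.
vm_sd_exact <- function(kappa) {
  f <- function(th) th^2 * exp(kappa * cos(th)) / (2 * pi * besselI(kappa, 0))
  sqrt(stats::integrate(f, -pi, pi)$value) * 180 / pi
}

vm_mae_exact <- function(kappa) {
  f <- function(th) abs(th) * exp(kappa * cos(th)) /
    (2 * pi * besselI(kappa, 0))
  stats::integrate(f, -pi, pi)$value * 180 / pi
}

# Minimal hand-built error table for predictor/metric tests.
toy_error_table <- function(error, hint_error,
                            failed = rep(FALSE, length(error)),
                            participant_id = 1L, block_id = 1L) {
  tibble::tibble(
    participant_id = participant_id,
    block_id = block_id,
    trial_index = seq_along(error),
    response_type = "pro",
    difficulty = "easy",
    order = "pro_first",
    error = error,
    abs_error = abs(error),
    hint_error = hint_error,
    abs_hint_error = abs(hint_error),
    failed = failed,
    failure_reason = ifelse(failed, "timeout_or_tracking", "none")
  )
}
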