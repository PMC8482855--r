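#' Experimental design specification
#'
#' Describes the hidden-target experiment: 40 blocks of 20 trials, the
#' response modality switching after trial 10, the four counterbalanced
#' condition cells (easy/hard difficulty crossed with pro-first/anti-first
#' response order), 20 evenly spaced candidate target locations each used
#' `n_blocks / 20` times, and 4 calibration blocks of 20 trials (10 pro
#' then 10 anti) over 10 evenly spaced locations.
#'
#' @param n_participants Number of simulated participants (default 20).
#' @param n_blocks Number of hidden-target blocks; must be divisible by 4
#'   and by `length(location_set)` (default 40).
#' @param trials_per_block Trials per block (default 20).
#' @param switch_trial Trial index after which the response modality flips
#'   (default 10).
#' @param location_set Candidate target angles, degrees (default 20 evenly
#'   spaced on `[0, 360)`).
#' @param kappa_easy,kappa_hard,kappa_training von Mises concentrations of
#'   the hint distribution in the easy, hard and training conditions
#'   (defaults 30, 5, 80; angular spreads of roughly 10, 26 and 6 degrees).
#' @param ring_radius Ring radius in degrees of visual angle; metadata only
#'   (default 7.5).
#' @param n_calibration_blocks Number of calibration blocks (default 4).
#' @param calibration_locations Calibration target angles (default 10
#'   evenly spaced).
#' @param seed Integer seed controlling design randomisation.
#' @return An object of class `design_spec` (a named list).
#' @export
design_spec <- function(n_participants = 20,
                        n_blocks = 40,
                        trials_per_block = 20,
                        switch_trial = 10,
                        location_set = seq(0, 360 - 18, by = 18),
                        kappa_easy = 30,
                        kappa_hard = 5,
                        kappa_training = 80,
                        ring_radius = 7.5,
                        n_calibration_blocks = 4,
                        calibration_locations = seq(0, 360 - 36, by = 36),
                        seed = 1L) {
  if (n_blocks %% 4 != 0) {
    stop("`n_blocks` must be divisible by 4 to counterbalance the four ",
         "condition cells.", call. = FALSE)
  }
  if (n_blocks %% length(location_set) != 0) {
    stop("`n_blocks` must be divisible by the number of candidate target ",
         "locations.", call. = FALSE)
  }
  stopifnot(
    n_participants >= 1, trials_per_block >= 2,
    switch_trial >= 1, switch_trial < trials_per_block,
    kappa_easy > 0, kappa_hard > 0, kappa_training > 0,
    n_calibration_blocks >= 1
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      switch_trial = as.integer(switch_trial),
      location_set = wrap_angle(location_set),
      kappa_easy = kappa_easy,
      kappa_hard = kappa_hard,
      kappa_training = kappa_training,
      ring_radius = ring_radius,
      n_calibration_blocks = as.integer(n_calibration_blocks),
      calibration_locations = wrap_angle(calibration_locations),
      seed = as.integer(seed)
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat("  blocks:", x$n_blocks, "x", x$trials_per_block,
      "trials (switch after trial", paste0(x$switch_trial, ")\n"))
  cat("  locations:", length(x$location_set), "evenly spaced; kappa easy/hard =",
      x$kappa_easy, "/", x$kappa_hard, "\n")
  cat("  calibration:", x$n_calibration_blocks, "blocks;",
      x$n_participants, "participants; seed", x$seed, "\n")
  invisible(x)
}

kappa_for <- function(spec, difficulty) {
  ifelse(difficulty == "easy", spec$kappa_easy, spec$kappa_hard)
}

#' Generate a counterbalanced block design
#'
#' Assigns each block a difficulty, a response order and a target location
#' such that each of the four condition cells (easy/hard x pro-first/
#' anti-first) receives `n_blocks / 4` blocks and each candidate location is
#' used exactly `n_blocks / length(location_set)` times, in a random order
#' that is deterministic given `seed`.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return A tibble with one row per block: `block_id`, `difficulty`
#'   (`"easy"`/`"hard"`), `order` (`"pro_first"`/`"anti_first"`), `kappa`,
#'   and `target_angle`.
#' @examples
#' d <- generate_design(design_spec())
#' table(d$difficulty, d$order)
#' @export
generate_design <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "design_spec"))
  withr::with_seed(seed, {
    cells <- tidyr::expand_grid(
      difficulty = c("easy", "hard"),
      order = c("pro_first", "anti_first")
    )
    cells <- cells[rep(seq_len(nrow(cells)), each = spec$n_blocks / 4L), ]
    cells <- cells[sample.int(nrow(cells)), ]
    locs <- rep(spec$location_set,
                each = spec$n_blocks / length(spec$location_set))
    locs <- sample(locs)
    tibble::tibble(
      block_id = seq_len(spec$n_blocks),
      difficulty = cells$difficulty,
      order = cells$order,
      kappa = kappa_for(spec, cells$difficulty),
      target_angle = locs
    )
  })
}

#' Per-trial response schedule for a block design
#'
#' Expands a block design to one row per trial, assigning each trial the
#' response modality implied by the block's order: trials `1..switch_trial`
#' use the order's first modality, the remainder the other.
#'
#' @param design A tibble from [generate_design()].
#' @param spec The [design_spec()] used to build it.
#' @return A tibble with `block_id`, `trial_index`, `response_type` joined
#'   to the block columns.
#' @export
trial_schedule <- function(design, spec) {
  stopifnot(inherits(spec, "design_spec"))
  out <- tidyr::expand_grid(
    design,
    trial_index = seq_len(spec$trials_per_block)
  )
  first <- ifelse(out$order == "pro_first", "pro", "anti")
  second <- ifelse(out$order == "pro_first", "anti", "pro")
  out$response_type <- ifelse(out$trial_index <= spec$switch_trial,
                              first, second)
  out
}
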