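test_that("learning_curve averages subjects then the group", {
  # constant error -> flat curve with zero SEM
  tr <- dplyr::bind_rows(
    toy_error_table(rep(5, 10), rep(0, 10), participant_id = 1L),
    toy_error_table(rep(5, 10), rep(0, 10), participant_id = 2L)
  )
  lc <- learning_curve(tr)
  expect_true(all(lc$mean == 5))
  expect_true(all(lc$sem == 0))
  expect_true(all(lc$n_subjects == 2))
})

test_that("hint-follower curve is flat at the hint MAE; learner's decreases", {
  spec <- small_spec(n_participants = 6, n_blocks = 40)
  flw <- make_errors(spec, agent_params(motor_sd_pro = 0,
                                        motor_sd_anti = 0), seed = 5)
  lc <- learning_curve(flw$errors)
  lc10 <- lc[lc$trial_index <= 10, ]
  # no trend: first and last trial means agree within noise
  expect_lt(abs(lc10$mean[1] - lc10$mean[10]),
            3 * sqrt(lc10$sem[1]^2 + lc10$sem[10]^2) + 0.5)
  lrn <- make_errors(spec, ideal_observer(3), seed = 5)
  lc2 <- learning_curve(lrn$errors)
  expect_gt(lc2$mean[lc2$trial_index == 1],
            lc2$mean[lc2$trial_index == 10])
})

test_that("half comparison detects learning and handles degenerate input", {
  tr <- toy_error_table(rep(c(4, 4, 4, 4, 4), 2), rep(0, 10),
                        participant_id = 1L)
  tr2 <- tr
  tr2$participant_id <- 2L
  h <- half_comparison(dplyr::bind_rows(tr, tr2))
  expect_equal(h$t, 0)
  expect_equal(h$p, 1)
  # zero-variance non-zero differences are a degenerate error case
  tr3 <- dplyr::bind_rows(
    toy_error_table(c(rep(2, 5), rep(1, 5)), rep(0, 10),
                    participant_id = 1L),
    toy_error_table(c(rep(3, 5), rep(2, 5)), rep(0, 10),
                    participant_id = 2L),
    toy_error_table(c(rep(4, 5), rep(3, 5)), rep(0, 10),
                    participant_id = 3L)
  )
  expect_error(half_comparison(tr3), "infinite")
  # a learning cohort shows a significant first-half/second-half drop
  lrn <- make_errors(small_spec(n_participants = 12, n_blocks = 40),
                     reference_agent(), seed = 8)
  hh <- half_comparison(lrn$errors)
  expect_gt(hh$mean_diff, 0)
  expect_lt(hh$p, 0.01)
  # and beats the hints it sees
  gh <- guess_vs_hint_comparison(lrn$errors)
  expect_lt(gh$mean_diff, 0)
  expect_lt(gh$p, 0.01)
})

test_that("modality difference index follows its closed form", {
  tr <- dplyr::bind_rows(
    toy_error_table(rep(3.5, 6), rep(0, 6)),
    within(toy_error_table(rep(7.1, 6), rep(0, 6)), {
      response_type <- "anti"
      block_id <- 2L
    })
  )
  idx <- modality_difference_index(tr)
  expect_equal(idx$index, (3.5 - 7.1) / (3.5 + 7.1), tolerance = 1e-12)
  expect_equal(round(idx$index, 4), -0.3396)
  # anti error -> 0 pushes the index to +1
  tr$abs_error[tr$response_type == "anti"] <- 1e-9
  expect_equal(modality_difference_index(tr)$index, 1, tolerance = 1e-6)
  # zero denominator -> NA
  tr$abs_error <- 0
  expect_true(is.na(modality_difference_index(tr)$index))
})

test_that("motor error estimates are ordered with the generative SDs", {
  spec <- design_spec(n_participants = 1, n_calibration_blocks = 500)
  cal <- simulate_calibration(spec, 4, 8, seed = 14)
  me <- estimate_motor_error(cal)
  expect_equal(nrow(me), 2)
  g <- setNames(me$gamma_motor, me$response_type)
  expect_gt(g[["anti"]], g[["pro"]])
  expect_equal(g[["pro"]], 4 * sqrt(2 / pi), tolerance = 0.05)
  expect_equal(g[["anti"]], 8 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("lower bound obeys quadrature, monotonicity and its limit", {
  # 3-4-5 triangle: pick kappa so the trial-1 hint error is exactly 4
  kappa <- 1 / ((4 / (180 / pi * sqrt(2 / pi)))^2)
  b <- lower_bound(gamma_motor = 3, kappa = kappa, t_max = 6)
  expect_equal(b$gamma[1], 5, tolerance = 1e-12)
  expect_true(all(diff(b$gamma) < 0))
  expect_true(all(b$gamma >= 3))
  # large-t limit is the motor floor
  b2 <- lower_bound(3, 30, t_max = 1e6)
  expect_equal(b2$gamma[1e6], 3, tolerance = 1e-4)
  expect_error(lower_bound(3, 0), "kappa")
  expect_error(lower_bound(-1, 30))
})

test_that("MAE quadrature equals SD quadrature times sqrt(2/pi)", {
  sd_m <- 3.5
  for (kappa in c(5, 30, 80)) {
    b <- lower_bound(expected_abs_from_sd(sd_m), kappa, 10)
    sd_quad <- sqrt(sd_m^2 + (kappa_to_sd(kappa) / sqrt(1:10))^2)
    expect_equal(b$gamma, expected_abs_from_sd(sd_quad),
                 tolerance = 1e-12)
  }
})

test_that("cumulative-mean observer attains the bound (exact-dispersion check)", {
  # hard condition: the sqrt(1/kappa) spread is ~7% below the true von
  # Mises dispersion, so the Monte Carlo comparison uses the exact-SD
  # oracle. Trials 2..10 only: the cumulative mean is near-normal there,
  # making the MAE-quadrature reading of the bound applicable; at t = 1
  # the raw von Mises error at kappa = 5 is visibly non-normal.
  spec <- design_spec(n_participants = 1, n_blocks = 800,
                      location_set = c(0, 90, 180, 270))
  co <- simulate_cohort(spec, ideal_observer(3.5), seed = 17,
                        calibration = FALSE)
  e <- preprocess(co$trials)
  hard <- e[e$difficulty == "hard" & e$trial_index %in% 2:10, ]
  obs <- tapply(hard$abs_error, hard$trial_index, mean)
  sem <- tapply(hard$abs_error, hard$trial_index,
                function(x) sd(x) / sqrt(length(x)))
  gm <- expected_abs_from_sd(3.5)
  gh <- expected_abs_from_sd(vm_sd_exact(5)) / sqrt(2:10)
  bound <- sqrt(gm^2 + gh^2)
  z <- (obs - bound) / sem
  expect_lt(max(abs(z)), 3)
  expect_lt(mean(abs(z)), 1.5)
})
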