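test_that("motor correction subtracts the modality's calibration error", {
  tr <- toy_error_table(error = rep(12.1, 10), hint_error = rep(0, 10))
  motor <- tibble::tibble(participant_id = 1L, response_type = "pro",
                          gamma_motor = 3.5)
  mc <- motor_corrected_error(tr, motor)
  expect_equal(unique(mc$corrected), 12.1 - 3.5)
  # no motor table -> corrected equals raw
  mc0 <- motor_corrected_error(tr, NULL)
  expect_equal(mc0$corrected, mc0$raw_mean)
  # missing calibration excludes the subject with a warning
  motor2 <- tibble::tibble(participant_id = 2L, response_type = "pro",
                           gamma_motor = 1)
  expect_warning(out <- motor_corrected_error(tr, motor2), "excluded")
  expect_equal(nrow(out), 0)
})

test_that("switch contrasts separate reset from full-transfer agents", {
  spec <- small_spec(n_participants = 10, n_blocks = 40)
  reset <- make_errors(spec, reference_agent(reset = TRUE), seed = 71)
  motor <- estimate_motor_error(reset$calibration)
  sw <- switch_contrast(reset$errors, motor)
  t10 <- sw$tests[sw$tests$pair == "trial11_vs_trial10", ]
  t1 <- sw$tests[sw$tests$pair == "trial11_vs_trial1", ]
  # performance drops from trial 10 to 11 in every condition...
  expect_true(all(t10$mean_diff > 0))
  expect_true(all(t10$p < 0.05))
  # ...and trial 11 is back at naive trial-1 levels
  pooled_z <- sum(t1$mean_diff) /
    sqrt(sum((t1$mean_diff / t1$t)^2))
  expect_lt(abs(pooled_z), 3)
  # a non-reset agent carries its estimate across the switch
  full <- make_errors(spec, reference_agent(reset = FALSE), seed = 72)
  motor_f <- estimate_motor_error(full$calibration)
  sw_f <- switch_contrast(full$errors, motor_f)
  t10_f <- sw_f$tests[sw_f$tests$pair == "trial11_vs_trial10", ]
  expect_lt(mean(t10_f$mean_diff), mean(t10$mean_diff) / 3)
  expect_identical(sw$p_adjust, "none")
})

test_that("identical values at both trials give t = 0, p = 1", {
  tr <- dplyr::bind_rows(lapply(1:3, function(p) {
    out <- toy_error_table(error = rep(6, 20), hint_error = rep(0, 20))
    out$participant_id <- p
    out
  }))
  sw <- switch_contrast(tr, NULL, trial_pairs = list(c(10, 11)))
  expect_equal(sw$tests$t, 0)
  expect_equal(sw$tests$p, 1)
})

test_that("confidence drops at the switch for an uncertainty-coupled agent", {
  spec <- small_spec(n_participants = 10, n_blocks = 40)
  reset <- make_errors(spec, reference_agent(reset = TRUE), seed = 73)
  cs <- confidence_switch(reset$errors)
  t10 <- cs$tests[cs$tests$pair == "trial11_vs_trial10", ]
  expect_true(all(t10$mean_diff < 0))
  expect_true(any(t10$p < 0.05))
  # constant confidence -> degenerate zero-variance guard
  tr <- dplyr::bind_rows(lapply(1:3, function(p) {
    out <- toy_error_table(error = rnorm(20), hint_error = rep(0, 20))
    out$participant_id <- p
    out$confidence <- 6L
    out
  }))
  cs2 <- confidence_switch(tr, trial_pairs = list(c(10, 11)))
  expect_equal(cs2$tests$t, 0)
})

test_that("rm_anova3 matches closed-form expectations on simple inputs", {
  grid <- tidyr::expand_grid(
    participant_id = 1:6, difficulty = c("easy", "hard"),
    trial = c("t10", "t11"), order = c("pro_first", "anti_first")
  )
  # all observations equal -> F = 0, p = 1 everywhere
  g0 <- dplyr::mutate(grid, y = 1)
  a0 <- rm_anova3(g0, "y", c("difficulty", "trial", "order"))
  expect_true(all(a0$F == 0))
  expect_true(all(a0$p == 1))
  expect_equal(nrow(a0), 7)
  # strong additive difficulty effect dominates
  set.seed(81)
  g1 <- dplyr::mutate(grid,
                      y = 5 * (difficulty == "hard") + rnorm(dplyr::n()))
  a1 <- rm_anova3(g1, "y", c("difficulty", "trial", "order"))
  expect_lt(a1$p[a1$effect == "difficulty"], 0.001)
  expect_gt(min(a1$df1), 1 - 1e-9)
  # unbalanced design errors, naming the cell
  expect_error(rm_anova3(g1[-1, ], "y", c("difficulty", "trial", "order")),
               "Unbalanced")
})

test_that("rm_anova3 p value agrees with a within-subject permutation oracle", {
  set.seed(91)
  grid <- tidyr::expand_grid(
    participant_id = 1:8, a = c("lo", "hi"), b = c("x", "y"),
    c = c("u", "v")
  )
  grid$y <- 0.6 * (grid$a == "hi") + rnorm(nrow(grid))
  obs <- rm_anova3(grid, "y", c("a", "b", "c"))
  f_obs <- obs$F[obs$effect == "a"]
  # permutation: flip the two a-levels independently per subject/b/c cell
  perm_f <- replicate(300, {
    g <- grid
    for (p in unique(g$participant_id)) {
      for (bb in c("x", "y")) {
        for (cc in c("u", "v")) {
          idx <- which(g$participant_id == p & g$b == bb & g$c == cc)
          if (runif(1) < 0.5) g$y[idx] <- g$y[rev(idx)]
        }
      }
    }
    r <- rm_anova3(g, "y", c("a", "b", "c"))
    r$F[r$effect == "a"]
  })
  p_perm <- mean(perm_f >= f_obs)
  p_aov <- obs$p[obs$effect == "a"]
  expect_lt(abs(p_perm - p_aov), 0.15)
})
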