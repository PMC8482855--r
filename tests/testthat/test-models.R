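test_that("predictor table computes lags and cumulative averages per block", {
  tr <- toy_error_table(error = c(10, 2, 5), hint_error = c(4, -2, 6))
  p <- build_predictors(tr)
  expect_equal(p$cumavg_hint, c(4, 1, 8 / 3))
  expect_equal(p$cumavg_guess, c(NA, 10, 6))
  expect_equal(p$guess_1, c(NA, 10, 2))
  expect_equal(p$hint_1, c(NA, 4, -2))
  expect_true(is.na(p$guess_3[3]))
})

test_that("failed trials are skipped so lags refer to the previous valid trial", {
  tr <- toy_error_table(error = c(10, 99, 2, 5),
                        hint_error = c(4, 0, -2, 6),
                        failed = c(FALSE, TRUE, FALSE, FALSE))
  p <- build_predictors(tr)
  expect_equal(nrow(p), 3)
  # at t = 3, lag 1 refers to trial 1's guess under the skip rule
  expect_equal(p$guess_1[p$trial_index == 3], 10)
  expect_equal(p$guess_1[p$trial_index == 4], 2)
  # cumulative averages use valid trials only
  expect_equal(p$cumavg_hint[p$trial_index == 4], (4 - 2 + 6) / 3)
  expect_equal(p$cumavg_guess[p$trial_index == 4], 6)
  # lags never cross block boundaries
  tr2 <- dplyr::bind_rows(tr, within(tr, block_id <- 2L))
  p2 <- build_predictors(tr2)
  expect_true(all(is.na(p2$guess_1[p2$trial_index == 1])))
})

test_that("fit_ols recovers exact linear structure and rejects bad input", {
  x <- c(1, 2, 3, 4, 5, 6)
  tab <- tibble::tibble(guess = 2 * x, hint_0 = x)
  f <- fit_ols(tab, "hint_0")
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-10)
  expect_lt(f$rss, 1e-18)
  # rank-deficient design errors
  tab$hint_1 <- tab$hint_0
  expect_error(fit_ols(tab, c("hint_0", "hint_1")), "[Ss]ingular")
  expect_error(fit_ols(tab[1:3, ], c("hint_0", "hint_1")), "few")
})

test_that("fit_ols agrees with an SVD pseudo-inverse oracle", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 40
    tab <- tibble::tibble(
      guess = rnorm(n), hint_0 = rnorm(n), guess_1 = rnorm(n),
      cumavg_hint = rnorm(n)
    )
    preds <- c("hint_0", "guess_1", "cumavg_hint")
    f <- fit_ols(tab, preds)
    x <- cbind(1, as.matrix(tab[, preds]))
    sv <- svd(x)
    beta <- sv$v %*% (crossprod(sv$u, tab$guess) / sv$d)
    expect_equal(unname(f$coefficients), drop(beta), tolerance = 1e-6)
    expect_equal(f$rss, sum((tab$guess - x %*% beta)^2),
                 tolerance = 1e-8)
  }
})

test_that("BIC follows the Gaussian closed form", {
  # equal RSS and k -> equal BIC
  expect_equal(bic(10, n = 50, k = 3), bic(10, n = 50, k = 3))
  # halving RSS at one extra parameter for n = 100
  d <- bic(5, n = 100, k = 4) - bic(10, n = 100, k = 3)
  expect_equal(d, 100 * log(0.5) + log(100), tolerance = 1e-12)
  expect_equal(round(d, 1), -64.7)
  # ln(n) penalty per added parameter at fixed RSS
  expect_equal(bic(7, n = 64, k = 5) - bic(7, n = 64, k = 4), log(64))
  expect_error(bic(0, n = 10, k = 2), "RSS")
})

test_that("Bayesian weights normalise and follow exp(-delta/2)", {
  expect_equal(bayesian_weights(42), 1)
  expect_equal(bayesian_weights(c(3, 3)), c(0.5, 0.5))
  w <- bayesian_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  # invariance to a common shift
  expect_equal(bayesian_weights(c(0, 2, 5) + 1e4),
               bayesian_weights(c(0, 2, 5)))
  expect_error(bayesian_weights(c(NA, NA)), "finite")
})

test_that("model comparison identifies generating dynamics", {
  spec <- small_spec(n_participants = 6, n_blocks = 40)
  # pure hint follower -> model 1
  co1 <- simulate_cohort(spec, model_agent(1, 1, noise_sd = 3), seed = 51,
                         calibration = FALSE)
  p1 <- build_predictors(preprocess(co1$trials))
  g1 <- compare_models(p1, models = model_specs()[1:5, ],
                       trial_range = 2:10)$group
  expect_equal(g1$model_id[which.max(g1$mean_weight)], 1L)
  # cumulative-average-of-guesses integrator -> model 5
  co5 <- simulate_cohort(spec, model_agent(5, 0.7, noise_sd = 3),
                         seed = 52, calibration = FALSE)
  p5 <- build_predictors(preprocess(co5$trials))
  g5 <- compare_models(p5, models = model_specs()[1:5, ],
                       trial_range = 2:10)$group
  expect_equal(g5$model_id[which.max(g5$mean_weight)], 5L)
  # weights sum to one within every subject
  fits <- compare_models(p5, models = model_specs()[1:5, ],
                         trial_range = 2:10)$fits
  sums <- tapply(fits$weight, fits$participant_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("splitting by modality or difficulty partitions the fits", {
  lrn <- make_errors(small_spec(n_participants = 4, n_blocks = 40),
                     reference_agent(), seed = 53)
  p <- build_predictors(lrn$errors)
  bm <- compare_models(p, models = model_specs()[1:5, ],
                       trial_range = 2:10, split = "by_modality")
  expect_setequal(unique(bm$group$response_type), c("pro", "anti"))
  bd <- compare_models(p, models = model_specs()[1:5, ],
                       trial_range = 2:10, split = "by_difficulty")
  expect_setequal(unique(bd$group$difficulty), c("easy", "hard"))
})

test_that("stepwise CV finds an informative predictor and a sane null RMSE", {
  # blocks where only the trial-9 guess carries signal for trial 10
  set.seed(61)
  n_blocks <- 40
  base <- toy_error_table(error = rep(0, 10), hint_error = rep(0, 10))
  blocks <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    g9 <- rnorm(1, 0, 10)
    out <- base
    out$block_id <- b
    out$error <- c(rnorm(8, 0, 10), g9, 0.9 * g9 + rnorm(1, 0, 1))
    out$abs_error <- abs(out$error)
    out$hint_error <- rnorm(10, 0, 10)
    out
  })
  st <- stepwise_forward_cv(blocks, target_trial = 10, folds = 10,
                            seed = 2)
  expect_equal(st$per_subject$selected[[1]][1], "guess_t9")
  expect_lt(st$per_subject$best_rmse, st$per_subject$null_rmse)
  # null-model RMSE on zero-mean noise is about the noise SD
  expect_equal(st$per_subject$null_rmse, 10, tolerance = 3)
  expect_error(stepwise_forward_cv(blocks[blocks$block_id <= 5, ],
                                   folds = 10), "folds")
})

test_that("time-resolved weights expose the memory structure", {
  spec <- small_spec(n_participants = 8, n_blocks = 40)
  lrn <- make_errors(spec, reference_agent(reset = TRUE), seed = 55)
  trw <- time_resolved_weights(lrn$errors)
  g <- trw$group[trw$group$weight == "w_guess", ]
  h <- trw$group[trw$group$weight == "w_hint", ]
  expect_lt(abs(g$mean[g$trial_index == 11]), 0.15)
  expect_gt(min(g$mean[g$trial_index %in% c(2:10, 12:20)]), 0.3)
  # hint reliance peaks at the naive trials 1 and 11
  expect_gt(min(h$mean[h$trial_index %in% c(1, 11)]), 0.8)
  expect_lt(max(h$mean[!h$trial_index %in% c(1, 11)]), 0.6)
  # deeper lags cannot cross the switch either
  trw2 <- time_resolved_weights(lrn$errors, lag = 2)
  g2 <- trw2$group[trw2$group$weight == "w_guess", ]
  expect_lt(max(abs(g2$mean[g2$trial_index %in% c(11, 12)])), 0.15)
})

test_that("modality weight contrast is null for a symmetric agent", {
  lrn <- make_errors(small_spec(n_participants = 8, n_blocks = 40),
                     reference_agent(), seed = 57)
  mwc <- modality_weight_contrast(build_predictors(lrn$errors))
  expect_equal(nrow(mwc$tests), 2)
  expect_true(all(c("pro", "anti") %in% mwc$per_subject$response_type))
  # same generative weights in both modalities: differences are small
  expect_lt(max(abs(mwc$tests$mean_diff)), 0.2)
})
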