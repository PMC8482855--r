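#' Model-recovery simulation study
#'
#' Generates cohorts from the dynamics of each listed candidate model,
#' runs the full pipeline (simulate, preprocess, build predictors,
#' BIC-weight comparison) and records which model attains the highest
#' group-mean Bayesian weight, yielding per-model recovery rates.
#'
#' @param gen_models Integer ids of the generating models (default 1:5,
#'   the single-predictor set).
#' @param n_cohorts Cohorts per generating model (default 50).
#' @param beta Generative coefficient given to every predictor of the
#'   generating model (default 0.7).
#' @param noise_sd Motor/residual noise SD in degrees (default 3).
#' @param spec A [design_spec()] (default: the standard 20-participant,
#'   40-block design).
#' @param fit_models Model set fitted for the comparison (default models
#'   1-5).
#' @param trial_range Trials entering the fits (default `2:10`, usable by
#'   every single-predictor model).
#' @param seed Integer base seed; cohort `i` of model `m` uses
#'   `seed + 1000 * m + i`.
#' @return A list with `results` (tibble: gen_model, cohort, winner) and
#'   `rates` (tibble: gen_model, recovery_rate).
#' @export
model_recovery_study <- function(gen_models = 1:5, n_cohorts = 50,
                                 beta = 0.7, noise_sd = 3,
                                 spec = design_spec(),
                                 fit_models = model_specs()[1:5, ],
                                 trial_range = 2:10, seed = 1L) {
  specs <- model_specs()
  results <- purrr::map_dfr(gen_models, function(m) {
    k <- length(specs$predictors[[m]])
    agent <- model_agent(m, rep(beta, k), noise_sd = noise_sd)
    purrr::map_dfr(seq_len(n_cohorts), function(i) {
      co <- simulate_cohort(spec, agent, seed = seed + 1000L * m + i,
                            calibration = FALSE)
      preds <- build_predictors(preprocess(co$trials))
      g <- compare_models(preds, models = fit_models,
                          trial_range = trial_range)$group
      tibble::tibble(gen_model = m, cohort = i,
                     winner = g$model_id[which.max(g$mean_weight)])
    })
  })
  rates <- results |>
    dplyr::group_by(.data$gen_model) |>
    dplyr::summarise(recovery_rate = mean(.data$winner == .data$gen_model),
                     .groups = "drop")
  list(results = results, rates = rates)
}

#' Type-I error calibration of the inferential machinery
#'
#' Repeatedly simulates null cohorts (independent standard-normal cell
#' values for every subject in the 2 x 2 x 2 within-subject layout) and
#' records the rejection rate at `alpha` of every repeated-measures ANOVA
#' effect and of a paired t test between two null conditions. Under the
#' null all rates should sit at the nominal level.
#'
#' @param n_reps Number of simulated null cohorts (default 1000).
#' @param n_subjects Subjects per cohort (default 20).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return A tibble with `test` (effect name or `"paired_t"`) and
#'   `rejection_rate`.
#' @export
null_calibration_study <- function(n_reps = 1000, n_subjects = 20,
                                   alpha = 0.05, seed = 1L) {
  grid <- tidyr::expand_grid(
    participant_id = seq_len(n_subjects),
    difficulty = c("easy", "hard"),
    trial = c("pre", "post"),
    order = c("pro_first", "anti_first")
  )
  effects <- NULL
  withr::with_seed(seed, {
    ps <- matrix(NA_real_, n_reps, 8)
    for (r in seq_len(n_reps)) {
      g <- grid
      g$y <- rnorm(nrow(g))
      a <- rm_anova3(g, "y", c("difficulty", "trial", "order"))
      if (is.null(effects)) effects <- a$effect
      x1 <- rnorm(n_subjects)
      x2 <- rnorm(n_subjects)
      ps[r, ] <- c(a$p, stats::t.test(x1, x2, paired = TRUE)$p.value)
    }
    tibble::tibble(
      test = c(effects, "paired_t"),
      rejection_rate = colMeans(ps < alpha)
    )
  })
}
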