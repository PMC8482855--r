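#' Build lagged and cumulative predictors per block
#'
#' For each participant and block, orders the valid (non-failed) trials and
#' derives, on the signed-error scale, the dependent variable `guess`
#' (current guess error) and the predictors `hint_0..hint_3` (current and
#' lagged hint errors), `guess_1..guess_3` (lagged guess errors),
#' `cumavg_hint` (mean of hint errors seen so far, including the current
#' trial) and `cumavg_guess` (mean of all previous guess errors, excluding
#' the current trial). Lags never cross block boundaries; failed trials are
#' skipped, so a lag refers to the previous *valid* trial. Undefined lags
#' are `NA` and the row is dropped only by models that require them.
#'
#' @param errors A flagged error table from [preprocess()] (needs `error`
#'   and `hint_error`).
#' @return A predictor tibble with `participant_id`, `block_id`,
#'   `trial_index`, `response_type`, `difficulty`, `order` (if present),
#'   `guess`, and the predictor columns.
#' @export
build_predictors <- function(errors) {
  stopifnot(all(c("error", "hint_error") %in% names(errors)))
  keep <- intersect(c("participant_id", "block_id", "trial_index",
                      "response_type", "difficulty", "order"),
                    names(errors))
  valid_trials(errors) |>
    dplyr::select(dplyr::all_of(keep), guess = "error",
                  hint_0 = "hint_error") |>
    dplyr::arrange(.data$participant_id, .data$block_id,
                   .data$trial_index) |>
    dplyr::group_by(.data$participant_id, .data$block_id) |>
    dplyr::mutate(
      hint_1 = dplyr::lag(.data$hint_0, 1),
      hint_2 = dplyr::lag(.data$hint_0, 2),
      hint_3 = dplyr::lag(.data$hint_0, 3),
      guess_1 = dplyr::lag(.data$guess, 1),
      guess_2 = dplyr::lag(.data$guess, 2),
      guess_3 = dplyr::lag(.data$guess, 3),
      cumavg_hint = cumsum(.data$hint_0) / dplyr::row_number(),
      cumavg_guess = dplyr::lag(cumsum(.data$guess) / dplyr::row_number(), 1)
    ) |>
    dplyr::ungroup()
}

#' Ordinary least squares fit of one candidate model
#'
#' Least-squares coefficients (with intercept) of `response ~ predictors`
#' on the complete-case rows of the table. The solution is the standard
#' QR-based OLS fit; rank deficiency is an error.
#'
#' @param table A predictor tibble ([build_predictors()]), already
#'   restricted to the rows to fit.
#' @param predictors Character vector of predictor column names.
#' @param response Response column name (default `"guess"`).
#' @return A list with `coefficients` (named, intercept first), `rss`,
#'   `n`, `k` (coefficients plus one for the error variance), `predictors`.
#' @export
fit_ols <- function(table, predictors, response = "guess") {
  stopifnot(all(c(response, predictors) %in% names(table)))
  cols <- c(response, predictors)
  dat <- table[stats::complete.cases(table[, cols, drop = FALSE]), cols,
               drop = FALSE]
  p <- length(predictors) + 1L
  if (nrow(dat) < p + 2L) {
    stop("Too few complete rows (", nrow(dat), ") to fit ", p,
         " coefficients.", call. = FALSE)
  }
  x <- cbind(`(Intercept)` = 1,
             as.matrix(dat[, predictors, drop = FALSE]))
  y <- dat[[response]]
  fit <- stats::lm.fit(x, y)
  if (fit$rank < ncol(x)) {
    stop("Singular fit: design matrix is rank deficient (predictors: ",
         paste(predictors, collapse = ", "), ").", call. = FALSE)
  }
  list(
    coefficients = fit$coefficients,
    rss = sum(fit$residuals^2),
    n = nrow(dat),
    k = p + 1L,
    predictors = predictors
  )
}

#' Gaussian-likelihood BIC of an OLS fit
#'
#' `n * log(RSS / n) + k * log(n)` with `k` counting the regression
#' coefficients (including the intercept) plus one for the error variance;
#' additive constants cancel in BIC differences.
#'
#' @param fit A fit from [fit_ols()], or the RSS value.
#' @param n,k Sample size and parameter count (taken from `fit` when a fit
#'   object is given).
#' @return The BIC value.
#' @export
bic <- function(fit, n = NULL, k = NULL) {
  if (is.list(fit)) {
    n <- fit$n
    k <- fit$k
    rss <- fit$rss
  } else {
    rss <- fit
  }
  stopifnot(!is.null(n), !is.null(k))
  if (rss <= 0) {
    stop("Degenerate fit: RSS must be > 0 for a Gaussian BIC.",
         call. = FALSE)
  }
  n * log(rss / n) + k * log(n)
}

#' Bayesian model weights from BIC values
#'
#' Rescales each BIC by the difference to the smallest in the set
#' (`delta`), then normalises `exp(-delta/2)`; the weights sum to one and
#' estimate the probability of each model being the best among those
#' compared. Invariant to adding any constant to all BICs.
#'
#' @param bics Numeric vector of BIC values.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' bayesian_weights(c(100, 102)) # ~0.731, 0.269
#' @export
bayesian_weights <- function(bics) {
  if (!any(is.finite(bics))) {
    stop("At least one BIC must be finite.", call. = FALSE)
  }
  delta <- bics - min(bics, na.rm = TRUE)
  w <- exp(-delta / 2)
  w / sum(w, na.rm = TRUE)
}

#' Compare candidate models per subject by Bayesian weights
#'
#' Fits every model of the set to each subject's rows in `trial_range`,
#' on the *common* complete-case row set of the union of all predictors
#' (so all models see identical data), and converts BICs to weights. The
#' default range 4:10 supports lags up to three; the single-predictor set
#' (models 1-5) can be evaluated on 2:10.
#'
#' @param table A predictor tibble from [build_predictors()].
#' @param models A subset of [model_specs()] (default all 11).
#' @param trial_range Trial indices entering the fits (default `4:10`).
#' @param split `"pooled"` (default), `"by_modality"` or `"by_difficulty"`:
#'   fit within levels of the splitting column.
#' @return A list with `fits` (tibble: split level, participant, model,
#'   coefficients list-column, rss, n, bic, delta_bic, weight) and
#'   `group` (mean weight per model per split level).
#' @export
compare_models <- function(table, models = model_specs(),
                           trial_range = 4:10,
                           split = c("pooled", "by_modality",
                                     "by_difficulty")) {
  split <- match.arg(split)
  split_col <- switch(split, pooled = NULL, by_modality = "response_type",
                      by_difficulty = "difficulty")
  all_preds <- unique(unlist(models$predictors))
  dat <- dplyr::filter(table, .data$trial_index %in% trial_range)
  dat <- dat[stats::complete.cases(
    dat[, c("guess", all_preds), drop = FALSE]
  ), ]
  if (nrow(dat) == 0) {
    stop("No complete rows in `trial_range` for the requested model set.",
         call. = FALSE)
  }
  groups <- dplyr::group_split(
    dplyr::group_by(dat, dplyr::across(dplyr::all_of(
      c(split_col, "participant_id")
    )))
  )
  fits <- purrr::map_dfr(groups, function(g) {
    rows <- purrr::map2_dfr(models$model_id, models$predictors,
                            function(id, preds) {
      f <- fit_ols(g, preds)
      tibble::tibble(
        model_id = id,
        coefficients = list(f$coefficients),
        rss = f$rss, n = f$n, k = f$k, bic = bic(f)
      )
    })
    rows$delta_bic <- rows$bic - min(rows$bic)
    rows$weight <- bayesian_weights(rows$bic)
    rows$participant_id <- g$participant_id[1]
    if (!is.null(split_col)) rows[[split_col]] <- g[[split_col]][1]
    rows
  })
  fits <- dplyr::left_join(fits, models[, c("model_id", "name")],
                           by = "model_id")
  group <- fits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(split_col, "model_id", "name")
    ))) |>
    dplyr::summarise(mean_weight = mean(.data$weight),
                     sem_weight = stats::sd(.data$weight) / sqrt(dplyr::n()),
                     n_subjects = dplyr::n(), .groups = "drop")
  list(fits = fits, group = group, trial_range = trial_range,
       split = split)
}

# Per-subject block-by-trial matrices of guess and hint errors for the
# stepwise analysis; only blocks with all needed trials valid are kept.
blockwise_matrix <- function(errors, participant, target_trial) {
  d <- valid_trials(errors) |>
    dplyr::filter(.data$participant_id == participant,
                  .data$trial_index <= target_trial)
  wide_g <- tidyr::pivot_wider(
    d[, c("block_id", "trial_index", "error")],
    names_from = "trial_index", values_from = "error",
    names_prefix = "guess_t"
  )
  wide_h <- tidyr::pivot_wider(
    d[, c("block_id", "trial_index", "hint_error")],
    names_from = "trial_index", values_from = "hint_error",
    names_prefix = "hint_t"
  )
  out <- dplyr::inner_join(wide_g, wide_h, by = "block_id")
  out[stats::complete.cases(out), ]
}

cv_rmse <- function(y, x, folds_id) {
  errs <- numeric(max(folds_id))
  for (f in seq_len(max(folds_id))) {
    tr <- folds_id != f
    te <- !tr
    if (is.null(x)) {
      pred <- mean(y[tr])
    } else {
      xt <- cbind(1, x[tr, , drop = FALSE])
      b <- stats::lm.fit(xt, y[tr])$coefficients
      b[is.na(b)] <- 0
      pred <- cbind(1, x[te, , drop = FALSE]) %*% b
    }
    errs[f] <- sqrt(mean((y[te] - pred)^2))
  }
  mean(errs)
}

#' Forward stepwise predictor selection with cross-validated RMSE
#'
#' Per subject, treats blocks as observations and predicts the guess error
#' at `target_trial` from that block's earlier guess errors
#' (`guess_t1..guess_t{target-1}`) and hint errors
#' (`hint_t1..hint_t{target}`). Greedy forward selection adds, at each
#' step, the predictor that most reduces the mean held-out RMSE over
#' `folds` folds (fold assignment deterministic given `seed`), stopping
#' when no candidate improves. The intercept-only (null) model RMSE is the
#' baseline.
#'
#' @param errors A flagged error table.
#' @param target_trial Trial whose guess error is predicted (default 10).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment (default 1).
#' @return A list with `per_subject` (tibble: participant_id, null_rmse,
#'   best_rmse, selected list-column, path list-column) and `inclusion`
#'   (tibble: predictor, n_subjects selected).
#' @export
stepwise_forward_cv <- function(errors, target_trial = 10, folds = 10,
                                seed = 1L) {
  participants <- sort(unique(errors$participant_id))
  per <- purrr::map_dfr(participants, function(p) {
    mat <- blockwise_matrix(errors, p, target_trial)
    if (nrow(mat) < folds) {
      stop("Participant ", p, " has fewer complete blocks (", nrow(mat),
           ") than folds (", folds, ").", call. = FALSE)
    }
    y <- mat[[paste0("guess_t", target_trial)]]
    cand <- setdiff(names(mat), c("block_id",
                                  paste0("guess_t", target_trial)))
    x_all <- as.matrix(mat[, cand, drop = FALSE])
    folds_id <- withr::with_seed(
      seed + p, sample(rep(seq_len(folds), length.out = length(y)))
    )
    selected <- character()
    best <- cv_rmse(y, NULL, folds_id)
    path <- tibble::tibble(step = 0L, predictor = "(none)",
                           cv_rmse = best)
    repeat {
      remaining <- setdiff(cand, selected)
      if (length(remaining) == 0) break
      trial_rmse <- vapply(remaining, function(v) {
        cv_rmse(y, x_all[, c(selected, v), drop = FALSE], folds_id)
      }, numeric(1))
      if (min(trial_rmse) >= best) break
      pick <- remaining[which.min(trial_rmse)]
      selected <- c(selected, pick)
      best <- min(trial_rmse)
      path <- dplyr::bind_rows(path, tibble::tibble(
        step = length(selected), predictor = pick, cv_rmse = best
      ))
    }
    tibble::tibble(
      participant_id = p,
      null_rmse = path$cv_rmse[1],
      best_rmse = best,
      n_selected = length(selected),
      selected = list(selected),
      path = list(path)
    )
  })
  inclusion <- per |>
    dplyr::pull("selected") |>
    unlist() |>
    table()
  inclusion <- tibble::tibble(
    predictor = names(inclusion),
    n_subjects = as.integer(inclusion)
  )
  list(per_subject = per, inclusion = inclusion)
}

#' Time-resolved regression weights across the response switch
#'
#' At each trial index `t`, regresses the guess error on the guess error
#' `lag` trials earlier and the current hint error, across a subject's
#' blocks (strict trial-index lags; blocks missing either trial are
#' dropped). Group-level significance is a two-sided one-sample t test of
#' the per-subject weights against zero. A memoryless transition at the
#' switch shows as a guess weight near zero at the first post-switch trial
#' together with a current-hint weight peaking there and at trial 1.
#'
#' @param errors A flagged error table.
#' @param lag Guess lag (1, 2 or 3; default 1).
#' @param trial_set Trial indices to evaluate (default `(lag+1):20` for
#'   the guess weight plus trial 1 for the hint-only model).
#' @param min_blocks Minimum complete blocks per subject per trial
#'   (default 8); subjects below it are omitted with a warning.
#' @return A list with `per_subject` (participant_id, trial_index,
#'   w_guess, w_hint) and `group` (trial_index, per-weight mean, sem, t,
#'   p, n_subjects).
#' @export
time_resolved_weights <- function(errors, lag = 1, trial_set = NULL,
                                  min_blocks = 8) {
  stopifnot(lag %in% 1:3)
  t_max <- max(errors$trial_index)
  if (is.null(trial_set)) trial_set <- seq_len(t_max)
  d <- valid_trials(errors)
  per <- purrr::map_dfr(sort(unique(d$participant_id)), function(p) {
    dp <- dplyr::filter(d, .data$participant_id == p)
    purrr::map_dfr(trial_set, function(t) {
      cur <- dplyr::filter(dp, .data$trial_index == t)[
        , c("block_id", "error", "hint_error")]
      has_lag <- t - lag >= 1
      if (has_lag) {
        prev <- dplyr::filter(dp, .data$trial_index == t - lag)[
          , c("block_id", "error")]
        names(prev)[2] <- "prev_error"
        cur <- dplyr::inner_join(cur, prev, by = "block_id")
      }
      cur <- cur[stats::complete.cases(cur), ]
      if (nrow(cur) < max(min_blocks, (2 + has_lag) + 2)) {
        warning("Participant ", p, ", trial ", t,
                ": too few complete blocks; omitted.", call. = FALSE)
        return(NULL)
      }
      x <- if (has_lag) cbind(1, cur$prev_error, cur$hint_error) else
        cbind(1, cur$hint_error)
      fit <- stats::lm.fit(x, cur$error)
      if (fit$rank < ncol(x)) {
        warning("Participant ", p, ", trial ", t,
                ": singular design; omitted.", call. = FALSE)
        return(NULL)
      }
      b <- fit$coefficients
      tibble::tibble(
        participant_id = p, trial_index = t,
        w_guess = if (has_lag) b[2] else NA_real_,
        w_hint = if (has_lag) b[3] else b[2]
      )
    })
  })
  one_sample <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    tt <- stats::t.test(x)
    c(unname(tt$statistic), tt$p.value)
  }
  group <- per |>
    tidyr::pivot_longer(c("w_guess", "w_hint"), names_to = "weight",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$trial_index, .data$weight) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      t = one_sample(.data$value)[1],
      p = one_sample(.data$value)[2],
      n_subjects = dplyr::n(),
      .groups = "drop"
    )
  list(per_subject = per, group = group, lag = lag)
}

#' Pro/anti contrast of regression weights
#'
#' Fits the full lagged model (model 11) separately to each subject's pro
#' and anti rows of the predictor table (trials 4-10 by default, where the
#' response type equals the block's first modality) and compares the
#' previous-guess weight (`guess_1`) and the current-hint weight
#' (`hint_0`) between modalities with paired two-sided t tests.
#'
#' @param table A predictor tibble.
#' @param trial_range Trial indices used (default `4:10`).
#' @return A list with `per_subject` (participant, modality, w_guess,
#'   w_hint) and `tests` (tibble: weight, t, p, df, mean_diff pro minus
#'   anti).
#' @export
modality_weight_contrast <- function(table, trial_range = 4:10) {
  preds <- model_specs()$predictors[[11]]
  dat <- dplyr::filter(table, .data$trial_index %in% trial_range)
  per <- dat |>
    dplyr::group_by(.data$participant_id, .data$response_type) |>
    dplyr::group_modify(function(g, key) {
      f <- fit_ols(g, preds)
      tibble::tibble(w_guess = unname(f$coefficients["guess_1"]),
                     w_hint = unname(f$coefficients["hint_0"]))
    }) |>
    dplyr::ungroup()
  wide_g <- tidyr::pivot_wider(per[, c("participant_id", "response_type",
                                       "w_guess")],
                               names_from = "response_type",
                               values_from = "w_guess")
  wide_h <- tidyr::pivot_wider(per[, c("participant_id", "response_type",
                                       "w_hint")],
                               names_from = "response_type",
                               values_from = "w_hint")
  tg <- paired_t_safe(wide_g$pro, wide_g$anti)
  th <- paired_t_safe(wide_h$pro, wide_h$anti)
  tests <- tibble::tibble(
    weight = c("guess_1", "hint_0"),
    t = c(tg$t, th$t), p = c(tg$p, th$p), df = c(tg$df, th$df),
    mean_diff = c(tg$mean_diff, th$mean_diff)
  )
  list(per_subject = per, tests = tests)
}
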