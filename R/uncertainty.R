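#' Regress response deviation on imposed shift
#'
#' The core behavioural statistic of the paradigm: ordinary least squares of
#' each trial's radial response deviation on that trial's imposed cursor
#' shift. The slope measures how strongly the learned expectation of the
#' shift pulls the response (the prior weight of the Bayesian observer);
#' the root-mean-squared error about the line is the behavioural proxy for
#' the uncertainty in the central nervous system's position estimate.
#'
#' RMSE is computed literally as `sqrt(SSE / n)` — root *mean* squared
#' error — not the residual standard error `sqrt(SSE / (n - 2))`; at the
#' block sizes used here (100+ trials) the two differ by under 1%.
#'
#' @param trials A data frame with numeric columns `shift` and `deviation`
#'   (cm); identifier columns (`participant_id`, `group`, `visit`, `block`),
#'   when present, are carried into the output.
#' @return A one-row tibble: any identifiers present, then `n_trials`,
#'   `slope`, `intercept`, `rmse`, `r_squared`.
#' @export
#' @examples
#' trials <- tibble::tibble(shift = c(-10, -8, -6, -4))
#' trials$deviation <- 0.5 * trials$shift + 3.75
#' fit_deviation_regression(trials) # slope 0.5, intercept 3.75, rmse 0
fit_deviation_regression <- function(trials) {
  check_trial_columns(trials, c("shift", "deviation"))
  n <- nrow(trials)
  if (n < 3L) {
    rlang::abort("Need at least 3 trials to fit the regression.",
                 class = "stepsense_insufficient_data")
  }
  if (stats::var(trials$shift) <= 0) {
    rlang::abort("Imposed shifts are constant; the regression is degenerate.",
                 class = "stepsense_degenerate_design")
  }
  fit <- stats::lm(deviation ~ shift, data = trials)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((trials$deviation - mean(trials$deviation))^2)
  ids <- intersect(c("participant_id", "group", "visit", "block"), names(trials))
  out <- dplyr::summarise(trials, dplyr::across(dplyr::all_of(ids), dplyr::first))
  dplyr::bind_cols(
    tibble::as_tibble(out),
    tibble::tibble(
      n_trials = n,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rmse = sqrt(sse / n),
      r_squared = if (sst > 0) 1 - sse / sst else 0
    )
  )
}

#' Per-participant-visit(-block) regression summaries for a cohort
#'
#' Applies [fit_deviation_regression()] to every analysis unit of a trial
#' table. The default unit is the participant-visit-block (five summaries
#' per visit), matching an analysis in which each participant contributes
#' several observations per visit and a participant random intercept absorbs
#' the repetition; `per_block = FALSE` pools all assessment trials of a
#' visit into one regression.
#'
#' Trials flagged as training (a logical `training` column, or `block == 0`)
#' are excluded; assessment blocks are numbered 1 and up. No outlier
#' trimming is applied.
#'
#' @param trials A cohort trial table (see [simulate_cohort()]).
#' @param per_block Summarise per block (default `TRUE`) or per visit.
#' @return A tibble of regression summaries, one row per unit.
#' @export
rmse_table <- function(trials, per_block = TRUE) {
  check_trial_columns(trials,
                      c("participant_id", "group", "visit", "shift", "deviation"))
  if (per_block && !"block" %in% names(trials)) {
    rlang::abort("`per_block = TRUE` needs a `block` column.",
                 class = "stepsense_schema_error")
  }
  if ("training" %in% names(trials)) trials <- dplyr::filter(trials, !.data$training)
  if ("block" %in% names(trials)) trials <- dplyr::filter(trials, .data$block >= 1L)
  keys <- c("participant_id", "group", "visit", if (per_block) "block")
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ fit_deviation_regression(.x)) |>
    dplyr::ungroup()
}

#' Invert the observer model: noise SDs from slope and RMSE
#'
#' Maps a fitted regression summary back to the observer's noise parameters
#' under the well-calibrated Bayesian model. The slope `w` identifies the
#' visual noise through `sigma_visual = sigma_prior * sqrt(w / (1 - w))`;
#' the residual RMSE then identifies the motor noise through
#' `sigma_motor^2 = rmse^2 - (1 - w)^2 * sigma_visual^2`. When the sampled
#' RMSE falls below the visual-noise floor the motor variance is clamped at
#' zero and flagged.
#'
#' @param summary A data frame with columns `slope` and `rmse` (e.g. one or
#'   more rows of [rmse_table()] output).
#' @param sigma_prior SD of the imposed shift distribution (cm, > 0),
#'   default 2.5.
#' @return The input with columns `sigma_visual_hat`, `sigma_motor_hat` and
#'   logical `clamped` appended.
#' @export
#' @examples
#' recover_sensory_noise(tibble::tibble(slope = 0.5, rmse = 2.0))
recover_sensory_noise <- function(summary, sigma_prior = 2.5) {
  check_trial_columns(summary, c("slope", "rmse"))
  if (sigma_prior <= 0) {
    rlang::abort("`sigma_prior` must be > 0.", class = "stepsense_invalid_parameter")
  }
  w <- summary$slope
  if (any(w <= 0 | w >= 1)) {
    bad <- which(w <= 0 | w >= 1)
    rlang::abort(
      sprintf("Slope outside (0, 1) in row(s) %s (values %s): the observer model is not invertible there.",
              paste(bad, collapse = ", "),
              paste(signif(w[bad], 3), collapse = ", ")),
      class = "stepsense_noninvertible"
    )
  }
  sv <- sigma_prior * sqrt(w / (1 - w))
  m2 <- summary$rmse^2 - (1 - w)^2 * sv^2
  dplyr::mutate(tibble::as_tibble(summary),
                sigma_visual_hat = sv,
                sigma_motor_hat = sqrt(pmax(0, m2)),
                clamped = m2 < 0)
}

#' Group-by-visit cell means of the uncertainty metric
#'
#' Averages regression RMSE first within participant-visit (so each
#' participant contributes one value per visit regardless of how many
#' blocks were summarised), then across participants within each group and
#' visit cell.
#'
#' @param summaries Output of [rmse_table()].
#' @return A tibble with `group`, `visit`, `n` (participants), `mean_rmse`,
#'   `sd_rmse` (across participants, cm).
#' @export
cell_means <- function(summaries) {
  check_trial_columns(summaries, c("participant_id", "group", "visit", "rmse"))
  summaries |>
    dplyr::group_by(.data$group, .data$visit, .data$participant_id) |>
    dplyr::summarise(rmse = mean(.data$rmse), .groups = "drop_last") |>
    dplyr::summarise(n = dplyr::n(), mean_rmse = mean(.data$rmse),
                     sd_rmse = stats::sd(.data$rmse), .groups = "drop")
}

check_trial_columns <- function(df, cols) {
  if (!is.data.frame(df)) {
    rlang::abort("Expected a data frame.", class = "stepsense_schema_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("Missing required column(s): %s.",
                         paste(missing, collapse = ", ")),
                 class = "stepsense_schema_error")
  }
  invisible(df)
}
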