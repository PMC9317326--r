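test_that("a perfect linear relation is fit exactly with zero rmse", {
  fit <- fit_deviation_regression(line_trials(0.5, 3.75))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 3.75)
  expect_equal(fit$rmse, 0)
  expect_equal(fit$r_squared, 1)
})

test_that("constant deviations give a flat line with zero rmse", {
  trials <- tibble::tibble(shift = c(-9, -7, -5, -3), deviation = rep(2.2, 4))
  fit <- fit_deviation_regression(trials)
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, 2.2)
  expect_equal(fit$rmse, 0)
})

test_that("degenerate regression inputs raise typed errors", {
  expect_error(fit_deviation_regression(line_trials(shifts = c(-5, -4))),
               class = "stepsense_insufficient_data")
  expect_error(
    fit_deviation_regression(tibble::tibble(shift = rep(-7.5, 5),
                                            deviation = rnorm(5))),
    class = "stepsense_degenerate_design")
  expect_error(rmse_table(tibble::tibble(shift = 1)),
               class = "stepsense_schema_error")
})

test_that("rmse is unchanged by adding a constant to all deviations", {
  set.seed(41)
  trials <- tibble::tibble(shift = sample_shifts(200))
  trials$deviation <- 0.4 * trials$shift + rnorm(200, 0, 1.5)
  f1 <- fit_deviation_regression(trials)
  trials$deviation <- trials$deviation + 10
  f2 <- fit_deviation_regression(trials)
  expect_equal(f2$rmse, f1$rmse)
  expect_equal(f2$slope, f1$slope)
  expect_equal(f2$intercept, f1$intercept + 10)
})

test_that("the rmse denominator is n, not n - 2", {
  set.seed(42)
  trials <- tibble::tibble(shift = sample_shifts(50))
  trials$deviation <- 0.5 * trials$shift + rnorm(50)
  fit <- lm(deviation ~ shift, data = trials)
  sse <- sum(residuals(fit)^2)
  expect_equal(fit_deviation_regression(trials)$rmse, sqrt(sse / 50))
})

test_that("rmse_table yields one summary per analysis unit", {
  tr <- simulate_cohort(tiny_design(seed = 14))
  per_block <- rmse_table(tr, per_block = TRUE)
  per_visit <- rmse_table(tr, per_block = FALSE)
  expect_equal(nrow(per_block), 3 * 2 * 2 * 2) # groups x subj x visits x blocks
  expect_equal(nrow(per_visit), 3 * 2 * 2)
  expect_true(all(per_block$n_trials == 25))
  expect_true(all(per_visit$n_trials == 50))
  expect_true(all(per_block$rmse >= 0))
})

test_that("training trials are excluded from the summaries", {
  tr <- simulate_cohort(tiny_design(seed = 15))
  tr0 <- tr[tr$block == 1, ]
  tr0$block <- 0L # relabel as a training block
  tr0$deviation <- tr0$deviation + 100
  both <- rbind(tr, tr0)
  expect_equal(as.data.frame(rmse_table(both)), as.data.frame(rmse_table(tr)))
})

test_that("the slope estimator is unbiased at the design's trial counts", {
  obs <- observer_params(sigma_visual = 2.5, sigma_motor = 2.365)
  w <- prior_weight(2.5, 2.5)
  set.seed(16)
  slopes <- replicate(200, {
    shifts <- sample_shifts(500)
    trials <- tibble::tibble(shift = shifts,
                             deviation = simulate_deviation(obs, shifts))
    fit_deviation_regression(trials)$slope
  })
  expect_lt(abs(mean(slopes) - w), 0.01)
})

test_that("larger motor noise yields stochastically larger rmse", {
  set.seed(17)
  wins <- vapply(1:20, function(i) {
    shifts <- sample_shifts(300)
    lo <- observer_params(sigma_visual = 2, sigma_motor = 1)
    hi <- observer_params(sigma_visual = 2, sigma_motor = 2.5)
    r_lo <- fit_deviation_regression(
      tibble::tibble(shift = shifts, deviation = simulate_deviation(lo, shifts)))$rmse
    r_hi <- fit_deviation_regression(
      tibble::tibble(shift = shifts, deviation = simulate_deviation(hi, shifts)))$rmse
    r_hi > r_lo
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("noise recovery inverts the observer algebra", {
  r <- recover_sensory_noise(tibble::tibble(slope = 0.5, rmse = 2.0))
  expect_equal(r$sigma_visual_hat, 2.5) # equal variances at slope one-half
  expect_equal(r$sigma_motor_hat, sqrt(4 - 1.5625))
  expect_false(r$clamped)
})

test_that("noise recovery clamps when rmse falls below the visual floor", {
  r <- recover_sensory_noise(tibble::tibble(slope = 0.5, rmse = 1.0))
  expect_equal(r$sigma_motor_hat, 0)
  expect_true(r$clamped)
})

test_that("noise recovery refuses slopes outside the invertible range", {
  expect_error(recover_sensory_noise(tibble::tibble(slope = 1.1, rmse = 2)),
               class = "stepsense_noninvertible")
  expect_error(recover_sensory_noise(tibble::tibble(slope = 0, rmse = 2)),
               class = "stepsense_noninvertible")
})

test_that("cell means average participants, not blocks", {
  # participant A has 4 block summaries, B has 1; equal weight per participant
  s <- tibble::tibble(
    participant_id = c(rep("A", 4), "B"),
    group = "NN", visit = 1,
    rmse = c(2, 2, 2, 2, 4))
  cm <- cell_means(s)
  expect_equal(cm$mean_rmse, 3)
  expect_equal(cm$n, 2)
})
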