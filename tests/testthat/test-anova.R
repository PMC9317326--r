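test_that("the mixed model reproduces the classical balanced RM-ANOVA", {
  # 2 groups x 4 participants x 2 visits, one observation per
  # participant-visit, constructed with clear subject and visit structure
  set.seed(61)
  dat <- tidyr::crossing(
    tibble::tibble(participant_id = sprintf("S%02d", 1:8),
                   group = rep(c("NN", "NT"), each = 4),
                   subj_eff = rnorm(8, 0, 0.8)),
    visit = 1:2
  ) |>
    dplyr::mutate(rmse = 2.5 + 0.5 * (group == "NT") - 0.3 * (visit == 2) +
                    0.2 * (group == "NT") * (visit == 2) +
                    subj_eff + rnorm(dplyr::n(), 0, 0.15))
  oracle <- classical_rm_anova(dat)
  fit <- fit_rm_anova(dat)
  tab <- tidy(fit)
  expect_equal(tab$f_value[tab$effect == "group"], oracle$f_group,
               tolerance = 1e-6)
  expect_equal(tab$f_value[tab$effect == "visit"], oracle$f_visit,
               tolerance = 1e-6)
  expect_equal(tab$f_value[tab$effect == "group:visit"], oracle$f_int,
               tolerance = 1e-6)
  # Satterthwaite denominator df recover the classical ones
  expect_equal(tab$df_den[tab$effect == "group"], oracle$df[["group"]],
               tolerance = 1e-4)
  expect_equal(tab$df_den[tab$effect == "visit"], oracle$df[["within"]],
               tolerance = 1e-4)
})

test_that("missing cells are reported as a fit error", {
  dat <- tibble::tibble(participant_id = c("A", "A", "B", "B"),
                        group = c("NN", "NN", "NT", "NT"),
                        visit = c(1, 2, 1, 2), rmse = rnorm(4))
  dat2 <- dat[dat$group != "NT" | dat$visit != 2, ]
  expect_error(fit_rm_anova(dat2), class = "stepsense_fit_error")
})

test_that("tukey-adjusted p values equal the studentized-range evaluation", {
  set.seed(62)
  dat <- tidyr::crossing(
    tibble::tibble(participant_id = sprintf("S%02d", 1:15),
                   group = rep(c("NN", "NT", "TN"), each = 5),
                   subj_eff = rnorm(15, 0, 0.3)),
    visit = 1:2
  ) |>
    dplyr::mutate(rmse = 2.5 + 0.4 * (group == "NT") - 0.2 * (group == "TN") +
                    subj_eff + rnorm(dplyr::n(), 0, 0.2))
  fit <- fit_rm_anova(dat)
  tk <- tukey_pairwise(fit, "group")
  expect_equal(nrow(tk), 3)
  oracle_p <- 1 - ptukey(abs(tk$t_ratio) * sqrt(2), nmeans = 3, df = tk$df)
  expect_equal(tk$p_value, oracle_p, tolerance = 1e-8)
})

test_that("tukey adjustment never reports less than the unadjusted p", {
  set.seed(63)
  dat <- tidyr::crossing(
    tibble::tibble(participant_id = sprintf("S%02d", 1:12),
                   group = rep(c("NN", "NT", "TN"), each = 4),
                   subj_eff = rnorm(12, 0, 0.3)),
    visit = 1:2
  ) |>
    dplyr::mutate(rmse = 2.5 + subj_eff + rnorm(dplyr::n(), 0, 0.3))
  fit <- fit_rm_anova(dat)
  tk <- tukey_pairwise(fit, "group")
  unadj <- 2 * pt(-abs(tk$t_ratio), tk$df)
  expect_true(all(tk$p_value >= unadj - 1e-12))
})

test_that("extreme group separation is flagged as significant", {
  set.seed(64)
  dat <- tidyr::crossing(
    tibble::tibble(participant_id = sprintf("S%02d", 1:20),
                   group = rep(c("NN", "NT"), each = 10),
                   subj_eff = rnorm(20, 0, 0.05)),
    visit = 1:2
  ) |>
    dplyr::mutate(rmse = 2 + 10 * 0.1 * (group == "NT") +
                    subj_eff + rnorm(dplyr::n(), 0, 0.1))
  tk <- tukey_pairwise(fit_rm_anova(dat), "group")
  expect_lt(tk$p_value[1], 0.001)
})

test_that("cohens d uses the pooled-cell definition", {
  expect_equal(cohens_d(2, 1, 2, 1), 0)
  expect_equal(cohens_d(2, 1, 1, 1), 1)
  # printed visit-1 vs visit-2 cells of the stimulated-second-visit group
  expect_equal(cohens_d(2.78, 0.57, 2.24, 0.47), 0.54 / sqrt((0.57^2 + 0.47^2) / 2))
  expect_error(cohens_d(2, 0, 1, 0), class = "stepsense_undefined_effect")
  expect_error(cohens_d(2, -1, 1, 1), class = "stepsense_invalid_parameter")
})

test_that("the balance model matches the classical two-by-four decomposition", {
  set.seed(65)
  dat <- tidyr::crossing(
    tibble::tibble(participant_id = sprintf("S%02d", 1:10),
                   tens = rep(c(FALSE, TRUE), each = 5),
                   subj_eff = rnorm(10, 0, 0.2)),
    condition = 1:4
  ) |>
    dplyr::mutate(mean_vtc = 1.4 - 0.15 * (condition - 1) +
                    0.05 * tens + subj_eff + rnorm(dplyr::n(), 0, 0.08))
  fit <- balance_anova(dat)
  # reuse the two-factor oracle with renamed columns
  oracle <- classical_rm_anova(
    dplyr::transmute(dat, participant_id, group = tens, visit = condition,
                     rmse = mean_vtc))
  tab <- tidy(fit)
  expect_equal(tab$f_value[tab$effect == "tens"], oracle$f_group,
               tolerance = 1e-6)
  expect_equal(tab$f_value[tab$effect == "condition"], oracle$f_visit,
               tolerance = 1e-6)
  expect_equal(tab$f_value[tab$effect == "tens:condition"], oracle$f_int,
               tolerance = 1e-6)
})

test_that("a condition-only effect is detected as such in most replicates", {
  set.seed(66)
  hits <- vapply(1:10, function(i) {
    dat <- tidyr::crossing(
      tibble::tibble(participant_id = sprintf("S%02d", 1:12),
                     tens = rep(c(FALSE, TRUE), each = 6),
                     subj_eff = rnorm(12, 0, 0.1)),
      condition = 1:4
    ) |>
      dplyr::mutate(mean_vtc = 1.3 - 0.12 * (condition - 1) +
                      subj_eff + rnorm(dplyr::n(), 0, 0.08))
    tab <- tidy(balance_anova(dat))
    c(cond = tab$p_value[tab$effect == "condition"] < 0.05,
      tens = tab$p_value[tab$effect == "tens"] < 0.05)
  }, logical(2))
  expect_gte(sum(hits["cond", ]), 9)
  expect_lte(sum(hits["tens", ]), 3)
})

test_that("missing sensory conditions are a fit error", {
  dat <- tidyr::crossing(
    tibble::tibble(participant_id = c("A", "B"), tens = c(FALSE, TRUE)),
    condition = 1:3
  ) |> dplyr::mutate(mean_vtc = rnorm(6))
  expect_error(balance_anova(dat), class = "stepsense_fit_error")
})

test_that("glance reports the fitted variance components", {
  tr <- simulate_cohort(tiny_design(seed = 67))
  fit <- fit_rm_anova(rmse_table(tr))
  g <- glance(fit)
  expect_equal(g$n_obs, 24)
  expect_equal(g$n_participants, 6)
  expect_true(g$sd_residual > 0)
})
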