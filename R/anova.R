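#' Group-by-visit repeated-measures ANOVA via a linear mixed model
#'
#' Fits `rmse ~ group * visit + (1 | participant_id)`: a three-group by
#' two-visit repeated-measures analysis in which the participant random
#' intercept accounts for each participant contributing several
#' observations (one per visit, or one per block and visit). F tests are
#' Type III with Satterthwaite denominator degrees of freedom.
#'
#' @param summaries A long-format tibble with columns `participant_id`,
#'   `group`, `visit`, `rmse` (e.g. from [rmse_table()]).
#' @param response Name of the response column, default `"rmse"`.
#' @param check_balance Error on missing group-by-visit cells (default
#'   `TRUE`).
#' @return An object of class `rm_anova`: a list with the `lmerMod` fit
#'   (`model`), the ANOVA table as a tibble (`anova`), and the factor names.
#' @seealso [tukey_pairwise()], [tens_contrast_visit1()],
#'   [tens_contrast_crossover()]
#' @export
fit_rm_anova <- function(summaries, response = "rmse", check_balance = TRUE) {
  check_trial_columns(summaries, c("participant_id", "group", "visit", response))
  dat <- dplyr::mutate(tibble::as_tibble(summaries),
                       group = factor(.data$group),
                       visit = factor(.data$visit),
                       participant_id = factor(.data$participant_id))
  if (check_balance) {
    cells <- dplyr::count(dat, .data$group, .data$visit, .drop = FALSE)
    if (any(cells$n == 0)) {
      rlang::abort(sprintf("Empty group-by-visit cell(s): %s.",
                           paste(sprintf("%s/visit %s", cells$group[cells$n == 0],
                                         cells$visit[cells$n == 0]),
                                 collapse = ", ")),
                   class = "stepsense_fit_error")
    }
    if (dplyr::n_distinct(dat$participant_id) < 2) {
      rlang::abort("Need at least 2 participants.", class = "stepsense_fit_error")
    }
  }
  fml <- stats::as.formula(
    sprintf("%s ~ group * visit + (1 | participant_id)", response))
  model <- suppress_singular(
    lmerTest::lmer(fml, data = dat,
                   contrasts = list(group = "contr.sum", visit = "contr.sum"))
  )
  new_rm_anova(model, factors = c("group", "visit"), response = response)
}

#' Stimulation-by-condition balance ANOVA via a linear mixed model
#'
#' Fits `mean_vtc ~ tens * condition + (1 | participant_id)`: the two
#' (stimulation on/off) by four (sensory condition) repeated-measures
#' analysis of the balance assessment, with Type III Satterthwaite F tests.
#'
#' @param vtc_table A tibble with columns `participant_id`, `tens`
#'   (logical or factor), `condition` (1-4), and the response column.
#' @param response Name of the response column, default `"mean_vtc"`.
#' @return An `rm_anova` object (see [fit_rm_anova()]).
#' @export
balance_anova <- function(vtc_table, response = "mean_vtc") {
  check_trial_columns(vtc_table, c("participant_id", "tens", "condition", response))
  dat <- dplyr::mutate(tibble::as_tibble(vtc_table),
                       tens = factor(.data$tens),
                       condition = factor(.data$condition),
                       participant_id = factor(.data$participant_id))
  cond_per_subj <- dplyr::summarise(
    dplyr::group_by(dat, .data$participant_id),
    k = dplyr::n_distinct(.data$condition), .groups = "drop")
  if (any(cond_per_subj$k < 4)) {
    rlang::abort("Every participant needs all 4 sensory conditions.",
                 class = "stepsense_fit_error")
  }
  fml <- stats::as.formula(
    sprintf("%s ~ tens * condition + (1 | participant_id)", response))
  model <- suppress_singular(
    lmerTest::lmer(fml, data = dat,
                   contrasts = list(tens = "contr.sum", condition = "contr.sum"))
  )
  new_rm_anova(model, factors = c("tens", "condition"), response = response)
}

new_rm_anova <- function(model, factors, response) {
  at <- suppressMessages(stats::anova(model, type = 3, ddf = "Satterthwaite"))
  tab <- tibble::tibble(
    effect = rownames(at),
    f_value = at$`F value`,
    df_num = at$NumDF,
    df_den = at$DenDF,
    p_value = at$`Pr(>F)`
  )
  structure(list(model = model, anova = tab, factors = factors,
                 response = response),
            class = "rm_anova")
}

suppress_singular <- function(expr) {
  withCallingHandlers(
    suppressMessages(expr),
    warning = function(w) {
      if (grepl("singular|converge", conditionMessage(w), ignore.case = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> %s ~ %s with participant random intercept\n",
              x$response, paste(x$factors, collapse = " * ")))
  cat("Type III F tests (Satterthwaite df):\n")
  print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rm_anova <- function(x, ...) x$anova

#' @export
glance.rm_anova <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  tibble::tibble(
    n_obs = stats::nobs(x$model),
    n_participants = lme4::ngrps(x$model)[["participant_id"]],
    sd_participant = vc$sdcor[vc$grp == "participant_id"][1],
    sd_residual = vc$sdcor[vc$grp == "Residual"][1],
    logLik = as.numeric(stats::logLik(x$model))
  )
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' All pairwise differences of estimated marginal means for a factor (or
#' factor combination) of a fitted [fit_rm_anova()] / [balance_anova()]
#' model, with p values adjusted by the studentized-range (Tukey HSD)
#' method.
#'
#' @param fit An `rm_anova` object.
#' @param factors Character vector of factor names to compare over; default
#'   is all crossed factors of the model.
#' @return A tibble with `contrast`, `estimate`, `se`, `df`, `t_ratio`,
#'   `p_value` (Tukey-adjusted).
#' @export
tukey_pairwise <- function(fit, factors = NULL) {
  stopifnot(inherits(fit, "rm_anova"))
  factors <- factors %||% fit$factors
  if (!all(factors %in% fit$factors)) {
    rlang::abort(sprintf("Unknown factor(s): %s.",
                         paste(setdiff(factors, fit$factors), collapse = ", ")),
                 class = "stepsense_input_error")
  }
  spec <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  emm <- emmeans::emmeans(fit$model, spec)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  tibble::tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    t_ratio = prs$t.ratio,
    p_value = prs$p.value
  )
}

#' Cohen's d between two cells
#'
#' Standardised mean difference using the pooled-SD (independent-cells)
#' definition `d = (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`. Note that
#' repeated-measures designs admit alternative standardisers (e.g. the SD
#' of within-participant change), which give larger values when visits are
#' positively correlated; this function implements the plain between-cell
#' form.
#'
#' @param mean1,sd1 Mean and SD of the first cell (cm).
#' @param mean2,sd2 Mean and SD of the second cell (cm).
#' @return The effect size `d` (dimensionless).
#' @export
#' @examples
#' cohens_d(2.0, 1.0, 1.0, 1.0) # 1
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (any(c(sd1, sd2) < 0)) {
    rlang::abort("SDs must be >= 0.", class = "stepsense_invalid_parameter")
  }
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (any(pooled == 0 & mean1 != mean2)) {
    rlang::abort("Zero pooled SD with unequal means: d is undefined.",
                 class = "stepsense_undefined_effect")
  }
  ifelse(pooled == 0, 0, (mean1 - mean2) / pooled)
}
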