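#' Visit-1 stimulation contrast
#'
#' Estimates the stimulation effect using visit 1 alone, where two groups
#' (NT, NN) stepped without stimulation and one (TN) with it: the average
#' of the two non-stimulated visit-1 cell means minus the stimulated
#' visit-1 cell mean,
#' `(mean_NT1 + mean_NN1) / 2 - mean_TN1`. Positive values mean the
#' stimulated group showed *less* uncertainty.
#'
#' When a fitted [fit_rm_anova()] model is supplied, the standard error,
#' Wald 95% confidence interval and p value come from the model's estimated
#' marginal means (unadjusted for multiplicity — this is a single planned
#' contrast); with cell means alone only the point estimate is returned.
#'
#' @param cells Either a [cell_means()] tibble (columns `group`, `visit`,
#'   `mean_rmse`) or a named numeric vector with elements `nt1`, `nn1`,
#'   `tn1`.
#' @param fit Optional `rm_anova` model for inference.
#' @return A one-row tibble with `label`, `estimate` (cm) and, with a
#'   model, `se`, `ci_low`, `ci_high`, `p_value`.
#' @export
#' @examples
#' tens_contrast_visit1(c(nt1 = 2.78, nn1 = 2.57, tn1 = 2.43)) # 0.245 cm
tens_contrast_visit1 <- function(cells, fit = NULL) {
  m <- contrast_cells(cells, c("nt1", "nn1", "tn1"))
  est <- (m[["nt1"]] + m[["nn1"]]) / 2 - m[["tn1"]]
  finish_contrast("visit-1 stimulation effect", est, fit,
                  weights = c(nn1 = 0.5, nt1 = 0.5, tn1 = -1))
}

#' Across-visit stimulation contrast (difference in differences)
#'
#' Isolates the stimulation effect from the practice effect by comparing
#' the visit-1-to-visit-2 improvement of the group stimulated on visit 2
#' (NT) against the improvement of the never-stimulated group (NN):
#' `(mean_NT1 - mean_NT2) - (mean_NN1 - mean_NN2)`. The NN change estimates
#' the pure practice effect; the NT change estimates practice plus
#' stimulation; their difference is the stimulation effect. Positive values
#' mean stimulation reduced uncertainty beyond practice alone.
#'
#' Inference (with a model) is unadjusted for multiple comparisons, as a
#' single planned contrast.
#'
#' @param cells Either a [cell_means()] tibble or a named numeric vector
#'   with elements `nt1`, `nt2`, `nn1`, `nn2`.
#' @param fit Optional `rm_anova` model for inference.
#' @return A one-row tibble as in [tens_contrast_visit1()].
#' @export
#' @examples
#' tens_contrast_crossover(c(nt1 = 2.78, nt2 = 2.24, nn1 = 2.57, nn2 = 2.40))
tens_contrast_crossover <- function(cells, fit = NULL) {
  m <- contrast_cells(cells, c("nt1", "nt2", "nn1", "nn2"))
  est <- (m[["nt1"]] - m[["nt2"]]) - (m[["nn1"]] - m[["nn2"]])
  finish_contrast("across-visit stimulation effect", est, fit,
                  weights = c(nt1 = 1, nt2 = -1, nn1 = -1, nn2 = 1))
}

# normalise cell-mean input to the named vector c(nn1 = ..., nt2 = ..., ...)
contrast_cells <- function(cells, needed) {
  if (is.data.frame(cells)) {
    check_trial_columns(cells, c("group", "visit", "mean_rmse"))
    m <- stats::setNames(cells$mean_rmse,
                         paste0(tolower(cells$group), cells$visit))
  } else if (is.numeric(cells) && !is.null(names(cells))) {
    m <- stats::setNames(cells, tolower(names(cells)))
  } else {
    rlang::abort("`cells` must be a cell-means tibble or a named numeric vector.",
                 class = "stepsense_input_error")
  }
  missing <- setdiff(needed, names(m))
  if (length(missing)) {
    rlang::abort(sprintf("Missing cell mean(s): %s.", paste(missing, collapse = ", ")),
                 class = "stepsense_input_error")
  }
  m
}

finish_contrast <- function(label, est, fit, weights) {
  out <- tibble::tibble(label = label, estimate = unname(est))
  if (is.null(fit)) return(out)
  stopifnot(inherits(fit, "rm_anova"))
  emm <- emmeans::emmeans(fit$model, ~ group * visit)
  grid <- as.data.frame(emm)
  key <- paste0(tolower(as.character(grid$group)), as.character(grid$visit))
  wvec <- stats::setNames(rep(0, nrow(grid)), key)
  wvec[names(weights)] <- weights
  ctr <- emmeans::contrast(emm, method = list(custom = unname(wvec)), adjust = "none")
  s <- summary(ctr, infer = c(TRUE, TRUE), level = 0.95)
  dplyr::mutate(out,
                se = s$SE, ci_low = s$lower.CL, ci_high = s$upper.CL,
                df = s$df, p_value = s$p.value,
                model_estimate = s$estimate)
}
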