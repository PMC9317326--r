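#' Bayesian ideal-observer parameters for the shifted-cursor stepping task
#'
#' Bundles the generative and believed prior over the imposed cursor shift
#' together with the observer's sensory and execution noise. On each trial a
#' backward radial shift is drawn from the generative prior
#' `N(mu_prior, sigma_prior^2)`; the observer sees the shifted cursor only
#' briefly and corrupted by visual noise, combines that likelihood with its
#' learned prior by posterior-mean (quadratic-loss) estimation, and steps to
#' compensate. A well-calibrated observer (`mu_belief == mu_prior`,
#' `sigma_belief == sigma_prior`, the default) has closed-form regression
#' predictions given by [expected_regression()].
#'
#' @param mu_prior Mean of the imposed shift distribution (cm; negative =
#'   backward). Default -7.5.
#' @param sigma_prior SD of the imposed shift distribution (cm, > 0).
#'   Default 2.5.
#' @param sigma_visual SD of the noise on the mid-movement visual feedback
#'   (cm, >= 0).
#' @param sigma_motor SD of execution noise added to the final radial
#'   deviation (cm, >= 0).
#' @param mu_belief Observer's learned prior mean (cm). Defaults to
#'   `mu_prior` (converged learning).
#' @param sigma_belief Observer's learned prior SD (cm, > 0). Defaults to
#'   `sigma_prior`.
#'
#' @return An object of class `observer_params` (a named list).
#' @seealso [prior_weight()], [simulate_deviation()], [expected_regression()]
#' @export
#' @examples
#' obs <- observer_params(sigma_visual = 2.5, sigma_motor = 0)
#' expected_regression(obs)
observer_params <- function(mu_prior = -7.5, sigma_prior = 2.5,
                            sigma_visual = 2.5, sigma_motor = 2.365,
                            mu_belief = mu_prior, sigma_belief = sigma_prior) {
  for (nm in c("mu_prior", "sigma_prior", "sigma_visual", "sigma_motor",
               "mu_belief", "sigma_belief")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort(sprintf("`%s` must be a single finite number.", nm),
                   class = "stepsense_invalid_parameter")
    }
  }
  if (sigma_prior <= 0 || sigma_belief <= 0) {
    rlang::abort("`sigma_prior` and `sigma_belief` must be > 0.",
                 class = "stepsense_invalid_parameter")
  }
  if (sigma_visual < 0 || sigma_motor < 0) {
    rlang::abort("`sigma_visual` and `sigma_motor` must be >= 0.",
                 class = "stepsense_invalid_parameter")
  }
  structure(
    list(mu_prior = mu_prior, sigma_prior = sigma_prior,
         mu_belief = mu_belief, sigma_belief = sigma_belief,
         sigma_visual = sigma_visual, sigma_motor = sigma_motor),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  shift prior   : N(%g, %g^2) cm\n", x$mu_prior, x$sigma_prior))
  cat(sprintf("  believed prior: N(%g, %g^2) cm%s\n", x$mu_belief, x$sigma_belief,
              if (x$mu_belief == x$mu_prior && x$sigma_belief == x$sigma_prior)
                " [well-calibrated]" else ""))
  cat(sprintf("  sigma_visual  : %g cm\n", x$sigma_visual))
  cat(sprintf("  sigma_motor   : %g cm\n", x$sigma_motor))
  w <- prior_weight(x$sigma_visual, x$sigma_belief)
  cat(sprintf("  prior weight w: %.4f\n", w))
  invisible(x)
}

#' Weight the observer places on its learned prior
#'
#' Under Gaussian cue combination the posterior mean of the shift given the
#' noisy visual feedback is a precision-weighted average of the feedback and
#' the believed prior mean. The prior receives weight
#' `w = sigma_visual^2 / (sigma_visual^2 + sigma_belief^2)`, which is also
#' the expected slope of the deviation-on-shift regression for a
#' well-calibrated observer: noiseless vision (`sigma_visual = 0`) gives
#' `w = 0` and full compensation; uninformative vision gives `w -> 1` and a
#' response driven entirely by expectation.
#'
#' @param sigma_visual SD of visual feedback noise (cm, >= 0). Vectorised.
#' @param sigma_belief Believed prior SD (cm, > 0). Vectorised.
#' @return Prior weight(s) in `[0, 1]`.
#' @export
#' @examples
#' prior_weight(2.5, 2.5) # 0.5: equally reliable cue and prior
#' prior_weight(0, 2.5)   # 0:   perfect vision ignores the prior
prior_weight <- function(sigma_visual, sigma_belief) {
  if (any(!is.finite(sigma_belief)) || any(sigma_belief <= 0)) {
    rlang::abort("`sigma_belief` must be > 0.",
                 class = "stepsense_invalid_parameter")
  }
  if (any(!is.finite(sigma_visual)) || any(sigma_visual < 0)) {
    rlang::abort("`sigma_visual` must be >= 0.",
                 class = "stepsense_invalid_parameter")
  }
  sigma_visual^2 / (sigma_visual^2 + sigma_belief^2)
}

#' Simulate radial response deviations for given cursor shifts
#'
#' Draws one trial outcome per element of `shift`. The observer receives
#' visual feedback `shift + e_v` with `e_v ~ N(0, sigma_visual^2)`, forms the
#' posterior-mean shift estimate
#' `s_hat = w * mu_belief + (1 - w) * (shift + e_v)` with
#' `w = prior_weight(sigma_visual, sigma_belief)`, compensates by stepping
#' `-s_hat` beyond the target, and lands with execution noise
#' `e_m ~ N(0, sigma_motor^2)`. The recorded radial deviation of the final
#' cursor position from the target is therefore
#' `shift - s_hat + e_m = w * (shift - mu_belief) - (1 - w) * e_v + e_m`.
#'
#' Uses R's global random-number stream; call [set.seed()] for
#' reproducibility.
#'
#' @param observer An [observer_params()] object.
#' @param shift Numeric vector of imposed shifts (cm, signed; negative =
#'   backward).
#' @return Numeric vector of deviations (cm), same length as `shift`.
#' @export
#' @examples
#' obs <- observer_params(sigma_visual = 0, sigma_motor = 0)
#' simulate_deviation(obs, c(-5, -7.5, -10)) # all zero: perfect compensation
simulate_deviation <- function(observer, shift) {
  stopifnot(inherits(observer, "observer_params"))
  if (!is.numeric(shift) || any(!is.finite(shift))) {
    rlang::abort("`shift` must be finite numeric.",
                 class = "stepsense_invalid_parameter")
  }
  n <- length(shift)
  w <- prior_weight(observer$sigma_visual, observer$sigma_belief)
  e_v <- if (observer$sigma_visual > 0) stats::rnorm(n, 0, observer$sigma_visual) else numeric(n)
  e_m <- if (observer$sigma_motor > 0) stats::rnorm(n, 0, observer$sigma_motor) else numeric(n)
  w * (shift - observer$mu_belief) - (1 - w) * e_v + e_m
}

#' Closed-form regression predictions for an observer
#'
#' Population values of the per-visit deviation-on-shift regression implied
#' by the generative model: slope `w`, intercept `-w * mu_belief`, and
#' residual root-mean-square
#' `rmse = sqrt((1 - w)^2 * sigma_visual^2 + sigma_motor^2)`. These hold for
#' any believed prior (the belief enters only the intercept); for a
#' well-calibrated observer they are exactly what the empirical regression
#' of [fit_deviation_regression()] recovers in expectation.
#'
#' With `sigma_motor = 0` the residual reduces to
#' `sigma_visual * sigma_prior^2 / (sigma_visual^2 + sigma_prior^2)`, which
#' is at most `sigma_prior / 2` (attained at `sigma_visual == sigma_prior`):
#' visual noise alone cannot produce arbitrarily large regression RMSE.
#'
#' @param observer An [observer_params()] object.
#' @return A one-row tibble with columns `slope`, `intercept`, `rmse`.
#' @export
#' @examples
#' expected_regression(observer_params(sigma_visual = 2.5, sigma_motor = 0))
expected_regression <- function(observer) {
  stopifnot(inherits(observer, "observer_params"))
  w <- prior_weight(observer$sigma_visual, observer$sigma_belief)
  tibble::tibble(
    slope = w,
    intercept = -w * observer$mu_belief,
    rmse = sqrt((1 - w)^2 * observer$sigma_visual^2 + observer$sigma_motor^2)
  )
}
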