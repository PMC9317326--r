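#' Crossover cohort design for the stepping protocol
#'
#' Describes the simulated study: three groups of `n_per_group` participants
#' (NN: never stimulated; NT: stimulated on visit 2 only; TN: stimulated on
#' visit 1 only), each completing `n_blocks` assessment blocks of
#' `trials_per_block` stepping trials on each of two visits. Imposed cursor
#' shifts are drawn from `N(shift_mu, shift_sigma^2)`.
#'
#' Participant-level noise parameters are drawn once per participant from
#' lognormal distributions whose mean and SD (on the cm scale) are the
#' baselines and the `between_sd_*` values. Three condition effects then
#' reduce noise additively: `tens_effect` whenever stimulation is on,
#' `visit_effect` on every second visit (practice), and `retention_effect`
#' as an extra second-visit reduction for the TN group only (the carried-over
#' benefit of having learned the task under stimulation). `effect_target`
#' chooses which noise source the reductions act on; the calibrated defaults
#' reduce both. Reductions are clamped so participant-level SDs stay
#' non-negative (with a warning).
#'
#' The defaults are calibrated so that the expected group-by-visit mean
#' regression RMSEs are, in cm: no-stimulation visit 1 cells 2.68,
#' stimulated visit 1 cell 2.41, NN visit 2 cell 2.41, stimulated visit 2
#' cell 2.14, and TN visit 2 cell 2.04.
#'
#' @param n_per_group Participants per group (default 10).
#' @param n_blocks Assessment blocks per visit (default 5).
#' @param trials_per_block Trials per block (default 100).
#' @param shift_mu,shift_sigma Imposed shift distribution (cm), defaults
#'   -7.5 and 2.5.
#' @param sigma_visual,sigma_motor Baseline noise SDs (cm).
#' @param tens_effect Reduction (cm) applied while stimulation is on.
#' @param visit_effect Reduction (cm) applied on visit 2 (practice).
#' @param retention_effect Extra visit-2 reduction (cm) for the TN group.
#' @param effect_target Which noise SD the reductions act on: `"both"`
#'   (default), `"visual"`, or `"motor"`.
#' @param between_sd_visual,between_sd_motor Between-participant SDs (cm) of
#'   the baseline noise parameters.
#' @param seed Integer seed making the cohort a pure function of the design.
#'
#' @return An object of class `cohort_design` (a named list).
#' @seealso [simulate_cohort()], [sample_shifts()]
#' @export
cohort_design <- function(n_per_group = 10, n_blocks = 5, trials_per_block = 100,
                          shift_mu = -7.5, shift_sigma = 2.5,
                          sigma_visual = 2.5, sigma_motor = 2.365,
                          tens_effect = 0.3, visit_effect = 0.3,
                          retention_effect = 0.4,
                          effect_target = c("both", "visual", "motor"),
                          between_sd_visual = 0.4, between_sd_motor = 0.4,
                          seed = 1L) {
  effect_target <- match.arg(effect_target)
  if (n_per_group < 1 || n_blocks < 1 || trials_per_block < 1) {
    rlang::abort("Counts must be >= 1.", class = "stepsense_invalid_parameter")
  }
  if (shift_sigma <= 0) {
    rlang::abort("`shift_sigma` must be > 0.", class = "stepsense_invalid_parameter")
  }
  if (sigma_visual < 0 || sigma_motor < 0 ||
      between_sd_visual < 0 || between_sd_motor < 0) {
    rlang::abort("Noise SDs must be >= 0.", class = "stepsense_invalid_parameter")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), groups = c("NN", "NT", "TN"),
         n_visits = 2L, n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         shift_mu = shift_mu, shift_sigma = shift_sigma,
         sigma_visual = sigma_visual, sigma_motor = sigma_motor,
         tens_effect = tens_effect, visit_effect = visit_effect,
         retention_effect = retention_effect, effect_target = effect_target,
         between_sd_visual = between_sd_visual,
         between_sd_motor = between_sd_motor,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>\n")
  cat(sprintf("  %d groups (%s) x %d participants x %d visits x %d blocks x %d trials = %d rows\n",
              length(x$groups), paste(x$groups, collapse = "/"), x$n_per_group,
              x$n_visits, x$n_blocks, x$trials_per_block,
              length(x$groups) * x$n_per_group * x$n_visits * x$n_blocks *
                x$trials_per_block))
  cat(sprintf("  shifts ~ N(%g, %g^2) cm; baseline sigma_visual %g, sigma_motor %g\n",
              x$shift_mu, x$shift_sigma, x$sigma_visual, x$sigma_motor))
  cat(sprintf("  effects on %s: TENS %g, visit %g, retention %g cm; seed %d\n",
              x$effect_target, x$tens_effect, x$visit_effect,
              x$retention_effect, x$seed))
  invisible(x)
}

#' Draw imposed cursor shifts
#'
#' i.i.d. draws from the trial-shift distribution `N(mu, sigma^2)`. Uses the
#' global random-number stream.
#'
#' @param n Number of draws (>= 1).
#' @param mu Mean shift (cm), default -7.5.
#' @param sigma Shift SD (cm, > 0), default 2.5.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' set.seed(1)
#' summary(sample_shifts(1000))
sample_shifts <- function(n, mu = -7.5, sigma = 2.5) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    rlang::abort("`n` must be >= 1.", class = "stepsense_invalid_parameter")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    rlang::abort("`sigma` must be > 0.", class = "stepsense_invalid_parameter")
  }
  stats::rnorm(n, mu, sigma)
}

# lognormal with given mean m > 0 and sd s on the natural scale;
# degenerate at m when s = 0
rlnorm_ms <- function(n, m, s) {
  if (s == 0 || m == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# stimulation schedule implied by group and visit
tens_on <- function(group, visit) {
  (group == "TN" & visit == 1L) | (group == "NT" & visit == 2L)
}

#' Simulate the full crossover trial table
#'
#' Generates one row per stepping trial of the whole cohort. Each
#' participant's baseline noise parameters are drawn once (lognormal around
#' the design baselines); on each visit the design's stimulation, practice
#' and retention reductions are applied (clamped at zero), shifts are drawn
#' from the shift distribution, and deviations come from
#' [simulate_deviation()]. Target directions cycle through the five step
#' directions; they are bookkeeping only and do not enter the generative
#' model.
#'
#' The result is a pure function of the design (including its seed); the
#' global RNG state is restored on exit.
#'
#' @param design A [cohort_design()].
#' @return A tibble with columns `participant_id`, `group`, `visit`,
#'   `block`, `trial`, `target_direction`, `shift`, `deviation`, `tens`.
#'   The per-participant-visit noise parameters actually used are attached
#'   as attribute `"participants"` (see [cohort_participants()]).
#' @export
#' @examples
#' trials <- simulate_cohort(cohort_design(n_per_group = 2, n_blocks = 1,
#'                                         trials_per_block = 20))
#' dplyr::count(trials, group, visit)
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(design$seed)

  n_subj <- length(design$groups) * design$n_per_group
  subj <- tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n_subj)),
    group = rep(design$groups, each = design$n_per_group),
    sigma_visual_0 = rlnorm_ms(n_subj, design$sigma_visual, design$between_sd_visual),
    sigma_motor_0 = rlnorm_ms(n_subj, design$sigma_motor, design$between_sd_motor)
  )

  pv <- tidyr::crossing(subj, visit = seq_len(design$n_visits)) |>
    dplyr::mutate(
      tens = tens_on(.data$group, .data$visit),
      reduction = design$tens_effect * .data$tens +
        design$visit_effect * (.data$visit == 2L) +
        design$retention_effect * (.data$group == "TN" & .data$visit == 2L),
      sigma_visual = .data$sigma_visual_0 -
        .data$reduction * (design$effect_target %in% c("both", "visual")),
      sigma_motor = .data$sigma_motor_0 -
        .data$reduction * (design$effect_target %in% c("both", "motor"))
    )
  if (any(pv$sigma_visual < 0) || any(pv$sigma_motor < 0)) {
    rlang::warn("Effect reductions drove a noise SD below zero; clamped at 0.")
    pv$sigma_visual <- pmax(pv$sigma_visual, 0)
    pv$sigma_motor <- pmax(pv$sigma_motor, 0)
  }

  n_trials <- design$n_blocks * design$trials_per_block
  trials <- pv |>
    dplyr::rowwise() |>
    dplyr::group_map(function(row, key) {
      obs <- observer_params(mu_prior = design$shift_mu,
                             sigma_prior = design$shift_sigma,
                             sigma_visual = row$sigma_visual,
                             sigma_motor = row$sigma_motor)
      shift <- sample_shifts(n_trials, design$shift_mu, design$shift_sigma)
      tibble::tibble(
        participant_id = row$participant_id,
        group = row$group,
        visit = row$visit,
        block = rep(seq_len(design$n_blocks), each = design$trials_per_block),
        trial = rep(seq_len(design$trials_per_block), design$n_blocks),
        target_direction = ((seq_len(n_trials) - 1L) %% 5L) + 1L,
        shift = shift,
        deviation = simulate_deviation(obs, shift),
        tens = row$tens
      )
    }) |>
    dplyr::bind_rows()

  attr(trials, "participants") <- pv |>
    dplyr::select("participant_id", "group", "visit", "tens",
                  "sigma_visual", "sigma_motor")
  trials
}

#' Per-participant-visit noise parameters of a simulated cohort
#'
#' Returns the effective `sigma_visual` and `sigma_motor` used for each
#' participant-visit of a [simulate_cohort()] table, for parameter-recovery
#' checks.
#'
#' @param trials A trial table produced by [simulate_cohort()].
#' @return A tibble with one row per participant-visit.
#' @export
cohort_participants <- function(trials) {
  p <- attr(trials, "participants")
  if (is.null(p)) {
    rlang::abort("No participant parameters attached; was this table produced by simulate_cohort()?",
                 class = "stepsense_input_error")
  }
  p
}
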