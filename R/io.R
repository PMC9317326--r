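#' Read and write trial tables
#'
#' Trial tables are plain CSV with a header row and at least the columns
#' `participant_id`, `group`, `visit`, `block`, `trial`, `shift`,
#' `deviation`; unknown columns are preserved. `read_trials()` validates
#' the schema and that `shift`/`deviation` parse as finite numbers.
#'
#' @param path File path.
#' @param trials A trial table tibble.
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_trial_columns(df, c("participant_id", "group", "visit", "block",
                            "trial", "shift", "deviation"))
  for (col in c("shift", "deviation")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- which(!is.numeric(v) | !is.finite(suppressWarnings(as.numeric(v))))
      rlang::abort(sprintf("Column `%s` has non-numeric or non-finite values (first bad row: %d).",
                           col, bad[1]),
                   class = "stepsense_parse_error")
    }
  }
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  check_trial_columns(trials, c("participant_id", "group", "visit", "block",
                                "trial", "shift", "deviation"))
  readr::write_csv(trials, path)
  invisible(path)
}

#' Read and write centre-of-pressure traces
#'
#' CoP traces are CSV files with columns `t` (s), `ap`, `ml` (cm) and a
#' comment line `# rate=<Hz>` above the header recording the sampling rate.
#' On read, the rate is parsed from that line when present and otherwise
#' inferred from the (required-uniform) timestamps.
#'
#' @param path File path.
#' @param trace A `cop_trace` tibble.
#' @return `read_cop()` returns a `cop_trace` tibble; `write_cop()` returns
#'   `path` invisibly.
#' @export
read_cop <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- NULL
  if (grepl("^#\\s*rate=", first)) {
    rate <- as.numeric(sub("^#\\s*rate=\\s*([0-9.eE+-]+).*", "\\1", first))
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  check_trial_columns(df, c("t", "ap", "ml"))
  dt <- diff(df$t)
  if (any(abs(dt - dt[1]) > 1e-9)) {
    rlang::abort("CoP timestamps are not uniformly spaced.",
                 class = "stepsense_parse_error")
  }
  if (is.null(rate) || !is.finite(rate)) rate <- 1 / dt[1]
  new_cop_trace(df, rate = rate)
}

#' @rdname read_cop
#' @export
write_cop <- function(trace, path) {
  check_trial_columns(trace, c("t", "ap", "ml"))
  rate <- cop_rate(trace)
  body <- readr::format_csv(tibble::as_tibble(trace)[c("t", "ap", "ml")])
  writeLines(c(sprintf("# rate=%g", rate), sub("\n$", "", body)), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default:
#' the cohort design, the uncertainty options (analysis unit), the VTC
#' options (filter cutoff, boundary semi-axes, projection horizon, cap
#' policy) and the seed. Round-trips losslessly through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param design A [cohort_design()].
#' @param per_block Analyse per block (default `TRUE`) or per visit.
#' @param cutoff Low-pass cutoff for CoP filtering (Hz).
#' @param a_ml,b_ap Base-of-support ellipse semi-axes (cm).
#' @param tau_max VTC projection horizon (s).
#' @param cap_policy `"include_capped"` or `"exclude_capped"`.
#' @param cop A [cop_params()] for the balance traces; its `bos` is rebuilt
#'   from `a_ml`/`b_ap`.
#' @param seed Master seed for the run.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(design = cohort_design(), per_block = TRUE,
                       cutoff = 10, a_ml = 5, b_ap = 12, tau_max = 10,
                       cap_policy = "include_capped",
                       cop = cop_params(bos = base_of_support(a_ml = a_ml, b_ap = b_ap)),
                       seed = 1L) {
  structure(list(design = design, per_block = per_block, cutoff = cutoff,
                 a_ml = a_ml, b_ap = b_ap, tau_max = tau_max,
                 cap_policy = cap_policy, cop = cop, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    design = unclass(config$design),
    per_block = config$per_block, cutoff = config$cutoff,
    a_ml = config$a_ml, b_ap = config$b_ap, tau_max = config$tau_max,
    cap_policy = config$cap_policy,
    cop = list(duration = config$cop$duration, rate = config$cop$rate,
               sway_scale = config$cop$sway_scale,
               smoothness = config$cop$smoothness,
               lp_cutoff = config$cop$lp_cutoff, seed = config$cop$seed),
    seed = config$seed
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  d <- x$design
  design <- cohort_design(
    n_per_group = d$n_per_group, n_blocks = d$n_blocks,
    trials_per_block = d$trials_per_block,
    shift_mu = d$shift_mu, shift_sigma = d$shift_sigma,
    sigma_visual = d$sigma_visual, sigma_motor = d$sigma_motor,
    tens_effect = d$tens_effect, visit_effect = d$visit_effect,
    retention_effect = d$retention_effect, effect_target = d$effect_target,
    between_sd_visual = d$between_sd_visual,
    between_sd_motor = d$between_sd_motor, seed = d$seed
  )
  bos <- base_of_support(a_ml = x$a_ml, b_ap = x$b_ap)
  run_config(design = design, per_block = x$per_block, cutoff = x$cutoff,
             a_ml = x$a_ml, b_ap = x$b_ap, tau_max = x$tau_max,
             cap_policy = x$cap_policy,
             cop = cop_params(duration = x$cop$duration, rate = x$cop$rate,
                              sway_scale = unlist(x$cop$sway_scale),
                              smoothness = x$cop$smoothness,
                              lp_cutoff = x$cop$lp_cutoff, bos = bos,
                              seed = x$cop$seed),
             seed = x$seed)
}

#' Run the full pipeline
#'
#' Simulates the crossover cohort, fits the per-unit deviation-on-shift
#' regressions, simulates and scores the balance traces (one trace per
#' participant and sensory condition on visit 1, where the NN and TN groups
#' differ only by stimulation), runs the group-by-visit and
#' stimulation-by-condition mixed-model analyses with Tukey follow-ups and
#' both planned stimulation contrasts, and (optionally) writes every table
#' plus a plain-text report and the resolved configuration to `out_dir`.
#' Deterministic given the config's seeds.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; `NULL` (default) skips writing.
#' @return A list with `trials`, `rmse`, `cells`, `anova`, `tukey`,
#'   `contrast_visit1`, `contrast_crossover`, `vtc`, `balance`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  trials <- with_stage("simulate-cohort", simulate_cohort(config$design))
  rmse <- with_stage("fit-uncertainty", rmse_table(trials, per_block = config$per_block))
  if (stats::sd(rmse$rmse) == 0) {
    rlang::warn("Degenerate uncertainty table: all regression RMSEs are identical; skipping inference.")
    cells <- cell_means(rmse)
    fit <- NULL; tk <- NULL
    c1 <- tens_contrast_visit1(cells)
    c2 <- tens_contrast_crossover(cells)
    bal <- NULL; vtab <- NULL
  } else {
    fit <- with_stage("analyze", fit_rm_anova(rmse))
    tk <- with_stage("analyze", tukey_pairwise(fit, "group"))
    cells <- cell_means(rmse)
    c1 <- with_stage("analyze", tens_contrast_visit1(cells, fit))
    c2 <- with_stage("analyze", tens_contrast_crossover(cells, fit))
    vtab <- with_stage("vtc", pipeline_vtc(config, cohort_participants(trials)))
    bal <- with_stage("analyze-balance", balance_anova(vtab))
  }
  out <- list(trials = trials, rmse = rmse, cells = cells,
              anova = fit, tukey = tk,
              contrast_visit1 = c1, contrast_crossover = c2,
              vtc = vtab, balance = bal, config = config)
  if (!is.null(out_dir)) write_report(out, out_dir)
  invisible(out)
}

# one balance trace per participant x condition on visit 1, NN vs TN
pipeline_vtc <- function(config, participants) {
  participants <- participants |>
    dplyr::filter(.data$visit == 1L, .data$group %in% c("NN", "TN"))
  bos <- base_of_support(a_ml = config$a_ml, b_ap = config$b_ap)
  purrr::pmap(
    list(participants$participant_id, participants$tens,
         seq_len(nrow(participants))),
    function(pid, tens, i) {
      purrr::map(1:4, function(cond) {
        tr <- simulate_cop(config$cop, cond,
                           seed = config$cop$seed + 17L * i + cond)
        dplyr::bind_cols(
          tibble::tibble(participant_id = pid, tens = tens, condition = cond),
          mean_vtc(vtc(tr, bos, cutoff = min(config$cutoff,
                                             config$cop$rate / 2 - 0.5),
                       tau_max = config$tau_max),
                   cap_policy = config$cap_policy)
        )
      }) |> dplyr::bind_rows()
    }
  ) |> dplyr::bind_rows()
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("Stage `%s` failed: %s", stage, conditionMessage(e)),
                 class = "stepsense_stage_error", parent = e)
  })
}

#' Write a results bundle to disk
#'
#' Writes the trial, regression-summary, cell-mean and balance tables as
#' CSV, the resolved configuration as YAML, and a plain-text analysis
#' summary (ANOVA tables, Tukey comparisons, planned contrasts) to
#' `out_dir`.
#'
#' @param results A bundle from [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(results$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(results$rmse, file.path(out_dir, "rmse.csv"))
  readr::write_csv(results$cells, file.path(out_dir, "cell_means.csv"))
  if (!is.null(results$vtc)) {
    readr::write_csv(results$vtc, file.path(out_dir, "vtc.csv"))
  }
  write_run_config(results$config, file.path(out_dir, "config.yaml"))
  lines <- c("stepsense pipeline report", strrep("=", 25), "")
  if (!is.null(results$anova)) {
    lines <- c(lines, "Group x visit mixed-model ANOVA (Type III, Satterthwaite):",
               utils::capture.output(print(as.data.frame(results$anova$anova),
                                           row.names = FALSE, digits = 4)), "")
  }
  if (!is.null(results$tukey)) {
    lines <- c(lines, "Tukey pairwise comparisons (group):",
               utils::capture.output(print(as.data.frame(results$tukey),
                                           row.names = FALSE, digits = 4)), "")
  }
  lines <- c(lines, "Planned stimulation contrasts (cm, unadjusted):",
             utils::capture.output(print(as.data.frame(
               dplyr::bind_rows(results$contrast_visit1,
                                results$contrast_crossover)),
               row.names = FALSE, digits = 4)), "")
  if (!is.null(results$balance)) {
    lines <- c(lines, "Stimulation x condition balance ANOVA:",
               utils::capture.output(print(as.data.frame(results$balance$anova),
                                           row.names = FALSE, digits = 4)))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
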