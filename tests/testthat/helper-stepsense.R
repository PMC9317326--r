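# Shared fixtures, built in code.

# trials lying exactly on a line deviation = slope * shift + intercept
line_trials <- function(slope = 0.5, intercept = 3.75,
                        shifts = seq(-12, -3, length.out = 20)) {
  tibble::tibble(shift = shifts, deviation = slope * shifts + intercept)
}

# a small, fast cohort design
tiny_design <- function(...) {
  cohort_design(n_per_group = 2, n_blocks = 2, trials_per_block = 25, ...)
}

# noiseless design: every deviation must be exactly zero
silent_design <- function(...) {
  cohort_design(n_per_group = 2, n_blocks = 1, trials_per_block = 10,
                sigma_visual = 0, sigma_motor = 0,
                tens_effect = 0, visit_effect = 0, retention_effect = 0,
                between_sd_visual = 0, between_sd_motor = 0, ...)
}

# a cop_trace from explicit samples
make_trace <- function(ap, ml = rep(0, length(ap)), rate = 25) {
  structure(tibble::tibble(t = (seq_along(ap) - 1) / rate, ap = ap, ml = ml),
            rate = rate, condition = NA_integer_,
            class = c("cop_trace", "tbl_df", "tbl", "data.frame"))
}

# smallest tau > 0 with p + v t + a t^2/2 on an origin-centred ellipse,
# for zero acceleration: solve the quadratic |scaled(p + v t)| = 1
ellipse_exit_time <- function(p, v, a_ml, b_ap) {
  px <- p[1] / a_ml; py <- p[2] / b_ap
  vx <- v[1] / a_ml; vy <- v[2] / b_ap
  A <- vx^2 + vy^2
  B <- 2 * (px * vx + py * vy)
  C <- px^2 + py^2 - 1
  if (A == 0) return(Inf)
  disc <- B^2 - 4 * A * C
  roots <- c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))
  min(roots[roots > 0])
}

# classical balanced repeated-measures ANOVA (one observation per
# participant-visit): between-factor `group`, within-factor `visit`
classical_rm_anova <- function(dat) {
  a <- length(unique(dat$group))
  b <- length(unique(dat$visit))
  n <- length(unique(dat$participant_id)) / a
  N <- nrow(dat)
  grand <- mean(dat$rmse)
  gm <- tapply(dat$rmse, dat$group, mean)
  vm <- tapply(dat$rmse, dat$visit, mean)
  cm <- tapply(dat$rmse, list(dat$group, dat$visit), mean)
  sm <- tapply(dat$rmse, dat$participant_id, mean)
  subj_group <- tapply(as.character(dat$group), dat$participant_id, `[`, 1)
  ss_group <- n * b * sum((gm - grand)^2)
  ss_subj <- b * sum((sm - grand)^2) - ss_group
  ss_visit <- n * a * sum((vm - grand)^2)
  ss_cells <- n * sum((cm - grand)^2)
  ss_int <- ss_cells - ss_group - ss_visit
  ss_tot <- sum((dat$rmse - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_visit - ss_int
  df_group <- a - 1; df_subj <- a * (n - 1)
  df_visit <- b - 1; df_int <- (a - 1) * (b - 1)
  df_err <- df_subj * (b - 1)
  list(
    f_group = (ss_group / df_group) / (ss_subj / df_subj),
    f_visit = (ss_visit / df_visit) / (ss_err / df_err),
    f_int = (ss_int / df_int) / (ss_err / df_err),
    df = c(group = df_subj, within = df_err)
  )
}
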