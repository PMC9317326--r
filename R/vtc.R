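#' Low-pass filter a centre-of-pressure trace
#'
#' Zero-phase (forward-backward) Butterworth low-pass filtering of both sway
#' axes before differentiation: double differentiation amplifies
#' high-frequency noise, so postural traces are conditioned first. A
#' second-order filter applied forward and backward gives a fourth-order
#' effective response with no phase distortion; the default cutoff is 10 Hz.
#'
#' @param trace A `cop_trace` tibble (columns `t`, `ap`, `ml`; attribute
#'   `rate`) as from [simulate_cop()] or [read_cop()].
#' @param cutoff Cutoff frequency (Hz), must be below the Nyquist rate.
#' @return The filtered trace, same class and length.
#' @export
preprocess_cop <- function(trace, cutoff = 10) {
  rate <- cop_rate(trace)
  if (cutoff >= rate / 2) {
    rlang::abort(sprintf("`cutoff` (%g Hz) must be below the Nyquist frequency (%g Hz).",
                         cutoff, rate / 2),
                 class = "stepsense_invalid_parameter")
  }
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  out <- trace
  out$ap <- filtfilt_padded(bf, trace$ap)
  out$ml <- filtfilt_padded(bf, trace$ml)
  out
}

# forward-backward filtering with odd-symmetric end reflection, so that
# constant and slowly varying signals pass without end transients
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1L, 3L * max(length(bf$a), length(bf$b)) * 10L)
  head_pad <- 2 * x[1] - x[seq(np + 1L, 2L, by = -1L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - np, by = -1L)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(np + 1L):(np + n)]
}

#' Finite-difference kinematics of a CoP trace
#'
#' Instantaneous velocity and acceleration of each sway axis by central
#' finite differences (one-sided at the end points); acceleration is the
#' central difference of the velocity.
#'
#' @param trace A `cop_trace` tibble, ideally already filtered with
#'   [preprocess_cop()].
#' @return The trace with columns `v_ap`, `v_ml` (cm/s) and `a_ap`, `a_ml`
#'   (cm/s^2) appended.
#' @export
cop_kinematics <- function(trace) {
  rate <- cop_rate(trace)
  if (nrow(trace) < 5L) {
    rlang::abort("Need at least 5 samples for kinematics.",
                 class = "stepsense_insufficient_data")
  }
  dt <- 1 / rate
  out <- trace
  out$v_ap <- fd_gradient(trace$ap, dt)
  out$v_ml <- fd_gradient(trace$ml, dt)
  out$a_ap <- fd_gradient(out$v_ap, dt)
  out$a_ml <- fd_gradient(out$v_ml, dt)
  out
}

# central differences, one-sided at the ends
fd_gradient <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g
}

#' Ballistic time-to-contact of one CoP state with the boundary
#'
#' Projects the instantaneous CoP state forward under constant acceleration,
#' `p(tau) = p + v * tau + a * tau^2 / 2`, and returns the smallest
#' `tau > 0` at which the projected path reaches the base-of-support
#' boundary. The first sign change of the signed boundary function is
#' bracketed on a dense grid of `tau_max / 2000` steps and refined by
#' bisection to 1e-6 s. A path that never reaches the boundary within
#' `tau_max` returns `tau_max` flagged as capped.
#'
#' @param p,v,a Numeric length-2 state `(ml, ap)`: position (cm), velocity
#'   (cm/s), acceleration (cm/s^2). `p` must lie strictly inside `bos`.
#' @param bos A [base_of_support()].
#' @param tau_max Projection horizon (s), default 10.
#' @return A list with `tau` (s) and logical `capped`.
#' @export
#' @examples
#' circ <- base_of_support(a_ml = 5, b_ap = 5)
#' contact_time(c(0, 0), c(1, 0), c(0, 0), circ)$tau # 5 s: distance / speed
contact_time <- function(p, v, a, bos, tau_max = 10) {
  stopifnot(inherits(bos, "base_of_support"))
  if (bos_signed(bos, p[1], p[2]) >= 0) {
    rlang::abort("CoP state lies on or outside the base of support.",
                 class = "stepsense_state_error")
  }
  taus <- seq(0, tau_max, length.out = 2001L)
  ml <- p[1] + v[1] * taus + 0.5 * a[1] * taus^2
  ap <- p[2] + v[2] * taus + 0.5 * a[2] * taus^2
  g <- bos_signed(bos, ml, ap)
  hit <- which(g >= 0)
  if (!length(hit)) return(list(tau = tau_max, capped = TRUE))
  i <- hit[1]
  lo <- taus[i - 1]; hi <- taus[i]
  f <- function(tau) {
    bos_signed(bos,
               p[1] + v[1] * tau + 0.5 * a[1] * tau^2,
               p[2] + v[2] * tau + 0.5 * a[2] * tau^2)
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  list(tau = (lo + hi) / 2, capped = FALSE)
}

#' Virtual time-to-contact series for a CoP trace
#'
#' The full VTC pipeline for one balance trial: centre the trace on its mean
#' CoP, low-pass filter, differentiate, and compute [contact_time()] for
#' every sample. Larger times-to-contact indicate a CoP state further (in
#' time) from the stability boundary, i.e. better balance.
#'
#' @param trace A `cop_trace` tibble.
#' @param bos A [base_of_support()]; its ellipse is centred on the
#'   trial-mean CoP by the centring step.
#' @param cutoff Low-pass cutoff (Hz) passed to [preprocess_cop()].
#' @param tau_max Projection horizon (s).
#' @param center Centre the trace on its mean CoP first (default `TRUE`).
#' @return A tibble of class `vtc_series` with columns `t`, `tau` (s) and
#'   `capped`; the fraction of capped samples is attached as attribute
#'   `capped_fraction`.
#' @export
#' @examples
#' tr <- simulate_cop(cop_params(), condition = 1)
#' head(vtc(tr))
vtc <- function(trace, bos = base_of_support(), cutoff = 10, tau_max = 10,
                center = TRUE) {
  if (center) {
    trace$ap <- trace$ap - mean(trace$ap)
    trace$ml <- trace$ml - mean(trace$ml)
  }
  k <- cop_kinematics(preprocess_cop(trace, cutoff))
  if (any(!bos_contains(bos, k$ml, k$ap))) {
    rlang::abort("Trace leaves the base of support; enlarge the boundary or check units.",
                 class = "stepsense_state_error")
  }
  n <- nrow(k)
  tau <- numeric(n)
  capped <- logical(n)
  for (i in seq_len(n)) {
    ct <- contact_time(c(k$ml[i], k$ap[i]), c(k$v_ml[i], k$v_ap[i]),
                       c(k$a_ml[i], k$a_ap[i]), bos, tau_max)
    tau[i] <- ct$tau
    capped[i] <- ct$capped
  }
  out <- tibble::tibble(t = k$t, tau = tau, capped = capped)
  structure(out, capped_fraction = mean(capped),
            class = c("vtc_series", class(out)))
}

#' Average virtual time-to-contact of a trial
#'
#' The per-trial summary statistic: the arithmetic mean of the per-sample
#' times-to-contact. Samples capped at the projection horizon are included
#' by default (treating the horizon as a conservative stand-in for "very
#' stable"); excluding them is available but shifts the mean down and is
#' reported with the capped fraction so the choice is visible.
#'
#' @param series A `vtc_series` from [vtc()].
#' @param cap_policy `"include_capped"` (default) or `"exclude_capped"`.
#' @return A one-row tibble with `mean_vtc` (s), `n`, `capped_fraction`.
#' @export
mean_vtc <- function(series, cap_policy = c("include_capped", "exclude_capped")) {
  cap_policy <- match.arg(cap_policy)
  check_trial_columns(series, c("tau", "capped"))
  if (nrow(series) == 0L) {
    rlang::abort("Empty VTC series.", class = "stepsense_insufficient_data")
  }
  keep <- if (cap_policy == "exclude_capped") !series$capped else rep(TRUE, nrow(series))
  if (!any(keep)) {
    rlang::abort("All samples are capped; nothing to average under `exclude_capped`.",
                 class = "stepsense_empty_mean")
  }
  tibble::tibble(mean_vtc = mean(series$tau[keep]), n = sum(keep),
                 capped_fraction = mean(series$capped))
}

cop_rate <- function(trace) {
  rate <- attr(trace, "rate")
  if (is.null(rate)) {
    check_trial_columns(trace, c("t"))
    dt <- diff(trace$t)
    if (length(dt) < 1L || any(abs(dt - dt[1]) > 1e-9)) {
      rlang::abort("Trace timestamps are not uniform; cannot infer the sampling rate.",
                   class = "stepsense_schema_error")
    }
    rate <- 1 / dt[1]
  }
  rate
}
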