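#' Base-of-support boundary
#'
#' The region within which the centre of pressure (CoP) can move without a
#' loss of balance. The default is an ellipse centred on the origin (trial
#' coordinates are centred on the mean CoP) with semi-axes matching a
#' feet-together stance: half stance width 5 cm medio-laterally, half foot
#' length 12 cm antero-posteriorly. A simple convex polygon (counter-
#' clockwise vertex list) is also supported.
#'
#' @param shape `"ellipse"` or `"polygon"`.
#' @param center Ellipse centre `c(ml, ap)` in cm.
#' @param a_ml,b_ap Ellipse semi-axes (cm, > 0): medio-lateral and
#'   antero-posterior.
#' @param vertices For polygons, a two-column matrix (ml, ap) of vertices of
#'   a convex polygon, in order.
#' @return An object of class `base_of_support`.
#' @export
#' @examples
#' bos <- base_of_support()                     # feet-together ellipse
#' base_of_support("polygon",
#'                 vertices = cbind(c(-5, 5, 5, -5), c(-12, -12, 12, 12)))
base_of_support <- function(shape = c("ellipse", "polygon"),
                            center = c(0, 0), a_ml = 5, b_ap = 12,
                            vertices = NULL) {
  shape <- match.arg(shape)
  if (shape == "ellipse") {
    if (a_ml <= 0 || b_ap <= 0) {
      rlang::abort("Semi-axes must be > 0.", class = "stepsense_invalid_parameter")
    }
    out <- list(shape = shape, center = center, a_ml = a_ml, b_ap = b_ap)
  } else {
    v <- as.matrix(vertices)
    if (is.null(vertices) || ncol(v) != 2L || nrow(v) < 3L) {
      rlang::abort("Polygon needs a 2-column matrix of >= 3 vertices.",
                   class = "stepsense_invalid_parameter")
    }
    # enforce counter-clockwise order and convexity via edge cross-products
    nx <- nrow(v)
    nxt <- c(2:nx, 1L)
    nx2 <- nxt[nxt]
    cr <- (v[nxt, 1] - v[, 1]) * (v[nx2, 2] - v[nxt, 2]) -
      (v[nxt, 2] - v[, 2]) * (v[nx2, 1] - v[nxt, 1])
    if (all(cr <= 0)) {
      v <- v[rev(seq_len(nx)), , drop = FALSE]
      cr <- -cr
    }
    if (any(cr <= 0)) {
      rlang::abort("Polygon must be simple and convex.",
                   class = "stepsense_invalid_parameter")
    }
    out <- list(shape = shape, vertices = v)
  }
  structure(out, class = "base_of_support")
}

# signed boundary function: negative strictly inside, 0 on the boundary,
# positive outside; continuous in (ml, ap). Vectorised over points.
bos_signed <- function(bos, ml, ap) {
  if (bos$shape == "ellipse") {
    ((ml - bos$center[1]) / bos$a_ml)^2 + ((ap - bos$center[2]) / bos$b_ap)^2 - 1
  } else {
    v <- bos$vertices
    nx <- nrow(v)
    nxt <- c(2:nx, 1L)
    # max over edges of the outward half-plane coordinate (ccw polygon)
    out <- rep(-Inf, length(ml))
    for (i in seq_len(nx)) {
      ex <- v[nxt[i], 1] - v[i, 1]
      ey <- v[nxt[i], 2] - v[i, 2]
      len <- sqrt(ex^2 + ey^2)
      d <- ((ml - v[i, 1]) * ey - (ap - v[i, 2]) * ex) / len
      out <- pmax(out, d)
    }
    out
  }
}

#' Is a point inside the base of support?
#'
#' @param bos A [base_of_support()].
#' @param ml,ap Point coordinates (cm). Vectorised.
#' @return Logical vector, `TRUE` strictly inside.
#' @export
bos_contains <- function(bos, ml, ap) {
  bos_signed(bos, ml, ap) < 0
}

#' Parameters for synthetic centre-of-pressure sway traces
#'
#' Describes 30-s quiet-stance sway recordings across the four sensory
#' conditions of the modified clinical test of sensory integration for
#' balance (rigid/compliant surface crossed with eyes open/closed). Sway is
#' modelled as a stationary Ornstein-Uhlenbeck process per axis — smooth,
#' zero-mean, bounded — with radial root-mean-square amplitude
#' `sway_scale[condition]`; harder sensory conditions sway more, so the
#' scales must be non-decreasing.
#'
#' @param duration Trial length (s), default 30.
#' @param rate Sampling rate (Hz), default 25 (portable force-plate
#'   typical); `duration * rate` must be a whole number of samples.
#' @param sway_scale Radial RMS sway per condition (cm), non-decreasing,
#'   length 4.
#' @param smoothness Ornstein-Uhlenbeck time constant (s), default 1.
#' @param lp_cutoff Low-pass cutoff (Hz) applied inside the generator to
#'   confine the trace to the physiological sway band, default 2; must be
#'   below the Nyquist frequency.
#' @param bos The [base_of_support()] boundary the trace must stay inside.
#' @param seed Integer seed.
#' @return An object of class `cop_params`.
#' @export
cop_params <- function(duration = 30, rate = 25,
                       sway_scale = c(0.9, 1.2, 1.3, 2.0),
                       smoothness = 1, lp_cutoff = 2,
                       bos = base_of_support(), seed = 1L) {
  n <- duration * rate
  if (abs(n - round(n)) > 1e-9 || n < 2) {
    rlang::abort("`duration * rate` must be a whole number of samples >= 2.",
                 class = "stepsense_invalid_parameter")
  }
  if (length(sway_scale) != 4L || any(diff(sway_scale) < 0) || any(sway_scale < 0)) {
    rlang::abort("`sway_scale` must be 4 non-decreasing non-negative values.",
                 class = "stepsense_invalid_parameter")
  }
  if (smoothness <= 0) {
    rlang::abort("`smoothness` must be > 0.", class = "stepsense_invalid_parameter")
  }
  if (lp_cutoff <= 0 || lp_cutoff >= rate / 2) {
    rlang::abort("`lp_cutoff` must be in (0, rate/2).",
                 class = "stepsense_invalid_parameter")
  }
  stopifnot(inherits(bos, "base_of_support"))
  structure(list(duration = duration, rate = rate, sway_scale = sway_scale,
                 smoothness = smoothness, lp_cutoff = lp_cutoff,
                 bos = bos, seed = as.integer(seed)),
            class = "cop_params")
}

# one stationary OU path with per-axis SD sd_axis
ou_path <- function(n, dt, tau, sd_axis) {
  if (sd_axis == 0) return(numeric(n))
  rho <- exp(-dt / tau)
  innov <- stats::rnorm(n, 0, sd_axis * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_axis)
  for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i]
  x
}

#' Simulate a centre-of-pressure sway trace
#'
#' Generates one 2-D quiet-stance CoP trace for the given sensory condition:
#' independent Ornstein-Uhlenbeck processes in the medio-lateral and
#' antero-posterior directions, zero-phase low-pass filtered at
#' `lp_cutoff` (confining the trace to the slow physiological sway band),
#' centred, and rescaled so the radial root-mean-square exactly equals
#' `sway_scale[condition]`. Traces whose excursions leave the base of
#' support are redrawn (up to 100 attempts, then an error): the boundary is
#' a hard physical constraint.
#'
#' @param params A [cop_params()].
#' @param condition Sensory condition 1-4 (1 = rigid surface, eyes open ...
#'   4 = compliant surface, eyes closed).
#' @param seed Optional seed overriding `params$seed`.
#' @return A tibble of class `cop_trace` with columns `t` (s), `ap`, `ml`
#'   (cm) and attributes `rate` and `condition`.
#' @export
#' @examples
#' tr <- simulate_cop(cop_params(), condition = 1)
#' sqrt(mean(tr$ap^2 + tr$ml^2)) # ~ sway_scale[1]
simulate_cop <- function(params, condition, seed = NULL) {
  stopifnot(inherits(params, "cop_params"))
  if (!condition %in% 1:4) {
    rlang::abort("`condition` must be 1, 2, 3 or 4.",
                 class = "stepsense_invalid_parameter")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(if (is.null(seed)) params$seed + condition else seed)

  n <- round(params$duration * params$rate)
  dt <- 1 / params$rate
  sd_axis <- params$sway_scale[condition] / sqrt(2)
  bf <- signal::butter(2, params$lp_cutoff / (params$rate / 2), type = "low")
  smooth_axis <- function(x) {
    if (sd_axis == 0) return(x)
    y <- filtfilt_padded(bf, x)
    y - mean(y)
  }
  for (attempt in seq_len(100L)) {
    ml <- smooth_axis(ou_path(n, dt, params$smoothness, sd_axis))
    ap <- smooth_axis(ou_path(n, dt, params$smoothness, sd_axis))
    rms <- sqrt(mean(ml^2 + ap^2))
    if (rms > 0) {
      k <- params$sway_scale[condition] / rms
      ml <- ml * k
      ap <- ap * k
    }
    if (all(bos_contains(params$bos, ml, ap))) {
      out <- tibble::tibble(t = (seq_len(n) - 1L) * dt, ap = ap, ml = ml)
      return(new_cop_trace(out, rate = params$rate, condition = condition))
    }
  }
  rlang::abort("Could not keep the trace inside the base of support in 100 attempts; reduce `sway_scale`.",
               class = "stepsense_generation_error")
}

new_cop_trace <- function(df, rate, condition = NA_integer_) {
  structure(df, rate = rate, condition = condition,
            class = c("cop_trace", class(df)))
}

#' @export
print.cop_trace <- function(x, ...) {
  cat(sprintf("<cop_trace> %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x), attr(x, "rate"), nrow(x) / attr(x, "rate"),
              if (!is.na(attr(x, "condition")))
                sprintf(", condition %d", attr(x, "condition")) else ""))
  NextMethod()
}
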