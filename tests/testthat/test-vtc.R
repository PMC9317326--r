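test_that("zero-phase filtering leaves a constant trace unchanged", {
  tr <- make_trace(rep(1.5, 200), rep(-0.5, 200))
  out <- preprocess_cop(tr, 10)
  expect_equal(out$ap, tr$ap, tolerance = 1e-8)
  expect_equal(out$ml, tr$ml, tolerance = 1e-8)
})

test_that("the filter passes slow sway and strongly attenuates fast noise", {
  rate <- 100
  t <- seq(0, 20, by = 1 / rate)
  interior <- seq(200, length(t) - 200)
  slow <- make_trace(sin(2 * pi * 1 * t), rate = rate)
  out <- preprocess_cop(slow, 10)
  amp_ratio <- max(abs(out$ap[interior])) / 1
  expect_gt(amp_ratio, 0.99)
  fast <- make_trace(sin(2 * pi * 20 * t), rate = rate)
  out2 <- preprocess_cop(fast, 10)
  expect_lt(max(abs(out2$ap[interior])), 0.05)
})

test_that("a cutoff at or above Nyquist is rejected", {
  tr <- make_trace(rnorm(100), rate = 25)
  expect_error(preprocess_cop(tr, 12.5), class = "stepsense_invalid_parameter")
})

test_that("finite-difference kinematics recover polynomial motion exactly", {
  rate <- 25
  t <- (0:199) / rate
  ramp <- make_trace(2 * t, rate = rate)
  k <- cop_kinematics(ramp)
  inner <- 3:197
  expect_equal(k$v_ap[inner], rep(2, length(inner)), tolerance = 1e-10)
  expect_equal(k$a_ap[inner], rep(0, length(inner)), tolerance = 1e-9)
  flat <- cop_kinematics(make_trace(rep(1, 50), rate = rate))
  expect_equal(max(abs(flat$v_ap)), 0)
  expect_equal(max(abs(flat$a_ap)), 0)
})

test_that("finite-difference velocity matches the analytic derivative", {
  rate <- 100
  t <- (0:999) / rate
  k <- cop_kinematics(make_trace(sin(2 * pi * t), rate = rate))
  inner <- 5:995
  truth <- 2 * pi * cos(2 * pi * t)
  expect_lt(max(abs(k$v_ap[inner] - truth[inner])) / (2 * pi), 0.005)
})

test_that("too-short traces are rejected", {
  expect_error(cop_kinematics(make_trace(1:4 / 10)),
               class = "stepsense_insufficient_data")
})

test_that("contact times match the elementary kinematic formulas", {
  circ5 <- base_of_support(a_ml = 5, b_ap = 5)
  # pure velocity: tau = distance / speed
  expect_equal(contact_time(c(0, 0), c(1, 0), c(0, 0), circ5)$tau, 5,
               tolerance = 1e-6)
  # pure acceleration: tau = sqrt(2 d / a)
  circ4 <- base_of_support(a_ml = 4, b_ap = 4)
  expect_equal(contact_time(c(0, 0), c(0, 0), c(2, 0), circ4)$tau, 2,
               tolerance = 1e-6)
  # motion away from the near side still exits at the far side
  expect_equal(contact_time(c(0, 0), c(-1, 0), c(0, 0), circ5, tau_max = 10)$tau,
               5, tolerance = 1e-6)
})

test_that("states outside the boundary and non-crossing paths are handled", {
  circ <- base_of_support(a_ml = 5, b_ap = 5)
  expect_error(contact_time(c(6, 0), c(1, 0), c(0, 0), circ),
               class = "stepsense_state_error")
  still <- contact_time(c(0, 0), c(0, 0), c(0, 0), circ, tau_max = 10)
  expect_equal(still$tau, 10)
  expect_true(still$capped)
})

test_that("grid-plus-bisection agrees with the closed-form ellipse exit", {
  set.seed(51)
  bos <- base_of_support(a_ml = 5, b_ap = 12)
  for (i in 1:200) {
    repeat {
      p <- c(runif(1, -4, 4), runif(1, -10, 10))
      if (bos_signed(bos, p[1], p[2]) < -0.01) break
    }
    v <- c(runif(1, -3, 3), runif(1, -3, 3))
    truth <- ellipse_exit_time(p, v, 5, 12)
    got <- contact_time(p, v, c(0, 0), bos, tau_max = 30)
    if (is.finite(truth) && truth <= 30) {
      expect_false(got$capped)
      expect_lt(abs(got$tau - truth), 1e-5)
    } else {
      expect_true(got$capped)
    }
  }
})

test_that("enlarging the boundary never shortens a contact time", {
  set.seed(52)
  bos1 <- base_of_support(a_ml = 5, b_ap = 12)
  bos2 <- base_of_support(a_ml = 7.5, b_ap = 18)
  for (i in 1:50) {
    p <- c(runif(1, -3, 3), runif(1, -8, 8))
    if (bos_signed(bos1, p[1], p[2]) >= 0) next
    v <- c(runif(1, -3, 3), runif(1, -3, 3))
    a <- c(runif(1, -2, 2), runif(1, -2, 2))
    t1 <- contact_time(p, v, a, bos1, tau_max = 10)
    t2 <- contact_time(p, v, a, bos2, tau_max = 10)
    expect_gte(t2$tau + 1e-9, t1$tau)
  }
})

test_that("polygon boundaries give the same exit as an equivalent region", {
  # square of half-width 5: exit along +ml from origin at 5 / v
  sq <- base_of_support("polygon",
                        vertices = cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5)))
  expect_equal(contact_time(c(0, 0), c(2, 0), c(0, 0), sq)$tau, 2.5,
               tolerance = 1e-6)
  expect_true(bos_contains(sq, 4.9, 4.9))
  expect_false(bos_contains(sq, 5.1, 0))
  expect_error(
    base_of_support("polygon",
                    vertices = cbind(c(0, 2, 1, 2, 0), c(0, 0, 1, 2, 2))),
    class = "stepsense_invalid_parameter")
})

test_that("the vtc series covers every sample and flags capped ones", {
  tr <- simulate_cop(cop_params(seed = 53), 2)
  s <- vtc(tr)
  expect_equal(nrow(s), nrow(tr))
  expect_true(all(s$tau > 0 & s$tau <= 10))
  expect_equal(attr(s, "capped_fraction"), mean(s$capped))
})

test_that("mean vtc honours the cap policy", {
  s <- structure(tibble::tibble(t = c(0, 0.04), tau = c(1, 10),
                                capped = c(FALSE, TRUE)),
                 class = c("vtc_series", "tbl_df", "tbl", "data.frame"))
  expect_equal(mean_vtc(s)$mean_vtc, 5.5)
  expect_equal(mean_vtc(s, "exclude_capped")$mean_vtc, 1)
  expect_equal(mean_vtc(s)$capped_fraction, 0.5)
  all_capped <- dplyr::mutate(s, capped = TRUE)
  expect_error(mean_vtc(all_capped, "exclude_capped"),
               class = "stepsense_empty_mean")
  flat <- tibble::tibble(t = 0:2, tau = c(1, 2, 3), capped = rep(FALSE, 3))
  expect_equal(mean_vtc(flat)$mean_vtc, 2)
})
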