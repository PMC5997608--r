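test_that("OUR from the dual-DO pair follows the residence-time formula", {
  expect_equal(our_from_dual_do(5, 5, 2), 0)
  expect_equal(our_from_dual_do(6, 4, 2), 1)
  expect_equal(our_from_dual_do(4, 6, 2), 0)  # clipped at zero
  expect_error(our_from_dual_do(6, 4, 0), "positive")
})

test_that("a simulated constant-OUR loop recovers the imposed OUR", {
  rc <- reactor_config()
  our_true <- 60  # mg O2/L/h
  out <- simulate_respirometer(our_true, duration_h = 1, reactor = rc)
  est <- tail(out$OUR_meas, 1) * 60  # mg/L/min -> mg/L/h
  expect_equal(est, our_true, tolerance = 0.01)
})

test_that("the OUR finite difference matches worked values and exact ramps", {
  expect_equal(d_our_dt(c(5, 5, 5, 5), dt_min = 0.5), c(0, 0, 0))
  expect_equal(d_our_dt(c(5.0, 4.8), n = 1, dt_min = 0.5), -0.4)
  # linear ramp: exact slope at every point, smoothed or not
  ramp <- seq(1, 4, by = 0.15)
  for (w in c(1, 3, 5)) {
    d <- d_our_dt(ramp, smooth_w = w, dt_min = 0.5)
    inner <- d[w:(length(d) - w)]
    expect_equal(inner, rep(0.3, length(inner)), tolerance = 1e-12)
  }
  expect_error(d_our_dt(c(1, 2), n = 2, dt_min = 0.5), "out of range")
})

test_that("noisy-feast derivative signs match the noise-free oracle on
           decision-relevant samples", {
  cyc <- fd_cycle_clean()
  fe <- cyc$trajectory[cyc$trajectory$phase == "feast", ]
  clean <- fe$OUR_meas[fe$t_h * 60 <= cyc$famine_onset_min]
  thr <- 0.1 * cyc$baseline_our  # the controller's trigger threshold
  set.seed(31)
  agree <- replicate(10, {
    sigma <- (max(clean) - min(clean)) / 20  # SNR 20
    noisy <- pmax(clean + rnorm(length(clean), 0, sigma), 0)
    d0 <- d_our_dt(clean, smooth_w = 5, lag = 4, causal = TRUE,
                   dt_min = 0.5)
    d1 <- d_our_dt(noisy, smooth_w = 5, lag = 4, causal = TRUE,
                   dt_min = 0.5)
    rel <- abs(d0) >= thr
    mean((sign(d0) == sign(d1))[rel])
  })
  expect_gte(mean(agree), 0.95)
})

test_that("feast-end detection finds the return to baseline", {
  # series that never fed: at baseline from the start
  s0 <- our_series(seq(0, 10, by = 0.5), rep(0.6, 21))
  expect_equal(detect_feast_end(s0, baseline = 0.6), 0)
  # zero baseline still terminates via the absolute floor
  s1 <- our_series(seq(0, 10, by = 0.5), rep(0, 21))
  expect_equal(detect_feast_end(s1, baseline = 0), 0)
  # never satisfied: warning + end of series
  s2 <- our_series(seq(0, 10, by = 0.5), rep(5, 21))
  expect_warning(res <- detect_feast_end(s2, baseline = 0.6), "never")
  expect_equal(res, 10)
})

test_that("detection hits the simulated substrate exhaustion and is
           monotone in the budget", {
  cyc <- fd_cycle_clean()
  fe <- cyc$trajectory[cyc$trajectory$phase == "feast", ]
  os <- our_series(fe$t_h * 60, fe$OUR_meas)
  last_pulse <- max(cyc$pulses$t_min)
  detected <- detect_feast_end(os, baseline = cyc$baseline_our,
                               after_min = last_pulse)
  true_exhaustion <- fe$t_min <- fe$t_h * 60
  true_exhaustion <- fe$t_min[fe$t_min > last_pulse & fe$S < 0.1][1]
  expect_lte(abs(detected - true_exhaustion), 2 * 0.5)  # within 2 samples
  # monotonicity: a later exhaustion time never yields an earlier detection
  d2 <- detect_feast_end(os, baseline = cyc$baseline_our,
                         after_min = last_pulse + 10)
  expect_gte(d2, detected)
})
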