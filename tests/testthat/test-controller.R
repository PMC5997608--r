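test_that("a rising OUR after START produces exactly one feeding event", {
  cfg <- controller_config(budget_total = 100, pulse_dose = 10)
  ctrl <- fd_controller(cfg)
  fd_start(ctrl, baseline = 0.5, t_min = 0)
  for (i in 1:60) {
    act <- fd_step(ctrl, 0.5 + 0.05 * i, t_min = i * 0.5)
    expect_identical(act$action, "hold")
  }
  lg <- pulse_log(ctrl)
  expect_identical(nrow(lg), 1L)
  expect_identical(lg$trigger, "START")
})

test_that("a zero budget terminates after the baseline check", {
  cfg <- controller_config(budget_total = 0, pulse_dose = 1e-9)
  ctrl <- fd_controller(cfg)
  expect_equal(fd_start(ctrl, baseline = 0.5), 0)
  acts <- vapply(1:10, function(i) fd_step(ctrl, 0.5, i * 0.5)$action, "")
  expect_identical(acts[cfg$k_settle], "terminate")
})

test_that("stepping before the compulsive START errors", {
  ctrl <- fd_controller(controller_config(budget_total = 100))
  expect_error(fd_step(ctrl, 0.5, 0), "before")
})

test_that("closed-loop pulse log satisfies the budget and trigger rules", {
  for (cyc in list(fd_cycle_clean(), fd_cycle_noisy())) {
    p <- cyc$pulses
    cfg <- cyc$scenario$controller
    # staircase: cumulative feed non-decreasing, ends exactly at budget
    expect_true(all(diff(p$cum_cmmol) > 0))
    expect_equal(max(p$cum_cmmol), cfg$budget_total, tolerance = 1e-12)
    expect_equal(cyc$cum_fed_cmmol, cfg$budget_total, tolerance = 1e-12)
    # at least floor(budget/dose) pulses, spaced >= one sample
    expect_gte(nrow(p), floor(cfg$budget_total / cfg$pulse_dose))
    expect_true(all(diff(p$t_min) >= cfg$sample_interval_min))
    # every non-START pulse triggered on a negative smoothed derivative
    trig <- p[p$trigger != "START", ]
    expect_true(all(trig$d_our_dt < 0))
    # termination reached famine state
    expect_identical(attr(p, "terminal_reason"), "budget_exhausted")
    expect_false(is.na(cyc$famine_onset_min))
  }
})

test_that("without inhibition the closed loop matches a single pulse", {
  kp <- kinetic_params(K_I = Inf)
  c_multi <- run_cycle(feast_only_fd(kp))
  c_single <- run_cycle(feast_only_single_pulse(kp))
  p_multi <- max(c_multi$trajectory$PHB * c_multi$trajectory$V_l)
  p_single <- max(c_single$trajectory$PHB * c_single$trajectory$V_l)
  expect_lt(abs(p_multi - p_single) / p_single, 0.01)
})

test_that("DO and OUR are anti-phase over the feast", {
  cyc <- fd_cycle_clean()
  fe <- cyc$trajectory[cyc$trajectory$phase == "feast", ]
  frac <- mean(sign(diff(fe$DO_out_meas)) == -sign(diff(fe$OUR_meas)))
  expect_gt(frac, 0.9)
})
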