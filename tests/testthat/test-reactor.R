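test_that("withdrawal keeps concentrations, scales volume, logs harvest", {
  st <- reactor_state(V = 3.4, S = 2, X_st = 31, PHB = 148, NH4 = 0.5)
  w0 <- apply_withdrawal(st, 0)
  expect_equal(w0$state$V, 3.4)
  expect_equal(w0$harvested[["PHB_cmmol"]], 0)
  w <- apply_withdrawal(st, 0.75)
  expect_equal(w$state$V, 0.85)
  expect_equal(w$state$PHB, 148)  # concentration unchanged
  expect_equal(w$harvested[["PHB_cmmol"]], 148 * 2.55)
  expect_error(apply_withdrawal(st, 1), "empty")
  expect_error(apply_withdrawal(st, -0.1), "0, 1")
})

test_that("settling selection removes light cells preferentially", {
  st <- reactor_state(V = 0.85, S = 5, X_st = 20, X_ns = 10, PHB = 60,
                      NH4 = 0.2)
  # no selectivity: both guilds lose the base fraction
  eq <- apply_settling_selection(st, settling_params(r_base = 0.2, s = 0))
  expect_equal(eq$removal[["storer"]], 0.2)
  expect_equal(eq$removal[["nonstorer"]], 0.2)
  # storers at/above the retention-saturating PHB load are fully kept
  sat <- apply_settling_selection(st, settling_params(r_base = 0.2, s = 1,
                                                      f_sat = 2))
  expect_equal(sat$removal[["storer"]], 0)  # f = 60/20 = 3 >= f_sat
  expect_equal(sat$removal[["nonstorer"]], 0.2)
  # intermediate PHB load: retention ratio storer:non-storer > 1, matching
  # the density law computed independently
  st2 <- reactor_state(V = 0.85, X_st = 20, X_ns = 10, PHB = 20)
  pars <- settling_params(r_base = 0.3, s = 0.8, f_sat = 2)
  mid <- apply_settling_selection(st2, pars)
  f <- 20 / 20
  expect_equal(mid$removal[["storer"]], 0.3 * (1 - 0.8 * f / 2))
  ret_ratio <- (1 - mid$removal[["storer"]]) / (1 - mid$removal[["nonstorer"]])
  expect_gt(ret_ratio, 1)
  # dissolved species are displaced back with the quiescent decant
  expect_equal(mid$state$S, st2$S)
})

test_that("respirometer loop matches its closed-form steady state", {
  rc <- reactor_config()
  out <- simulate_respirometer(90, duration_h = 1, reactor = rc)
  expect_equal(tail(out$DO_in - out$DO_out, 1), respirometer_gap(90, rc),
               tolerance = 0.01)
  # zero OUR: no gap
  out0 <- simulate_respirometer(0, duration_h = 0.5, reactor = rc)
  expect_equal(tail(out0$DO_in - out0$DO_out, 1), 0, tolerance = 1e-9)
  expect_error(reactor_config(Q_l_min = 0), "positive")
})

test_that("a step change in OUR relaxes on the loop time scale", {
  rc <- reactor_config()
  step_fun <- function(t) ifelse(t < 0.5, 30, 90)
  out <- simulate_respirometer(step_fun, duration_h = 1.5, reactor = rc)
  gap <- out$DO_in - out$DO_out
  g0 <- respirometer_gap(30, rc); g1 <- respirometer_gap(90, rc)
  expect_equal(gap[which.min(abs(out$t_h - 0.49))], g0, tolerance = 0.02)
  # several loop residence times after the step the new steady gap holds
  tau_h <- rc$V_reac / (rc$Q_l_min * 60)
  expect_equal(gap[which.min(abs(out$t_h - (0.5 + 8 * tau_h)))], g1,
               tolerance = 0.05)
  # monotone relaxation between the two plateaus
  mid <- gap[out$t_h > 0.5 & out$t_h < 0.5 + 8 * tau_h]
  expect_true(all(diff(mid) > -1e-9))
})

test_that("a zero-duration cycle is the identity on the state", {
  sc <- scenario_preset("SBR2")
  sc$schedule <- cycle_schedule(list(name = "noop", duration_min = 0))
  st <- reactor_state(V = 3.15, S = 1, X_st = 20, X_ns = 5, PHB = 10,
                      NH4 = 0.7)
  cyc <- run_cycle(sc, state = st)
  for (f in c("V", "S", "X_st", "X_ns", "PHB", "NH4"))
    expect_equal(cyc$state[[f]], st[[f]], tolerance = 1e-12)
})

test_that("3/4 withdrawal plus full refill dilutes biomass fourfold", {
  sc <- scenario_preset("SBR2")
  sc$schedule <- cycle_schedule(
    list(name = "draw", duration_min = 0, withdraw_fraction = 0.75),
    list(name = "refill", duration_min = 0,
         nutrient_vol_l = 2.3, nutrient_nh4_mmol_l = 6.44,
         feed_cmmol = 0.001, feed_vol_l = 0.25))
  st <- reactor_state(V = 3.4, X_st = 31)
  cyc <- run_cycle(sc, state = st)
  expect_equal(cyc$state$X_st, 31 / 4, tolerance = 1e-9)
  expect_equal(cyc$state$V, 3.4, tolerance = 1e-12)
})

test_that("scenario YAML round-trips through read/write", {
  sc <- scenario_preset("FD")
  path <- tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$kinetics$q_s_max, sc$kinetics$q_s_max)
  expect_equal(sc2$controller$budget_total, sc$controller$budget_total)
  expect_equal(schedule_length_h(sc2$schedule), schedule_length_h(sc$schedule))
  expect_equal(sc2$init$X_st, sc$init$X_st)
  expect_equal(sc2$settling$r_base, sc$settling$r_base)
})
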