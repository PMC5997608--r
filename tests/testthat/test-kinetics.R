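random_state <- function() {
  c(S = runif(1, 0, 150), X_st = runif(1, 1, 60), X_ns = runif(1, 0, 60),
    PHB = runif(1, 0, 100), NH4 = runif(1, 0, 5))
}

test_that("starvation limit gives zero conversion and endogenous OUR only", {
  kp <- kinetic_params()
  rv <- reaction_rates(c(S = 0, X_st = 31, X_ns = 0, PHB = 0, NH4 = 0), kp)
  expect_equal(rv$dS, 0)
  expect_equal(rv$dPHB, 0)
  expect_equal(rv$r_growth, 0)
  expect_equal(rv$OUR, kp$m_O2 * 31, tolerance = 1e-12)
})

test_that("ideal feast conditions reproduce the specific storage rate", {
  # S >> K_S, S << K_I, empty cells: dPHB/dt = Y_PS_max q_s_max X
  kp <- kinetic_params(q_s_max = 1.05, Y_PS_max = 0.81, K_S = 1e-9,
                       K_I = Inf)
  rv <- reaction_rates(c(S = 10, X_st = 31, X_ns = 0, PHB = 0, NH4 = 0), kp)
  expect_equal(rv$dPHB, 0.85 * 31, tolerance = 0.01)
  expect_equal(rv$dS, -1.05 * 31, tolerance = 1e-6)
})

test_that("carbon and electron balances close at every rate evaluation", {
  set.seed(21)
  for (i in 1:200) {
    kp <- kinetic_params(q_s_max = runif(1, 0.5, 3),
                         Y_PS_max = runif(1, 0.4, 0.87),
                         mu_max = runif(1, 0.05, 0.4),
                         Y_X_PHB = runif(1, 0.4, 0.9))
    st <- random_state()
    rv <- reaction_rates(st, kp)
    scale <- max(abs(rv$dS), rv$CO2, 1e-6)
    # carbon: what leaves one pool enters another or becomes CO2
    expect_lt(abs(rv$dS + rv$dX_st + rv$dX_ns + rv$dPHB + rv$CO2),
              1e-9 * scale)
    # electrons: 4 per mol O2
    eb <- kp$gamma_S * (-rv$dS) - kp$gamma_P * rv$dPHB -
      kp$gamma_X * (rv$dX_st + rv$dX_ns) - 4 * rv$OUR
    expect_lt(abs(eb), 1e-9 * max(4 * rv$OUR, 1e-6))
    expect_gte(rv$CO2, 0)
    expect_gte(rv$OUR, 0)
  }
})

test_that("storage rate is non-increasing in cellular PHB content", {
  kp <- kinetic_params()
  f <- seq(0, kp$f_phb_max, length.out = 40)
  x <- 31
  dphb <- vapply(f, function(fi) {
    reaction_rates(c(S = 20, X_st = x, X_ns = 0, PHB = fi * x, NH4 = 0),
                   kp)$dPHB
  }, numeric(1))
  expect_true(all(diff(dphb) <= 1e-9))
  expect_lt(dphb[40], 0.05 * dphb[1])  # near capacity storage has collapsed
})

test_that("invalid states and parameter sets are rejected", {
  kp <- kinetic_params()
  expect_error(reaction_rates(c(S = -1, X_st = 1, X_ns = 0, PHB = 0,
                                NH4 = 0), kp), "negative")
  expect_error(kinetic_params(Y_PS_max = 0.95), "electrons")
  expect_error(kinetic_params(Y_X_PHB = 1.2), "carbon balance")
  expect_error(kinetic_params(q_s_max = -1), "positive")
})
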