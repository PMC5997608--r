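# The two-tank respirometer loop on its own: an aerated 3-L tank and an
# unaerated 1-L reaction tank exchanging liquid, with first-order DO
# sensors. Used to validate the OUR measurement chain against closed forms.

#' Steady-state DO gap across the reaction tank
#'
#' At steady state the reaction tank balance gives
#' `DO_in - DO_out = OUR x V_reac / Q`.
#'
#' @param our_mg_l_h volumetric oxygen uptake rate, mg O2/L/h.
#' @param reactor a [reactor_config()].
#' @return DO difference in mg/L.
#' @export
respirometer_gap <- function(our_mg_l_h, reactor = reactor_config()) {
  our_mg_l_h * reactor$V_reac / (reactor$Q_l_min * 60)
}

#' Simulate the respirometer loop under a prescribed OUR
#'
#' Integrates the two-tank DO balance (aerated tank with kLa transfer,
#' unaerated reaction tank, recirculation flow Q) plus the first-order
#' sensor lag, with the biological OUR imposed as a known function of time.
#' This isolates the measurement chain from the kinetics.
#'
#' @param our_mg_l_h OUR as a constant (mg O2/L/h) or a function of time
#'   in hours.
#' @param duration_h simulated time, h.
#' @param reactor a [reactor_config()].
#' @param dt_out_min output resolution, minutes.
#' @param DO0 initial DO in both tanks, mg/L (default saturation).
#' @return data.frame with `t_h`, `DO_in` (aeration tank), `DO_out`
#'   (reaction tank), `DO_in_meas`, `DO_out_meas` (lagged sensor readings)
#'   and `OUR_meas` (mg O2/L/min from the lagged pair).
#' @export
simulate_respirometer <- function(our_mg_l_h, duration_h,
                                  reactor = reactor_config(),
                                  dt_out_min = 0.1, DO0 = NULL) {
  rc <- reactor
  fo <- if (is.function(our_mg_l_h)) our_mg_l_h else function(t) our_mg_l_h
  Qh <- rc$Q_l_min * 60
  tau_s <- rc$sensor_tau_s / 3600
  if (is.null(DO0)) DO0 <- rc$DO_sat
  y0 <- c(DOa = DO0, DOr = DO0, DOim = DO0, DOom = DO0)
  rhs <- function(t, y, p) {
    our <- fo(t)
    list(c(rc$kLa * (rc$DO_sat - y[1]) + (Qh / rc$V_aer) * (y[2] - y[1]) - our,
           (Qh / rc$V_reac) * (y[1] - y[2]) - our,
           (y[1] - y[3]) / tau_s,
           (y[2] - y[4]) / tau_s))
  }
  times <- seq(0, duration_h, by = dt_out_min / 60)
  out <- as.data.frame(deSolve::lsoda(y0, times, rhs, NULL,
                                      rtol = 1e-9, atol = 1e-9))
  names(out) <- c("t_h", "DO_in", "DO_out", "DO_in_meas", "DO_out_meas")
  out$OUR_meas <- our_from_dual_do(out$DO_in_meas, out$DO_out_meas,
                                   rc$V_reac / rc$Q_l_min)
  out
}
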