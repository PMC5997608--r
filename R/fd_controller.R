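# Feed-on-demand controller: a compulsive first pulse, then one fixed dose
# whenever the smoothed OUR shows a relative decline (dOUR/dt below a small
# negative threshold), under a hard total budget; terminates once the
# budget is spent and the OUR has returned to the endogenous baseline
# (famine state).

#' Feed-on-demand controller configuration
#'
#' The raw feeding rule is: feed while dOUR/dt < 0, stop while >= 0, under
#' a fixed total budget. Applied verbatim to a sampled, noisy signal this
#' rule chatters (an unbiased derivative of a flat signal is negative half
#' the time), so the implementation hardens it in three ways, all exposed
#' here: a trailing moving-median over `smooth_w` samples, a derivative
#' taken across `deriv_lag` samples, and a trigger threshold of
#' `-deriv_tol_frac x baseline` per minute (a *relative* decline; with a
#' noise-free signal the behaviour reduces to the raw sign rule). A short
#' refractory period after each dose represents the pump/controller
#' dead-time and keeps dose bursts from outrunning the oxygen response.
#'
#' @param budget_total total acetate budget, Cmmol (e.g. 182 Cmmol/L times
#'   the working volume).
#' @param pulse_dose acetate per pulse, Cmmol; default `budget_total / 30`.
#' @param sample_interval_min OUR sampling interval, minutes.
#' @param smooth_w trailing moving-median window (samples).
#' @param deriv_lag derivative baseline lag (samples): dOUR/dt is
#'   (sm[n] - sm[n - deriv_lag]) / (deriv_lag x dt).
#' @param deriv_tol_frac relative-decline threshold: feed when the smoothed
#'   derivative is below `-deriv_tol_frac x baseline` per minute.
#' @param refractory_samples minimum samples between consecutive doses.
#' @param k_settle consecutive at-baseline samples required to declare the
#'   famine state after budget exhaustion.
#' @param tol relative tolerance above baseline for the famine check.
#' @param baseline_min length of the pre-feed window used to estimate the
#'   endogenous OUR baseline, minutes.
#' @param feed_conc_cmol_l carbon concentration of the feed solution,
#'   Cmol/L (0.85 M sodium acetate = 1.7 Cmol/L).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(budget_total,
                              pulse_dose = budget_total / 30,
                              sample_interval_min = 0.5,
                              smooth_w = 5,
                              deriv_lag = 4,
                              deriv_tol_frac = 0.1,
                              refractory_samples = 6,
                              k_settle = 4,
                              tol = 0.1,
                              baseline_min = 10,
                              feed_conc_cmol_l = 1.7) {
  if (budget_total < 0) stop("budget_total must be non-negative")
  if (budget_total > 0 && (pulse_dose <= 0 || pulse_dose > budget_total))
    stop("need 0 < pulse_dose <= budget_total")
  if (sample_interval_min <= 0) stop("sample_interval_min must be positive")
  if (deriv_lag < 1) stop("deriv_lag must be at least 1 sample")
  structure(list(budget_total = budget_total, pulse_dose = pulse_dose,
                 sample_interval_min = sample_interval_min,
                 smooth_w = smooth_w, deriv_lag = deriv_lag,
                 deriv_tol_frac = deriv_tol_frac,
                 refractory_samples = refractory_samples,
                 k_settle = k_settle, tol = tol,
                 baseline_min = baseline_min,
                 feed_conc_cmol_l = feed_conc_cmol_l),
            class = "controller_config")
}

#' Create a feed-on-demand controller
#'
#' Returns a stateful controller object. Drive it with [fd_start()] (the
#' compulsive first pulse) and then [fd_step()] once per OUR sample.
#'
#' @param config a [controller_config()].
#' @return An object of class `fd_controller` (an environment).
#' @export
fd_controller <- function(config) {
  stopifnot(inherits(config, "controller_config"))
  ctrl <- new.env(parent = emptyenv())
  ctrl$config <- config
  ctrl$started <- FALSE
  ctrl$terminated <- FALSE
  ctrl$fed_cum <- 0
  ctrl$baseline <- NA_real_
  ctrl$buffer <- numeric(0)    # raw OUR samples
  ctrl$smoothed <- numeric(0)  # trailing-median samples
  ctrl$since_dose <- Inf
  ctrl$at_baseline_run <- 0L
  ctrl$log <- list()
  ctrl$terminal_reason <- NA_character_
  class(ctrl) <- "fd_controller"
  ctrl
}

log_pulse <- function(ctrl, t_min, dose, trigger, deriv = NA_real_) {
  ctrl$fed_cum <- ctrl$fed_cum + dose
  ctrl$log[[length(ctrl$log) + 1L]] <-
    data.frame(t_min = t_min, dose_cmmol = dose, cum_cmmol = ctrl$fed_cum,
               trigger = trigger, d_our_dt = deriv)
}

#' Start the controller with the compulsive first pulse
#'
#' @param ctrl an [fd_controller()].
#' @param baseline endogenous OUR baseline, mg O2/L/min.
#' @param t_min current time, minutes.
#' @return The START dose in Cmmol (0 if the budget is 0).
#' @export
fd_start <- function(ctrl, baseline, t_min = 0) {
  stopifnot(inherits(ctrl, "fd_controller"))
  if (ctrl$started) stop("controller already started")
  if (baseline < 0) stop("baseline must be non-negative")
  ctrl$started <- TRUE
  ctrl$baseline <- baseline
  dose <- min(ctrl$config$pulse_dose, ctrl$config$budget_total)
  if (dose > 0) {
    log_pulse(ctrl, t_min, dose, "START")
    ctrl$since_dose <- 0L
  }
  dose
}

#' Advance the controller by one OUR sample
#'
#' Applies the hardened feeding rule (see [controller_config()]): feed one
#' dose iff the smoothed dOUR/dt shows a relative decline, the refractory
#' period has passed and budget remains; once the budget is exhausted and
#' the OUR has stayed at the endogenous baseline for `k_settle` consecutive
#' samples, terminate (famine state reached); otherwise hold.
#'
#' @param ctrl an [fd_controller()] that has been started with [fd_start()].
#' @param our_sample measured OUR, mg O2/L/min.
#' @param t_min current time, minutes.
#' @return A list with `action` ("feed", "hold" or "terminate"), `dose`
#'   (Cmmol, 0 unless feeding) and `deriv` (the smoothed derivative, NA
#'   while the lag buffer fills).
#' @export
fd_step <- function(ctrl, our_sample, t_min) {
  stopifnot(inherits(ctrl, "fd_controller"))
  if (!ctrl$started) stop("fd_step() called before fd_start()")
  cfg <- ctrl$config
  if (ctrl$terminated) return(list(action = "terminate", dose = 0,
                                   deriv = NA_real_))

  ctrl$buffer <- c(ctrl$buffer, our_sample)
  nb <- length(ctrl$buffer)
  sm <- stats::median(ctrl$buffer[max(1, nb - cfg$smooth_w + 1):nb])
  ctrl$smoothed <- c(ctrl$smoothed, sm)
  ctrl$since_dose <- ctrl$since_dose + 1L
  L <- cfg$deriv_lag
  deriv <- if (nb > L)
    (sm - ctrl$smoothed[nb - L]) / (L * cfg$sample_interval_min)
  else NA_real_

  remaining <- cfg$budget_total - ctrl$fed_cum
  if (remaining <= 1e-9) {
    thresh <- ctrl$baseline * (1 + cfg$tol) + 0.02
    ctrl$at_baseline_run <-
      if (our_sample <= thresh) ctrl$at_baseline_run + 1L else 0L
    if (ctrl$at_baseline_run >= cfg$k_settle) {
      ctrl$terminated <- TRUE
      ctrl$terminal_reason <- "budget_exhausted"
      return(list(action = "terminate", dose = 0, deriv = deriv))
    }
    return(list(action = "hold", dose = 0, deriv = deriv))
  }

  trigger <- -cfg$deriv_tol_frac * ctrl$baseline
  if (!is.na(deriv) && deriv < trigger &&
      ctrl$since_dose >= cfg$refractory_samples) {
    dose <- min(cfg$pulse_dose, remaining)
    log_pulse(ctrl, t_min, dose, "dOURdt<0", deriv)
    ctrl$since_dose <- 0L
    return(list(action = "feed", dose = dose, deriv = deriv))
  }
  list(action = "hold", dose = 0, deriv = deriv)
}

#' Pulse log of a controller
#'
#' @param ctrl an [fd_controller()].
#' @return A data.frame of class `pulse_log` with columns `t_min`,
#'   `dose_cmmol`, `cum_cmmol`, `trigger`, `d_our_dt` (the smoothed
#'   derivative at the trigger sample; NA for the START pulse), and
#'   attribute `terminal_reason`.
#' @export
pulse_log <- function(ctrl) {
  stopifnot(inherits(ctrl, "fd_controller"))
  df <- if (length(ctrl$log)) do.call(rbind, ctrl$log) else
    data.frame(t_min = numeric(0), dose_cmmol = numeric(0),
               cum_cmmol = numeric(0), trigger = character(0),
               d_our_dt = numeric(0))
  structure(df, terminal_reason = ctrl$terminal_reason,
            class = c("pulse_log", "data.frame"))
}

#' @export
print.pulse_log <- function(x, ...) {
  cat(sprintf("<pulse_log> %d pulses, %.1f Cmmol fed", nrow(x),
              if (nrow(x)) max(x$cum_cmmol) else 0))
  tr <- attr(x, "terminal_reason")
  if (!is.na(tr)) cat(" | terminated:", tr)
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more pulses\n")
  invisible(x)
}
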