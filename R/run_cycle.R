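# One SBR cycle: discrete feed/withdraw/settle events with exact mass
# bookkeeping, ODE integration between events, and optional feed-on-demand
# control during the feast.

# bolus addition of feed solution: dilutes everything, adds carbon/ammonium
bolus <- function(y, V, vol_l, cmmol = 0, nh4_mmol = 0) {
  V1 <- V + vol_l
  dil <- V / V1
  y[1:5] <- y[1:5] * dil
  y[["S"]] <- y[["S"]] + cmmol / V1
  y[["NH4"]] <- y[["NH4"]] + nh4_mmol / V1
  list(y = y, V = V1)
}

state_to_y <- function(state, kp, rc) {
  y <- c(S = state$S, X_st = state$X_st, X_ns = state$X_ns, PHB = state$PHB,
         NH4 = state$NH4, DO_a = state$DO_aer, DO_r = state$DO_reac,
         DO_im = NA_real_, DO_om = NA_real_, CO2 = 0, O2 = 0)
  if (is.na(y[["DO_a"]])) {
    # initialise DO at the respiratory steady state of the loop
    rv <- rate_vector(pmax(y[1:5], 0), kp)
    our_mg <- 32 * rv$OUR
    Qh <- rc$Q_l_min * 60
    doa <- rc$DO_sat - our_mg * (rc$V_aer + rc$V_reac) / (rc$kLa * rc$V_aer)
    dor <- doa - our_mg * rc$V_reac / Qh
    y[["DO_a"]] <- max(doa, 0)
    y[["DO_r"]] <- max(dor, 0)
  }
  if (is.na(y[["DO_im"]])) y[["DO_im"]] <- y[["DO_a"]]
  if (is.na(y[["DO_om"]])) y[["DO_om"]] <- y[["DO_r"]]
  y
}

y_to_state <- function(y, V, t) {
  reactor_state(V = V, S = max(y[["S"]], 0), X_st = max(y[["X_st"]], 0),
                X_ns = max(y[["X_ns"]], 0), PHB = max(y[["PHB"]], 0),
                NH4 = max(y[["NH4"]], 0), DO_aer = y[["DO_a"]],
                DO_reac = y[["DO_r"]], t = t)
}

carbon_amount <- function(y, V) sum(y[c("S", "X_st", "X_ns", "PHB")]) * V

electron_amount <- function(y, V, kp) {
  (kp$gamma_S * y[["S"]] + kp$gamma_X * (y[["X_st"]] + y[["X_ns"]]) +
     kp$gamma_P * y[["PHB"]]) * V
}

new_event_row <- function(t_h, name, dV = 0, C_in = 0, C_out = 0, N_in = 0,
                          N_out = 0, X_out = 0, PHB_out = 0) {
  data.frame(t_h = t_h, event = name, dV_l = dV, C_in_cmmol = C_in,
             C_out_cmmol = C_out, N_in_mmol = N_in, N_out_mmol = N_out,
             X_out_cmmol = X_out, PHB_out_cmmol = PHB_out)
}

empty_events <- function() new_event_row(numeric(0), character(0),
                                         numeric(0), numeric(0), numeric(0),
                                         numeric(0), numeric(0), numeric(0),
                                         numeric(0))

#' Run one SBR cycle
#'
#' Executes the phases of the scenario's schedule in order: boluses at phase
#' start, ODE integration across the phase (closed-loop feed-on-demand
#' control if the phase carries the controller), withdrawal and settling
#' selection at phase end. Every discrete action is logged with the exact
#' amounts moved, so carbon, electron and volume ledgers close over the
#' cycle.
#'
#' @param scenario an [sbr_scenario()] (see also [scenario_preset()]).
#' @param state initial [reactor_state()]; default `scenario$init`.
#' @param seed integer seed for the DO sensor noise; `NULL` leaves the RNG
#'   state alone.
#' @param dt_out_min trajectory output resolution, minutes.
#' @return An object of class `sbr_cycle`: a list with `trajectory`
#'   (data.frame: t_h, phase, V_l, S, X_st, X_ns, PHB, NH4, DO_aer, DO_reac,
#'   DO_in_meas, DO_out_meas (lagged sensor readings), OUR (mmol O2/L/h),
#'   OUR_meas (mg O2/L/min from the lagged pair), cum_fed_cmmol), `events`,
#'   `pulses` (a `pulse_log` or NULL), `state` (final), `balance` (carbon,
#'   electron and volume closure), and harvest totals.
#' @export
run_cycle <- function(scenario, state = NULL, seed = NULL,
                      dt_out_min = scenario$dt_out_min) {
  stopifnot(inherits(scenario, "sbr_scenario"))
  if (!is.null(seed)) set.seed(seed)
  kp <- scenario$kinetics
  rc <- scenario$reactor
  if (is.null(state)) state <- scenario$init
  stopifnot(inherits(state, "reactor_state"))

  rhs <- make_rhs(kp, rc)
  tau_res_min <- rc$V_reac / rc$Q_l_min

  env <- new.env(parent = emptyenv())
  env$traj <- list()
  env$events <- list()
  push_traj <- function(out, phase, V_now, cum_now) {
    df <- as.data.frame(out)
    names(df) <- c("t_h", .y_names, "OUR")
    df$phase <- phase
    df$V_l <- V_now
    df$OUR_meas <- pmax((df$DO_im - df$DO_om) / tau_res_min, 0)
    df$cum_fed_cmmol <- cum_now
    env$traj[[length(env$traj) + 1L]] <- df
  }
  add_event <- function(...) {
    env$events[[length(env$events) + 1L]] <- new_event_row(...)
  }

  y <- state_to_y(state, kp, rc)
  V <- state$V
  t_h <- 0
  cum_fed <- 0
  pulses <- NULL
  famine_onset_min <- NA_real_
  baseline_our <- NA_real_

  C0 <- carbon_amount(y, V)
  E0 <- electron_amount(y, V, kp)
  V0 <- V
  dt_out_h <- dt_out_min / 60

  for (ph in scenario$schedule) {
    # --- phase-start boluses
    if (!is.null(ph$feed_cmmol) && ph$feed_cmmol > 0) {
      vol <- if (!is.null(ph$feed_vol_l)) ph$feed_vol_l else
        ph$feed_cmmol / (1000 * 1.7)
      b <- bolus(y, V, vol, cmmol = ph$feed_cmmol)
      y <- b$y; V <- b$V
      cum_fed <- cum_fed + ph$feed_cmmol
      add_event(t_h, "carbon_feed", dV = vol, C_in = ph$feed_cmmol)
    }
    if (!is.null(ph$nutrient_vol_l) && ph$nutrient_vol_l > 0) {
      nh4 <- ph$nutrient_vol_l * ph$nutrient_nh4_mmol_l
      b <- bolus(y, V, ph$nutrient_vol_l, nh4_mmol = nh4)
      y <- b$y; V <- b$V
      add_event(t_h, "nutrient_feed", dV = ph$nutrient_vol_l, N_in = nh4)
    }

    dur_h <- ph$duration_min / 60
    if (dur_h > 1e-12) {
      if (isTRUE(ph$controller)) {
        cl <- run_feast_closed_loop(y, V, rhs, t_h, dur_h, scenario,
                                    tau_res_min, cum_fed, push_traj,
                                    add_event, ph$name)
        y <- cl$y; V <- cl$V
        cum_fed <- cl$cum_fed
        pulses <- cl$pulses
        famine_onset_min <- cl$famine_onset_min
        baseline_our <- cl$baseline
      } else {
        out <- integrate_span(y, V, rhs, t_h, dur_h, dt_out_h)
        push_traj(out, ph$name, V, cum_fed)
        y <- out[nrow(out), 1 + seq_along(.y_names)]
        names(y) <- .y_names
      }
      t_h <- t_h + dur_h
    }

    # --- phase-end actions
    if (!is.null(ph$withdraw_fraction) && ph$withdraw_fraction > 0) {
      st <- y_to_state(y, V, t_h)
      wd <- apply_withdrawal(st, ph$withdraw_fraction)
      h <- wd$harvested
      add_event(t_h, "withdrawal", dV = -h[["V_l"]],
                C_out = h[["S_cmmol"]] + h[["X_st_cmmol"]] +
                  h[["X_ns_cmmol"]] + h[["PHB_cmmol"]],
                N_out = h[["NH4_mmol"]],
                X_out = h[["X_st_cmmol"]] + h[["X_ns_cmmol"]],
                PHB_out = h[["PHB_cmmol"]])
      V <- wd$state$V
    }
    if (isTRUE(ph$settle) && !is.null(scenario$settling)) {
      st <- y_to_state(y, V, t_h)
      ss <- apply_settling_selection(st, scenario$settling)
      r <- ss$removed
      add_event(t_h, "settling_selection", dV = 0,
                C_out = r[["S_cmmol"]] + r[["X_st_cmmol"]] +
                  r[["X_ns_cmmol"]] + r[["PHB_cmmol"]],
                N_out = r[["NH4_mmol"]],
                X_out = r[["X_st_cmmol"]] + r[["X_ns_cmmol"]],
                PHB_out = r[["PHB_cmmol"]])
      y[["S"]] <- ss$state$S; y[["NH4"]] <- ss$state$NH4
      y[["X_st"]] <- ss$state$X_st; y[["X_ns"]] <- ss$state$X_ns
      y[["PHB"]] <- ss$state$PHB
    }
  }

  if (!length(env$traj)) {
    # event-only schedule: log the initial instant so downstream consumers
    # always see at least one row
    row <- matrix(c(0, state_to_y(state, kp, rc),
                    rate_vector(pmax(state_to_y(state, kp, rc)[1:5], 0),
                                kp)$OUR), nrow = 1)
    colnames(row) <- c("time", .y_names, "OUR")
    push_traj(row, scenario$schedule[[1]]$name, state$V, 0)
  }
  trajectory <- do.call(rbind, env$traj)
  rownames(trajectory) <- NULL
  trajectory <- trajectory[, c("t_h", "phase", "V_l", "S", "X_st", "X_ns",
                               "PHB", "NH4", "DO_a", "DO_r", "DO_im",
                               "DO_om", "OUR", "OUR_meas", "cum_fed_cmmol")]
  names(trajectory)[match(c("DO_a", "DO_r", "DO_im", "DO_om"),
                          names(trajectory))] <-
    c("DO_aer", "DO_reac", "DO_in_meas", "DO_out_meas")

  events <- if (length(env$events)) do.call(rbind, env$events) else
    empty_events()
  rownames(events) <- NULL

  Cend <- carbon_amount(y, V)
  Eend <- electron_amount(y, V, kp)
  C_in <- sum(events$C_in_cmmol)
  C_out <- sum(events$C_out_cmmol)
  co2 <- y[["CO2"]]; o2 <- y[["O2"]]
  carbon_err <- abs(C0 + C_in - Cend - C_out - co2) / max(C0 + C_in, 1)
  e_removed <- kp$gamma_S * sum(events$C_out_cmmol - events$X_out_cmmol -
                                  events$PHB_out_cmmol) +
    kp$gamma_X * sum(events$X_out_cmmol) +
    kp$gamma_P * sum(events$PHB_out_cmmol)
  electron_err <- abs(E0 + kp$gamma_S * C_in - Eend - e_removed - 4 * o2) /
    max(E0 + kp$gamma_S * C_in, 1)
  volume_err <- abs(V0 + sum(events$dV_l) - V)

  structure(list(
    trajectory = trajectory,
    events = events,
    pulses = pulses,
    state = y_to_state(y, V, t_h),
    cum_fed_cmmol = cum_fed,
    famine_onset_min = famine_onset_min,
    baseline_our = baseline_our,
    balance = list(carbon_rel_err = carbon_err,
                   electron_rel_err = electron_err,
                   volume_abs_err_l = volume_err,
                   co2_cmmol = unname(co2), o2_mmol = unname(o2)),
    harvest_phb_cmmol = sum(events$PHB_out_cmmol[events$event == "withdrawal"]),
    scenario_name = scenario$name,
    scenario = scenario),
    class = "sbr_cycle")
}

# closed-loop feast: baseline window, compulsive START, then per-sample
# control on the measured (noisy, lagged) OUR signal
run_feast_closed_loop <- function(y, V, rhs, t0_h, dur_h, scenario,
                                  tau_res_min, cum_fed, push_traj,
                                  add_event, phase_name) {
  cfg <- scenario$controller
  stopifnot(inherits(cfg, "controller_config"))
  sigma <- scenario$noise$do_sigma
  dt_min <- cfg$sample_interval_min
  dt_h <- dt_min / 60
  n_total <- floor(dur_h * 60 / dt_min)
  n_base <- max(2L, round(cfg$baseline_min / dt_min))
  t0_min <- t0_h * 60

  ctrl <- fd_controller(cfg)
  feed_vol <- function(dose) dose / (1000 * cfg$feed_conc_cmol_l)

  # --- baseline window (stable endogenous OUR before any feeding)
  out <- integrate_span(y, V, rhs, t0_h, n_base * dt_h, dt_h)
  push_traj(out, phase_name, V, cum_fed)
  y <- out[nrow(out), 1 + seq_along(.y_names)]
  names(y) <- .y_names
  base_samples <- pmax((out[-1, "DO_im"] - out[-1, "DO_om"] +
                          stats::rnorm(nrow(out) - 1L, 0, sigma)) /
                         tau_res_min, 0)
  baseline <- mean(utils::tail(base_samples, min(6, length(base_samples))))

  dose <- fd_start(ctrl, baseline, t0_min + n_base * dt_min)
  if (dose > 0) {
    b <- bolus(y, V, feed_vol(dose), cmmol = dose)
    y <- b$y; V <- b$V
    cum_fed <- cum_fed + dose
    add_event(t0_h + n_base * dt_h, "fd_pulse", dV = feed_vol(dose),
              C_in = dose)
  }

  # integrate in blocks of samples; controller decisions are still taken at
  # every sample (on the dense output), and a triggered dose rolls the state
  # back to the exact trigger sample before resuming
  terminated_at <- NA_real_
  block <- 8L
  i <- n_base
  while (i < n_total && is.na(terminated_at)) {
    nb <- min(block, n_total - i)
    out <- integrate_span(y, V, rhs, t0_h + i * dt_h, nb * dt_h, dt_h)
    stop_k <- nb
    acted <- FALSE
    for (k in seq_len(nb)) {
      yk <- out[k + 1L, 1 + seq_along(.y_names)]
      names(yk) <- .y_names
      smp <- max((yk[["DO_im"]] - yk[["DO_om"]] +
                    stats::rnorm(1, 0, sigma)) / tau_res_min, 0)
      act <- fd_step(ctrl, smp, t0_min + (i + k) * dt_min)
      if (act$action == "feed" || act$action == "terminate") {
        stop_k <- k
        acted <- TRUE
        break
      }
    }
    push_traj(out[2:(stop_k + 1L), , drop = FALSE], phase_name, V, cum_fed)
    y <- out[stop_k + 1L, 1 + seq_along(.y_names)]
    names(y) <- .y_names
    i <- i + stop_k
    if (acted && act$action == "feed") {
      b <- bolus(y, V, feed_vol(act$dose), cmmol = act$dose)
      y <- b$y; V <- b$V
      cum_fed <- cum_fed + act$dose
      add_event(t0_h + i * dt_h, "fd_pulse", dV = feed_vol(act$dose),
                C_in = act$dose)
    } else if (acted && act$action == "terminate") {
      terminated_at <- t0_min + i * dt_min
    }
  }

  # famine state reached (or window over): integrate the rest in one call
  remaining_h <- dur_h - i * dt_h
  if (remaining_h > 1e-12) {
    out <- integrate_span(y, V, rhs, t0_h + i * dt_h, remaining_h, dt_h)
    push_traj(out[-1, , drop = FALSE], phase_name, V, cum_fed)
    y <- out[nrow(out), 1 + seq_along(.y_names)]
    names(y) <- .y_names
  }

  list(y = y, V = V, cum_fed = cum_fed, pulses = pulse_log(ctrl),
       famine_onset_min = terminated_at, baseline = baseline)
}

#' @export
print.sbr_cycle <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<sbr_cycle> scenario '%s': %.1f h, %d trajectory points\n",
              x$scenario_name, max(tr$t_h), nrow(tr)))
  cat(sprintf("  PHB max %.1f Cmmol/L at %.2f h | fed %.1f Cmmol | final X %.1f Cmmol/L\n",
              max(tr$PHB), tr$t_h[which.max(tr$PHB)], x$cum_fed_cmmol,
              x$state$X_st + x$state$X_ns))
  cat(sprintf("  balance closure: carbon %.2e, electron %.2e (relative)\n",
              x$balance$carbon_rel_err, x$balance$electron_rel_err))
  invisible(x)
}

#' @export
summary.sbr_cycle <- function(object, ...) {
  print(object)
  m <- try(cycle_metrics(object), silent = TRUE)
  if (!inherits(m, "try-error")) print(m)
  invisible(object)
}
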