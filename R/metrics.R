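# Cycle performance metrics: specific rates, storage yield, feast length,
# volumetric productivity and the feast/famine ratio, computed either from
# simulated trajectories or from sampled measurement tables.

#' Specific acetate uptake rate
#'
#' q_AC = Ac / (X t): acetate consumed over the feast divided by the active
#' biomass present and the feast duration. Amounts and biomass must share a
#' basis (both absolute Cmmol or both Cmmol/L).
#'
#' @param ac_consumed acetate consumed, Cmmol (or Cmmol/L).
#' @param x active biomass, Cmmol (or Cmmol/L), > 0.
#' @param t_h feast duration, h, > 0.
#' @return Rate in Cmol/Cmol/h.
#' @export
specific_uptake_rate <- function(ac_consumed, x, t_h) {
  if (any(x <= 0) || any(t_h <= 0))
    stop("undefined rate: biomass and duration must be positive")
  if (any(ac_consumed < 0)) stop("consumed amount must be non-negative")
  ac_consumed / (x * t_h)
}

#' Specific PHB storage rate
#'
#' q_P = PHB / (X t), on the same basis as [specific_uptake_rate()].
#'
#' @param phb_formed PHB formed over the feast, Cmmol (or Cmmol/L).
#' @inheritParams specific_uptake_rate
#' @return Rate in Cmol/Cmol/h.
#' @export
specific_storage_rate <- function(phb_formed, x, t_h) {
  if (any(x <= 0) || any(t_h <= 0))
    stop("undefined rate: biomass and duration must be positive")
  if (any(phb_formed < 0)) stop("formed amount must be non-negative")
  phb_formed / (x * t_h)
}

#' Storage yield
#'
#' Y_P/S = q_P / q_AC, the fraction of consumed acetate carbon stored as
#' PHB.
#'
#' @param q_p specific PHB storage rate.
#' @param q_ac specific acetate uptake rate, > 0.
#' @return Yield in Cmol PHB/Cmol Ac.
#' @export
storage_yield <- function(q_p, q_ac) {
  if (any(q_ac <= 0)) stop("q_AC must be positive")
  q_p / q_ac
}

#' Feast length implied by an acetate budget
#'
#' Inverts q_AC = Ac / (X t): t = Ac / (q_AC X).
#'
#' @param ac_total total acetate fed, Cmmol (or Cmmol/L).
#' @param q_ac specific uptake rate, Cmol/Cmol/h, > 0.
#' @param x active biomass on the same basis, > 0.
#' @return Feast length in h.
#' @export
feast_length_from_budget <- function(ac_total, q_ac, x) {
  if (any(q_ac <= 0) || any(x <= 0)) stop("q_AC and X must be positive")
  if (any(ac_total < 0)) stop("budget must be non-negative")
  ac_total / (q_ac * x)
}

#' Volumetric PHB productivity
#'
#' Stored (harvested) PHB divided by working volume and elapsed time.
#'
#' @param phb_g harvested PHB, g.
#' @param v_l working volume, L.
#' @param days elapsed time, days.
#' @return g PHB/L/day.
#' @export
volumetric_productivity <- function(phb_g, v_l, days) {
  if (any(v_l <= 0) || any(days <= 0)) stop("volume and time must be positive")
  if (any(phb_g < 0)) stop("harvested mass must be non-negative")
  phb_g / (v_l * days)
}

#' Feast-to-famine duration ratio
#'
#' @param t_feast_h,t_famine_h phase lengths, h; famine must be positive.
#' @return Dimensionless ratio.
#' @export
tfe_tfa <- function(t_feast_h, t_famine_h) {
  if (any(t_famine_h <= 0)) stop("famine length must be positive")
  if (any(t_feast_h < 0)) stop("feast length must be non-negative")
  t_feast_h / t_famine_h
}

new_cycle_metrics <- function(lst) structure(lst, class = "cycle_metrics")

#' @export
print.cycle_metrics <- function(x, ...) {
  cat("<cycle_metrics>\n")
  cat(sprintf("  time of PHB max:   %.2f h\n", x$t_phb_max_h))
  cat(sprintf("  PHB max:           %.1f Cmmol/L (%.1f wt%%)\n",
              x$phb_max_cmmol_l, x$phb_max_wt))
  cat(sprintf("  q_AC:              %.3f Cmol Ac/Cmol X/h\n", x$q_ac))
  cat(sprintf("  q_P:               %.3f Cmol PHB/Cmol X/h\n", x$q_p))
  cat(sprintf("  Y_P/S:             %.3f Cmol/Cmol\n", x$y_ps))
  if (!is.null(x$q_ac_max) && is.finite(x$q_ac_max))
    cat(sprintf("  q_AC,max / q_P,max (30-min window): %.3f / %.3f\n",
                x$q_ac_max, x$q_p_max))
  if (is.finite(x$vol_prod_g_l_d))
    cat(sprintf("  volumetric productivity: %.2f g PHB/L/day\n",
                x$vol_prod_g_l_d))
  if (is.finite(x$tfe_tfa))
    cat(sprintf("  t_Fe/t_Fa:         %.2f\n", x$tfe_tfa))
  invisible(x)
}

#' @export
as.data.frame.cycle_metrics <- function(x, ...) {
  as.data.frame(unclass(x)[vapply(unclass(x), is.numeric, logical(1))])
}

# sliding-window maximum specific rate from cumulative series
window_max_rate <- function(t_h, cum, x_cmmol, window_h = 0.5) {
  n <- length(t_h)
  if (n < 3) return(NA_real_)
  best <- 0
  j <- 1L
  for (i in seq_len(n)) {
    while (t_h[i] - t_h[j] > window_h) j <- j + 1L
    if (i > j) {
      r <- (cum[i] - cum[j]) / (t_h[i] - t_h[j]) / x_cmmol
      if (is.finite(r) && r > best) best <- r
    }
  }
  best
}

#' Performance metrics of one simulated cycle
#'
#' Computes the standard cycle record from an [run_cycle()] result: the
#' feast length is taken as the time of the sampled PHB maximum; acetate
#' consumed is total carbon fed during the feast plus the drop in residual
#' acetate; the biomass basis is the mean active-biomass amount over the
#' feast. Aggregate rates use amounts (Cmmol), so dilution by feed volumes
#' is handled exactly. Sliding 30-min window maxima of both specific rates
#' are reported alongside the feast aggregates.
#'
#' @param cycle an `sbr_cycle` from [run_cycle()].
#' @param feast_phase name of the feast phase in the trajectory.
#' @return An object of class `cycle_metrics`.
#' @export
cycle_metrics <- function(cycle, feast_phase = NULL) {
  stopifnot(inherits(cycle, "sbr_cycle"))
  tr <- cycle$trajectory
  if (is.null(feast_phase)) feast_phase <- tr$phase[1]
  fe <- tr[tr$phase == feast_phase, ]
  if (!nrow(fe)) stop("no feast phase '", feast_phase, "' in trajectory")

  phb_amt <- fe$PHB * fe$V_l
  j <- which.max(phb_amt)
  t_feast <- fe$t_h[j] - fe$t_h[1]
  if (t_feast <= 0) stop("missing feast boundary: PHB maximum at feast start")

  x_amt <- (fe$X_st + fe$X_ns) * fe$V_l
  x_basis <- mean(x_amt[seq_len(j)])
  fed <- fe$cum_fed_cmmol[j] - fe$cum_fed_cmmol[1] +
    sum(cycle$events$C_in_cmmol[cycle$events$event == "carbon_feed" &
                                  cycle$events$t_h <= fe$t_h[1] + 1e-9])
  s_amt <- fe$S * fe$V_l
  consumed <- fed + s_amt[1] - s_amt[j]
  phb_formed <- phb_amt[j] - phb_amt[1]

  q_ac <- specific_uptake_rate(consumed, x_basis, t_feast)
  q_p <- specific_storage_rate(phb_formed, x_basis, t_feast)

  cyc_h <- max(tr$t_h) - min(tr$t_h)
  t_famine <- cyc_h - t_feast
  v_work <- cycle$scenario$reactor$V_work
  harv_g <- cmol_to_mass(cycle$harvest_phb_cmmol, cmol_mass(phb_formula()))
  vol_prod <- if (cycle$harvest_phb_cmmol > 0 && cyc_h > 0)
    volumetric_productivity(harv_g, v_work, cyc_h / 24) else NA_real_

  new_cycle_metrics(list(
    t_phb_max_h = t_feast,
    phb_max_cmmol_l = fe$PHB[j],
    phb_max_wt = phb_weight_percent(fe$PHB[j], fe$X_st[j] + fe$X_ns[j]),
    q_ac = q_ac,
    q_p = q_p,
    y_ps = storage_yield(q_p, q_ac),
    q_ac_max = window_max_rate(fe$t_h, fe$cum_fed_cmmol + s_amt[1] - s_amt,
                               x_basis),
    q_p_max = window_max_rate(fe$t_h, phb_amt, x_basis),
    ac_consumed_cmmol = consumed,
    x_cmmol = x_basis,
    vol_prod_g_l_d = vol_prod,
    tfe_tfa = if (t_famine > 0) tfe_tfa(t_feast, t_famine) else NA_real_,
    feast_phase = feast_phase))
}

#' Metrics from an offline measurement table
#'
#' The analysis path for sampled (e.g. 50-min interval) chemistry tables
#' with columns `t_min`, `HAc_g_l`, `PHB_g_l`, `VSS_g_l`, `NH4_mmol_l`.
#' Active biomass is VSS minus PHB; concentrations are converted to
#' Cmmol/L; the feast window ends at the sampled PHB maximum (or at
#' `feast_end_min` if given); rates come from endpoint differences.
#'
#' @param table measurement data.frame.
#' @param fed_cmmol_l total acetate fed during the feast, Cmmol/L
#'   (required for pulsed-fed cycles where the residual-acetate drop does
#'   not reflect the consumption; defaults to 0, i.e. consumption equals
#'   the drop in measured HAc).
#' @param feast_end_min optional feast boundary; default: time of the PHB
#'   maximum.
#' @param cycle_h nominal cycle length used for the feast/famine ratio.
#' @return An object of class `cycle_metrics`. If the PHB column is all
#'   zero, `q_p = 0` and the yield is `NA` (flagged undefined).
#' @export
metrics_from_samples <- function(table, fed_cmmol_l = 0,
                                 feast_end_min = NULL, cycle_h = 18) {
  need <- c("t_min", "HAc_g_l", "PHB_g_l", "VSS_g_l", "NH4_mmol_l")
  if (!all(need %in% names(table)))
    stop("measurement table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table) < 2) stop("measurement table too short")
  tb <- table[order(table$t_min), ]

  phb <- mass_to_cmol(pmax(tb$PHB_g_l, 0), cmol_mass(phb_formula()))
  hac <- mass_to_cmol(pmax(tb$HAc_g_l, 0), cmol_mass(acetate_formula()))
  x <- mass_to_cmol(active_biomass(pmax(tb$VSS_g_l, 0),
                                   pmin(pmax(tb$PHB_g_l, 0), pmax(tb$VSS_g_l, 0))),
                    cmol_mass(biomass_formula()))

  j <- if (is.null(feast_end_min)) which.max(phb) else
    max(which(tb$t_min <= feast_end_min))
  t_feast <- (tb$t_min[j] - tb$t_min[1]) / 60
  if (!is.finite(t_feast) || t_feast <= 0)
    stop("missing feast boundary: cannot locate the PHB maximum")

  x_basis <- mean(x[seq_len(j)])
  consumed <- max(fed_cmmol_l + hac[1] - hac[j], 0)
  phb_formed <- max(phb[j] - phb[1], 0)

  all_zero_phb <- all(tb$PHB_g_l <= 0)
  q_ac <- if (consumed > 0) specific_uptake_rate(consumed, x_basis, t_feast)
    else 0
  q_p <- specific_storage_rate(phb_formed, x_basis, t_feast)

  new_cycle_metrics(list(
    t_phb_max_h = t_feast,
    phb_max_cmmol_l = phb[j],
    phb_max_wt = phb_weight_percent(phb[j], x[j]),
    q_ac = q_ac,
    q_p = if (all_zero_phb) 0 else q_p,
    y_ps = if (all_zero_phb || q_ac <= 0) NA_real_ else
      storage_yield(q_p, q_ac),
    q_ac_max = NA_real_, q_p_max = NA_real_,
    ac_consumed_cmmol = consumed,
    x_cmmol = x_basis,
    vol_prod_g_l_d = NA_real_,
    tfe_tfa = if (cycle_h > t_feast) tfe_tfa(t_feast, cycle_h - t_feast)
      else NA_real_,
    feast_phase = "feast"))
}
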