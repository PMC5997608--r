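# Diagnostic base-graphics plots for simulated cycles and enrichments.

#' Plot a simulated SBR cycle
#'
#' Three stacked panels over the feast (or the whole cycle): DO and OUR
#' (anti-phase signals), the cumulative-feed staircase with residual
#' acetate, and the PHB / biomass / ammonium trajectories.
#'
#' @param x an `sbr_cycle`.
#' @param feast_only restrict the time axis to the first phase.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.sbr_cycle <- function(x, feast_only = FALSE, ...) {
  tr <- x$trajectory
  if (feast_only) tr <- tr[tr$phase == tr$phase[1], ]
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 4), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))

  graphics::plot(tr$t_h, tr$DO_reac, type = "l", col = "firebrick",
                 xlab = "", ylab = "DO (mg/L)",
                 main = sprintf("scenario '%s'", x$scenario_name))
  graphics::par(new = TRUE)
  graphics::plot(tr$t_h, tr$OUR_meas, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4); graphics::mtext("OUR (mg O2/L/min)", 4, 2)
  graphics::legend("topright", c("DO out", "OUR"), lty = 1, bty = "n",
                   col = c("firebrick", "steelblue"))

  graphics::plot(tr$t_h, tr$cum_fed_cmmol, type = "s", col = "darkgreen",
                 xlab = "", ylab = "cumulative feed (Cmmol)")
  graphics::par(new = TRUE)
  graphics::plot(tr$t_h, tr$S, type = "l", col = "grey40", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4); graphics::mtext("acetate (Cmmol/L)", 4, 2)

  graphics::matplot(tr$t_h, cbind(tr$PHB, tr$X_st + tr$X_ns, tr$NH4 * 10),
                    type = "l", lty = 1,
                    col = c("darkorange", "black", "purple"),
                    xlab = "time (h)", ylab = "Cmmol/L")
  graphics::legend("topright", c("PHB", "X", "NH4 x10 (mmol/L)"), lty = 1,
                   col = c("darkorange", "black", "purple"), bty = "n")
  invisible(x)
}

#' Plot an enrichment run
#'
#' MLSS-equivalent at the end of the feast and the maximum PHB weight
#' fraction per cycle, with the detected steady-state day marked.
#'
#' @param x an `sbr_enrichment`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.sbr_enrichment <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  graphics::plot(x$day, x$mlss_g_l, type = "b", pch = 16, cex = 0.6,
                 xlab = "", ylab = "MLSS (g/L)",
                 main = attr(x, "scenario_name"))
  graphics::plot(x$day, x$phb_max_wt, type = "b", pch = 16, cex = 0.6,
                 xlab = "day", ylab = "PHB max (wt%)")
  sd <- attr(x, "steady_day")
  if (!is.na(sd)) graphics::abline(v = sd, lty = 2, col = "grey50")
  invisible(x)
}
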