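# End-to-end pipeline commands: simulate a cycle, run an enrichment, or
# analyse a measurement table, writing CSV/JSON artefacts. These functions
# back the thin command-line wrapper in inst/cli/.

#' Simulate one cycle and write its artefacts
#'
#' Runs one cycle of the chosen scenario and writes `trajectory.csv`,
#' `events.csv`, `pulses.csv` (if feed-on-demand control ran) and
#' `metrics.json` into `out_dir`.
#'
#' @param scenario preset name or an [sbr_scenario()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @param controller `"preset"` keeps the scenario's feeding regimen;
#'   `"single-pulse"` replaces the feast controller by one bolus of
#'   `single_pulse_cmmol_l`; `"none"` removes all carbon feeding.
#' @param single_pulse_cmmol_l bolus size for `"single-pulse"`, Cmmol per
#'   litre of working volume.
#' @param kinetics a [kinetic_params()].
#' @return The `sbr_cycle`, invisibly; side effect: files in `out_dir`.
#' @export
cmd_simulate <- function(scenario = "FD", out_dir = ".", seed = 1,
                         controller = c("preset", "single-pulse", "none"),
                         single_pulse_cmmol_l = 124.5,
                         kinetics = kinetic_params()) {
  controller <- match.arg(controller)
  sc <- if (is.character(scenario))
    scenario_preset(scenario, kinetics = kinetics) else scenario
  stopifnot(inherits(sc, "sbr_scenario"))
  if (controller != "preset") {
    ph <- sc$schedule[[1]]
    ph$controller <- NULL
    if (controller == "single-pulse") {
      dose <- single_pulse_cmmol_l * sc$reactor$V_work
      ph$feed_cmmol <- dose
      ph$feed_vol_l <- dose / (1000 * 1.7)
    }
    sched <- sc$schedule
    sched[[1]] <- ph
    sc$schedule <- cycle_schedule(sched)
    sc$controller <- NULL
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cyc <- run_cycle(sc, seed = seed)
  utils::write.csv(cyc$trajectory, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(cyc$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(cyc$pulses))
    utils::write.csv(as.data.frame(cyc$pulses),
                     file.path(out_dir, "pulses.csv"), row.names = FALSE)
  m <- cycle_metrics(cyc)
  jsonlite::write_json(
    c(as.list(as.data.frame(m)),
      list(scenario = sc$name, seed = seed,
           balance = cyc$balance[c("carbon_rel_err", "electron_rel_err")])),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(cyc)
}

#' Run an enrichment simulation and write the daily summary
#'
#' @param scenario `"SBR1"` or `"SBR2"` (or a custom [sbr_scenario()]).
#' @param n_days simulated days; 0 produces an empty summary.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param ... passed to [run_enrichment()].
#' @return The `sbr_enrichment` data.frame, invisibly; side effect:
#'   `enrichment.csv` in `out_dir`.
#' @export
cmd_enrich <- function(scenario = "SBR1", n_days = 30, out_dir = ".",
                       seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enr <- if (n_days > 0)
    run_enrichment(scenario, n_days = n_days, seed = seed, ...)
  else structure(data.frame(cycle = integer(0), day = numeric(0),
                            mlss_g_l = numeric(0),
                            phb_max_cmmol_l = numeric(0),
                            phb_max_wt = numeric(0),
                            x_total_cmmol_l = numeric(0),
                            storer_frac = numeric(0),
                            settling_on = logical(0)),
                 steady_day = NA_real_, scenario_name = scenario,
                 class = c("sbr_enrichment", "data.frame"))
  utils::write.csv(as.data.frame(enr), file.path(out_dir, "enrichment.csv"),
                   row.names = FALSE)
  invisible(enr)
}

#' Analyse a measurement CSV into a cycle-metrics record
#'
#' @param csv_path path to a measurement table (columns t_min, HAc_g_l,
#'   PHB_g_l, VSS_g_l, NH4_mmol_l; `#` comment lines allowed).
#' @param fed_cmmol_l,feast_end_min passed to [metrics_from_samples()].
#' @param out optional path for a JSON copy of the record.
#' @return A `cycle_metrics` object.
#' @export
cmd_metrics <- function(csv_path, fed_cmmol_l = 0, feast_end_min = NULL,
                        out = NULL) {
  tb <- tryCatch(utils::read.csv(csv_path, comment.char = "#"),
                 error = function(e)
                   stop("cannot parse measurement CSV '", csv_path, "': ",
                        conditionMessage(e)))
  m <- metrics_from_samples(tb, fed_cmmol_l = fed_cmmol_l,
                            feast_end_min = feast_end_min)
  if (!is.null(out))
    jsonlite::write_json(as.list(as.data.frame(m)), out, auto_unbox = TRUE,
                         digits = NA)
  m
}

#' Write the synthetic fixture suite
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return Named vector of file paths, invisibly.
#' @export
cmd_fixtures <- function(out_dir = ".", seed = 1) {
  make_fixture_suite(out_dir, seed = seed)
}
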