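# Scenario container and the four shipped presets: the two start-up SBRs
# (with and without settling selection), the operational feed-on-demand
# cycle, and the batch storage-capacity experiment.

#' Simulation scenario
#'
#' Bundles reactor geometry, kinetics, a cycle schedule, an initial state
#' and optional controller/settling/noise settings into one validated
#' object consumed by [run_cycle()] and [run_enrichment()].
#'
#' @param name scenario label.
#' @param reactor a [reactor_config()].
#' @param kinetics a [kinetic_params()].
#' @param schedule a [cycle_schedule()].
#' @param init a [reactor_state()].
#' @param controller a [controller_config()] or `NULL`.
#' @param settling a [settling_params()] or `NULL` (no settling selection).
#' @param noise list with `do_sigma`: additive Gaussian noise on each DO
#'   sensor reading, mg/L.
#' @param dt_out_min default trajectory output resolution, minutes.
#' @return An object of class `sbr_scenario`.
#' @export
sbr_scenario <- function(name, reactor = reactor_config(),
                         kinetics = kinetic_params(),
                         schedule, init, controller = NULL, settling = NULL,
                         noise = list(do_sigma = 0.05), dt_out_min = 0.5) {
  stopifnot(inherits(reactor, "reactor_config"),
            inherits(kinetics, "kinetic_params"),
            inherits(schedule, "cycle_schedule"),
            inherits(init, "reactor_state"))
  if (!is.null(controller)) stopifnot(inherits(controller, "controller_config"))
  if (!is.null(settling)) stopifnot(inherits(settling, "settling_params"))
  has_ctrl_phase <- any(vapply(schedule, function(p) isTRUE(p$controller),
                               logical(1)))
  if (has_ctrl_phase && is.null(controller))
    stop("schedule has a controller phase but no controller_config given")
  structure(list(name = name, reactor = reactor, kinetics = kinetics,
                 schedule = schedule, init = init, controller = controller,
                 settling = settling, noise = noise,
                 dt_out_min = dt_out_min),
            class = "sbr_scenario")
}

#' @export
print.sbr_scenario <- function(x, ...) {
  cat(sprintf("<sbr_scenario> '%s': %d phases, %.1f h cycle%s%s\n", x$name,
              length(x$schedule), schedule_length_h(x$schedule),
              if (!is.null(x$controller)) ", feed-on-demand control" else "",
              if (!is.null(x$settling)) ", settling selection" else ""))
  invisible(x)
}

# nutrient feed strength: 2.3 L dosed into 0.85 L residue gives ~4.7 mmol/L
.nutrient_vol_l <- 2.3
.nutrient_nh4_mmol_l <- 6.44

#' Built-in scenario presets
#'
#' `"SBR1"`: 18-h start-up cycle with double growth limitation and settling
#' selection (360 min feast with a single acetate pulse of 124.5 Cmmol/L of
#' working volume and 3/4 withdrawal at its end, 25 min settling selection,
#' 695 min famine opened by the nutrient feed). `"SBR2"`: the same without
#' settling selection (720 min famine). `"FD"`: the operational cycle with
#' feed-on-demand control under a 182 Cmmol/L acetate budget. `"batch"`:
#' a 12-h ammonium-free accumulation run in the 4-L respirometer fed on
#' demand from 1.5 M sodium acetate.
#'
#' @param name preset name.
#' @param kinetics a [kinetic_params()].
#' @param overrides named list of scenario components to replace (shallow
#'   merge; each value must be a valid component object, e.g. a
#'   `controller_config`).
#' @return An [sbr_scenario()].
#' @export
scenario_preset <- function(name = c("SBR1", "SBR2", "FD", "batch"),
                            kinetics = kinetic_params(),
                            overrides = list()) {
  name <- match.arg(name)
  rc <- reactor_config()
  v_work <- rc$V_work
  feed_conc <- 1.7  # 0.85 M sodium acetate, Cmol/L

  startup_feast <- function() list(
    name = "feast", duration_min = 360,
    feed_cmmol = 124.5 * v_work,
    feed_vol_l = 124.5 * v_work / (1000 * feed_conc),
    withdraw_fraction = 0.75)
  famine <- function(dur) list(
    name = "famine", duration_min = dur,
    nutrient_vol_l = .nutrient_vol_l,
    nutrient_nh4_mmol_l = .nutrient_nh4_mmol_l)

  carbon_vol <- 124.5 * v_work / (1000 * feed_conc)  # 250 mL of 0.85 M NaAc
  inoculum <- reactor_state(V = v_work - carbon_vol,
                            S = 0, X_st = 10.4, X_ns = 198.1, PHB = 2,
                            NH4 = 1.0)

  sc <- switch(name,
    SBR1 = sbr_scenario(
      name = "SBR1", reactor = rc, kinetics = kinetics,
      schedule = cycle_schedule(
        startup_feast(),
        list(name = "settling", duration_min = 25, settle = TRUE),
        famine(695)),
      init = inoculum,
      settling = settling_params()),
    SBR2 = sbr_scenario(
      name = "SBR2", reactor = rc, kinetics = kinetics,
      schedule = cycle_schedule(startup_feast(), famine(720)),
      init = inoculum),
    FD = sbr_scenario(
      name = "FD", reactor = rc, kinetics = kinetics,
      schedule = cycle_schedule(
        list(name = "feast", duration_min = 360, controller = TRUE,
             withdraw_fraction = 0.75),
        list(name = "settling", duration_min = 25, settle = TRUE),
        famine(695)),
      init = reactor_state(V = 3.15, S = 0, X_st = 33.5, X_ns = 0.1,
                           PHB = 0.5, NH4 = 0.12),
      controller = controller_config(budget_total = 182 * v_work,
                                     feed_conc_cmol_l = feed_conc),
      settling = settling_params()),
    batch = sbr_scenario(
      name = "batch",
      reactor = reactor_config(V_work = 4),
      kinetics = kinetics,
      schedule = cycle_schedule(
        list(name = "accumulation", duration_min = 720, controller = TRUE)),
      init = reactor_state(V = 4, S = 0, X_st = 31, X_ns = 0, PHB = 0.5,
                           NH4 = 0),
      controller = controller_config(budget_total = 260 * 4,
                                     pulse_dose = 120,
                                     feed_conc_cmol_l = 3.0))
  )
  for (nm in names(overrides)) sc[[nm]] <- overrides[[nm]]
  do.call(sbr_scenario, sc[c("name", "reactor", "kinetics", "schedule",
                             "init", "controller", "settling", "noise",
                             "dt_out_min")])
}

## ---- YAML configuration I/O ---------------------------------------------

#' Write or read a scenario as YAML
#'
#' The YAML layout mirrors the scenario components: blocks `reactor`,
#' `kinetics`, `schedule`, `init`, `controller`, `settling`, `noise`.
#'
#' @param scenario an [sbr_scenario()].
#' @param path file path.
#' @return `read_scenario()` returns an [sbr_scenario()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sbr_scenario"))
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  kin <- unclass(scenario$kinetics)
  kin <- kin[setdiff(names(kin), c("gamma_S", "gamma_P", "gamma_X"))]
  cfg <- list(name = scenario$name,
              reactor = strip(scenario$reactor),
              kinetics = kin,
              schedule = lapply(scenario$schedule, unclass),
              init = strip(scenario$init),
              controller = strip(scenario$controller),
              settling = strip(scenario$settling),
              noise = scenario$noise,
              dt_out_min = scenario$dt_out_min)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("name", "reactor", "kinetics", "schedule", "init")
  if (!all(need %in% names(cfg)))
    stop("scenario YAML must contain: ", paste(need, collapse = ", "))
  init <- cfg$init
  init$t <- NULL
  init <- init[!vapply(init, is.null, logical(1))]
  sbr_scenario(
    name = cfg$name,
    reactor = do.call(reactor_config, cfg$reactor),
    kinetics = do.call(kinetic_params, cfg$kinetics),
    schedule = cycle_schedule(cfg$schedule),
    init = do.call(reactor_state, init),
    controller = if (!is.null(cfg$controller))
      do.call(controller_config, cfg$controller),
    settling = if (!is.null(cfg$settling))
      do.call(settling_params, cfg$settling),
    noise = if (!is.null(cfg$noise)) cfg$noise else list(do_sigma = 0.05),
    dt_out_min = if (!is.null(cfg$dt_out_min)) cfg$dt_out_min else 0.5)
}
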