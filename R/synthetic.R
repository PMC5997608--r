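# Synthetic measurement generator: turns simulated trajectories into the
# kind of data the analysis path consumes in practice - offline chemistry
# at ~50-min intervals with multiplicative assay noise, and a 0.5-min DO
# log - without any laboratory input.

#' Sampling plan for synthetic measurements
#'
#' @param offline_interval_min spacing of the offline chemistry samples,
#'   minutes.
#' @param do_interval_min spacing of the DO log, minutes.
#' @param cv multiplicative coefficients of variation per analyte, named
#'   `HAc`, `PHB`, `VSS`, `NH4` (defaults reflect routine GC and
#'   gravimetric/colorimetric assay precision).
#' @param do_sigma additive DO sensor noise, mg/L.
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(offline_interval_min = 50, do_interval_min = 0.5,
                          cv = c(HAc = 0.03, PHB = 0.04, VSS = 0.03,
                                 NH4 = 0.05),
                          do_sigma = 0.05) {
  if (offline_interval_min <= 0 || do_interval_min <= 0)
    stop("sampling intervals must be positive")
  need <- c("HAc", "PHB", "VSS", "NH4")
  if (!all(need %in% names(cv))) stop("cv needs entries HAc, PHB, VSS, NH4")
  if (any(cv < 0) || do_sigma < 0) stop("noise levels must be non-negative")
  structure(list(offline_interval_min = offline_interval_min,
                 do_interval_min = do_interval_min,
                 cv = cv[need], do_sigma = do_sigma),
            class = "sampling_plan")
}

#' Sample a simulated trajectory as offline measurements plus a DO log
#'
#' Interpolates the trajectory at the offline grid, converts to laboratory
#' units (HAc, PHB and VSS in g/L with VSS = biomass + PHB; ammonium in
#' mmol/L) and applies multiplicative Gaussian noise per analyte; the DO
#' log carries additive sensor noise. A pure function of
#' (trajectory, plan, seed): with all CVs zero the table equals the
#' interpolated trajectory exactly.
#'
#' @param cycle an `sbr_cycle` from [run_cycle()], or its trajectory
#'   data.frame.
#' @param plan a [sampling_plan()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list with `measurements` (data.frame: t_min, HAc_g_l, PHB_g_l,
#'   VSS_g_l, NH4_mmol_l) and `do_log` (data.frame: t_min, DO_in, DO_out).
#' @export
sample_trajectory <- function(cycle, plan = sampling_plan(), seed = NULL) {
  stopifnot(inherits(plan, "sampling_plan"))
  tr <- if (inherits(cycle, "sbr_cycle")) cycle$trajectory else cycle
  if (is.null(tr) || !nrow(tr)) stop("empty trajectory")
  if (!is.null(seed)) set.seed(seed)

  t_min <- tr$t_h * 60
  grid <- seq(min(t_min), max(t_min), by = plan$offline_interval_min)
  # integrator round-off can leave concentrations at -1e-12; clip at zero
  ip <- function(v) pmax(stats::approx(t_min, v, xout = grid,
                                       ties = "ordered")$y, 0)

  phb_g <- cmol_to_mass(ip(tr$PHB), cmol_mass(phb_formula()))
  x_g <- cmol_to_mass(ip(tr$X_st) + ip(tr$X_ns), cmol_mass(biomass_formula()))
  hac_g <- cmol_to_mass(ip(tr$S), cmol_mass(acetate_formula()))
  nh4 <- ip(tr$NH4)

  noisy <- function(v, cv) if (cv > 0)
    pmax(v * (1 + stats::rnorm(length(v), 0, cv)), 0) else v
  phb_n <- noisy(phb_g, plan$cv[["PHB"]])
  meas <- data.frame(
    t_min = grid,
    HAc_g_l = noisy(hac_g, plan$cv[["HAc"]]),
    PHB_g_l = phb_n,
    VSS_g_l = pmax(noisy(x_g, plan$cv[["VSS"]]) + phb_n, phb_n),
    NH4_mmol_l = noisy(nh4, plan$cv[["NH4"]]))

  do_grid <- seq(min(t_min), max(t_min), by = plan$do_interval_min)
  ipd <- function(v) stats::approx(t_min, v, xout = do_grid,
                                   ties = "ordered")$y
  addn <- function(v) if (plan$do_sigma > 0)
    v + stats::rnorm(length(v), 0, plan$do_sigma) else v
  do_log <- data.frame(t_min = do_grid,
                       DO_in = addn(ipd(tr$DO_aer)),
                       DO_out = addn(ipd(tr$DO_reac)))
  list(measurements = meas, do_log = do_log)
}

write_fixture_csv <- function(df, path, scenario, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scenario=%s seed=%d generator=phbsbr %s",
                     scenario, seed,
                     as.character(utils::packageVersion("phbsbr"))), con)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  path
}

#' Read a fixture CSV written by [make_fixture_suite()]
#' @param path file path.
#' @return data.frame (the metadata comment line is skipped).
#' @export
read_fixture_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Generate the bundled synthetic fixture suite
#'
#' Simulates one cycle of each scenario (start-up SBR, feed-on-demand,
#' batch accumulation), samples it with the default plan and writes small
#' CSV fixtures (measurement tables plus the FD pulse log). Byte-identical
#' for a given seed.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param kinetics kinetic parameter set used for all scenarios.
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1, kinetics = kinetic_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan <- sampling_plan()
  paths <- c()
  scens <- c("SBR1", "FD", "batch")
  for (i in seq_along(scens)) {
    nm <- scens[i]
    cyc <- run_cycle(scenario_preset(nm, kinetics = kinetics),
                     seed = seed + i, dt_out_min = 2)
    smp <- sample_trajectory(cyc, plan, seed = seed + 100 + i)
    p <- file.path(dir, sprintf("%s_measurements.csv", tolower(nm)))
    write_fixture_csv(smp$measurements, p, nm, seed)
    paths[paste0(tolower(nm), "_measurements")] <- p
    if (nm == "FD") {
      p2 <- file.path(dir, "fd_pulses.csv")
      write_fixture_csv(as.data.frame(cyc$pulses), p2, nm, seed)
      paths["fd_pulses"] <- p2
    }
  }
  invisible(paths)
}
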