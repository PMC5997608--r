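# Shared simulated objects, computed once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# full feed-on-demand cycle, sensor noise off
fd_cycle_clean <- function() memo("fd_clean", {
  sc <- scenario_preset("FD")
  sc$noise$do_sigma <- 0
  run_cycle(sc, seed = 1)
})

# full feed-on-demand cycle with default sensor noise
fd_cycle_noisy <- function() memo("fd_noisy", {
  run_cycle(scenario_preset("FD"), seed = 42)
})

# one start-up cycle with settling selection
sbr1_cycle <- function() memo("sbr1", {
  run_cycle(scenario_preset("SBR1"), seed = 3, dt_out_min = 2)
})

# feast-only scenario builders used by the pulsed-vs-single-pulse checks
feast_only_fd <- function(kinetics = kinetic_params()) {
  sc <- scenario_preset("FD", kinetics = kinetics)
  sc$noise$do_sigma <- 0
  ph <- sc$schedule[[1]]
  ph$withdraw_fraction <- NULL
  sc$schedule <- cycle_schedule(list(ph))
  sc$settling <- NULL
  sc
}

feast_only_single_pulse <- function(kinetics = kinetic_params(),
                                    dose_cmmol_l = 182) {
  sc <- feast_only_fd(kinetics)
  ph <- sc$schedule[[1]]
  ph$controller <- NULL
  ph$feed_cmmol <- dose_cmmol_l * sc$reactor$V_work
  ph$feed_vol_l <- ph$feed_cmmol / 1700
  sc$schedule <- cycle_schedule(list(ph))
  sc$controller <- NULL
  sc
}

# random normalised elemental formula for property tests
random_formula <- function() {
  elemental_formula(C = 1, H = stats::runif(1, 0, 3),
                    O = stats::runif(1, 0, 1.5), N = stats::runif(1, 0, 0.5))
}
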