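# phbsbr

Simulation and analysis of a sequencing batch reactor (SBR) that couples
the **enrichment** of polyhydroxybutyrate (PHB)-storing mixed cultures with
**PHB accumulation**, under feast–famine operation with double growth
limitation, settling selection, and feed-on-demand substrate control driven
by the online oxygen uptake rate (OUR).

## Who this is for

Bioprocess engineers and microbial-ecology modellers who want to study —
without a reactor — how an acetate-fed activated-sludge community enriches
in PHB storers, how a dOUR/dt-triggered pulse feeder avoids substrate
inhibition, and how cycle performance metrics (specific rates, storage
yield, volumetric productivity) respond to operating choices.

## The model in brief

Two guilds share the reactor. Storers take up acetate at

    q_S = q_s_max · S/(K_S+S) · K_I/(K_I+S) · (1 − (f/f_max)^α)

(Monod × substrate inhibition × storage-capacity saturation, with
f = PHB/X in Cmol/Cmol), banking a fraction `Y_PS_max` of the carbon as
PHB during the nitrogen-free feast and growing on the polymer
(`μ_max·f/(K_f+f)·N/(K_N+N)`, yield `Y_X_PHB`) during the famine once
nutrients are dosed. Non-storers grow only when acetate and ammonium
co-occur and otherwise just oxidise substrate. CO₂ comes from the carbon
balance and OUR from the electron balance (γ_acetate = 4, γ_PHB = 4.5,
γ_biomass = 4.2 e⁻/Cmol; 4 e⁻ per mol O₂), so both balances close to
machine precision at every step. All organics are carried in Cmmol/L
(biomass CH₁.₈O₀.₅N₀.₂ = 24.6 g/Cmol, PHB CH₁.₅O₀.₅ = 21.5 g/Cmol).

The engine (`run_cycle`) interleaves ODE integration (deSolve) with the
discrete SBR actions — carbon/nutrient boluses, 3/4 withdrawal, settling
selection — and a two-tank respirometer loop with lagged DO sensors
provides the measured OUR that the feed-on-demand controller samples every
0.5 min: one dose whenever the smoothed dOUR/dt shows a relative decline,
under a hard 182 Cmmol/L budget, until the OUR returns to the endogenous
baseline. `calibrate_kinetics()` inverts the closed loop to fit
`q_s_max`/`Y_PS_max` to observed cycle metrics.

## Worked example

```r
library(phbsbr)
scenario <- scenario_preset("FD")        # feed-on-demand operational cycle
cycle <- run_cycle(scenario, seed = 1)
print(cycle)
#> <sbr_cycle> scenario 'FD': 18.0 h, 2163 trajectory points
#>   PHB max 145.0 Cmmol/L at 5.42 h | fed 618.8 Cmmol | final X 30.7 Cmmol/L
#>   balance closure: carbon 6.26e-15, electron 5.59e-15 (relative)
cycle_metrics(cycle)
#> <cycle_metrics>
#>   time of PHB max:   5.42 h
#>   PHB max:           145.0 Cmmol/L (80.6 wt%)
#>   q_AC:              1.066 Cmol Ac/Cmol X/h
#>   q_P:               0.875 Cmol PHB/Cmol X/h
#>   Y_P/S:             0.821 Cmol/Cmol
#>   q_AC,max / q_P,max (30-min window): 1.256 / 1.028
#>   volumetric productivity: 3.22 g PHB/L/day
#>   t_Fe/t_Fa:         0.43
head(as.data.frame(cycle$pulses), 3)
#>   t_min dose_cmmol cum_cmmol  trigger    d_our_dt
#> 1  10.0   20.62667  20.62667    START          NA
#> 2  21.5   20.62667  41.25333 dOURdt<0 -0.12640073
#> 3  29.5   20.62667  61.88000 dOURdt<0 -0.07842588
```

Reading this: the controller fed the whole 182 Cmmol/L budget in 30
demand-paced pulses; storage peaked at 145 Cmmol/L (80.6 wt% of solids)
5.4 h after the start — the feast — giving a specific uptake rate of
1.07 Cmol Ac/Cmol X/h, a specific storage rate of 0.88 Cmol PHB/Cmol X/h
and a storage yield of 0.82 Cmol/Cmol. Over the famine the culture regrows
four-fold on the stored polymer (final X ≈ 31 Cmmol/L) while ammonium
falls from ≈ 4.7 mmol/L to zero. `plot(cycle)` shows the anti-phase DO/OUR
traces, the cumulative-feed staircase and the mass trajectories;
`run_enrichment("SBR1", n_days = 30, seed = 1)` simulates the start-up
period (MLSS collapse and recovery, storer take-over, and the settling
selection's head start over the settling-free control).

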