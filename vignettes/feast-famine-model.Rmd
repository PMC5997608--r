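---
title: "The feast-famine SBR model behind phbsbr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The feast-famine SBR model behind phbsbr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phbsbr)
```

## What the package simulates

A sequencing batch reactor (SBR) that couples two jobs usually done in
separate reactors: enriching a mixed culture in polyhydroxybutyrate
(PHB)-storing bacteria, and accumulating PHB for harvest. The regime is
aerobic dynamic feeding with *double growth limitation*: acetate is dosed
at the start of the feast phase with no ammonium present, so carbon can
only be stored, and nutrients are dosed at the start of the famine phase
with no acetate present, so growth can only run on the stored polymer.
Cells that cannot store do not grow in either phase and wash out with the
3/4 volume withdrawal at the end of each feast. A brief settling-selection
step after the withdrawal additionally decants cells that are too light to
settle - cells are light precisely when they carry little PHB - adding a
physical selective pressure on top of the ecological one.

During the operational period the feast is fed on demand: substrate is
pulsed whenever the derivative of the online oxygen uptake rate (OUR)
turns negative, under a hard total budget (182 Cmmol acetate per litre of
working volume per cycle). Small pulses keep the residual acetate
concentration low, which avoids substrate inhibition and is what raises
the attainable PHB content.

All organic species are carried internally in carbon-millimoles per litre
(Cmmol/L). Active biomass CH1.8O0.5N0.2 weighs 24.6 g/Cmol, the PHB
monomer CH1.5O0.5 21.5 g/Cmol, and acetate CH2O has a degree of reduction
of exactly 4 electron equivalents per Cmol.

## The kinetic model

The published study reports observed cycle metrics (specific uptake rate
q_AC, specific storage rate q_P, storage yield Y_P/S) but no rate
equations, so the rate laws here are the minimal forms that reproduce the
observed numbers and the three qualitative behaviours the study leans on:
pulsed feeding out-performing a single pulse, storage slowing at high
cellular PHB content, and famine growth consuming the stored polymer
within about 12 h.

Storers take up acetate at

    q_S = q_s_max * S/(K_S + S) * K_I/(K_I + S) * (1 - (f/f_max)^alpha)

where `f = PHB/X` is the cellular polymer fraction (Cmol/Cmol). The three
factors are Monod saturation (`K_S` = 1 Cmmol/L), classical substrate
inhibition (`K_I` = 60 Cmmol/L; `Inf` disables it), and storage-capacity
saturation (`f_max` = 8, `alpha` = 4). `f_max` = 8 corresponds to a
ceiling of 87.5 wt% PHB, which keeps the batch plateau (~86 wt%)
attainable. A fraction `Y_PS_max` of the carbon taken up becomes PHB, the
rest is respired. Because the polymer is more reduced than the substrate
(4.5 vs 4 electron equivalents per Cmol), yields at or above
gamma_S/gamma_P = 8/9 are physically impossible and `kinetic_params()`
rejects them; the calibrated default is 0.85, which reproduces the
observed net yield of ~0.82 after the maintenance drain.

During the feast no ammonium is present and growth is off (that is the
point of double growth limitation). In the famine, storers grow on their
polymer at `mu_max * f/(K_f + f) * NH4/(K_N + NH4)` with yield `Y_X_PHB` =
0.70 Cmol X/Cmol PHB. With the biomass nitrogen content of 0.2 mol N per
Cmol X, the published famine numbers are mutually consistent and emerge
from the simulation without further tuning: 4.7 mmol N/L supports a
regrowth of about 23 Cmmol X/L (7.9 -> 31), consuming the ~36 Cmmol/L of
PHB present after the withdrawal within about 12 h.

Non-storers grow only when external acetate and ammonium co-occur - under
double growth limitation that happens only through the residual ammonium
the storers could not use - and additionally oxidise acetate without
growth (`q_ns_ox` = 0.30 Cmol/Cmol/h): nitrogen-starved heterotrophs keep
respiring external substrate, so an unselected community wastes feast
carbon that storers would otherwise bank. This overflow term is what makes
the start-up transient realistic (low PHB content early on, rising as the
storers take over) and what gives settling selection its value.

Maintenance respiration (`m_O2` = 0.03 mmol O2/Cmol X/h) oxidises PHB when
polymer is present and biomass otherwise, with a smooth switch. This
particular construction makes the carbon and electron balances close
identically at every rate evaluation: CO2 is computed from the carbon
balance and OUR from the electron balance (4 electron equivalents per mol
O2), so conservation over a cycle is limited only by the integrator's
preservation of linear invariants - in practice machine precision, and the
test suite demands better than 1e-6 relative closure. An m_O2 an order of
magnitude larger, as one might read off typical endogenous-respiration
tables, would exceed the oxygen-transfer capacity of the aerated tank and
drive the dissolved oxygen negative; 0.03 gives a clearly visible
endogenous OUR baseline (~1 mg DO gap at the sensing pair) while keeping
the reaction-tank DO above the 2 mg/L the study maintained.

## Reactor engine and the respirometer loop

`run_cycle()` executes a `cycle_schedule()`: boluses (carbon, nutrient) at
phase starts, lsoda integration across each phase, withdrawal and settling
selection at phase ends. Every discrete action is logged with the exact
amounts moved, so each cycle carries its own carbon, electron and volume
ledgers. Feeds are idealised as instantaneous boluses (the study's 15-min
dosing window is short against the 6-h feast).

Dissolved oxygen lives in a two-tank respirometer loop: a 3-L aerated tank
(kLa = 60 1/h, saturation 7.5 mg/L at 30 degrees C) exchanging 1 L/min
with an unaerated 1-L reaction tank; both respire. Two first-order sensors
(10 s lag) read the reaction tank's inflow and outflow DO, and the
measured OUR is their difference divided by the residence time (1 min).
The recirculation flow is not stated in the study; 1 L/min keeps the
reaction tank above ~2 mg/L at peak feast respiration, which a 0.5 L/min
loop would not. Similarly, kLa = 60 1/h is the smallest round value that
sustains the feast OUR implied by the published rates; DO never limits the
kinetics (no oxygen Monod term), matching the study's non-limiting
aeration.

Settling selection removes a fraction `r_base * (1 - s * f/f_sat)`
(clamped to [0, 1]) of each guild's cells, where `f` is the guild's PHB
fraction. Retention saturates at `f_sat` = 2: even moderately laden cells
are dense enough to settle completely within the 10-min window, so the
step taxes only PHB-poor cells. The decant after a quiescent settle
displaces the just-added water rather than mixed broth, so dissolved
species stay in the reactor. `r_base` = 0.25 encodes the strong physical
selection suggested by the study's sludge-volume-index drop. These three
choices matter: with removal proportional to `f/f_max` and a fully-mixed
decant, the settle step taxes storers and wastes leftover feast acetate,
and the simulated settling reactor then starts up *slower* than the
control - the opposite of what was observed.

## The feed-on-demand controller

The published rule is bang-bang: feed while dOUR/dt < 0, stop while >= 0,
under a fixed budget, with a compulsive first pulse and termination once
the budget is spent and the OUR has returned to the endogenous baseline.
Applied verbatim to a sampled noisy signal the rule chatters: an unbiased
one-step derivative of a flat signal is negative half the time, and with
the default sensor noise (sigma = 0.05 mg/L per DO reading) the whole
budget would be dumped in minutes. `controller_config()` therefore hardens
the rule - a trailing 5-sample median, a derivative across 4 samples
(2 min), a trigger threshold of 10% of the baseline per minute (a
*relative* decline), and a 6-sample pump refractory - and exposes every
constant. With a noise-free signal the behaviour reduces to the raw sign
rule; with noise, the trigger's sign agrees with the noise-free oracle on
>99% of decision-relevant samples. A consequence worth knowing: the
derivative magnitude depends on the lag convention, but its sign - the
only thing the control decision uses - does not.

The pulse dose defaults to budget/30, giving the ~30-step staircase of
cumulative feed with ~11-min spacing that demand-paced feeding produces at
the calibrated kinetics; the feast then ends (OUR back at baseline, budget
exhausted) at about 5.5-6.0 h, matching the published 5.6 +/- 0.25 h.

## Calibration

`calibrate_kinetics()` inverts the closed loop: given observed (q_AC, q_P)
it sets the gross yield in closed form - the maintenance drain on PHB is
exactly `(4/gamma_P) * m_O2 / q_AC` per Cmol of acetate consumed - and
then finds `q_s_max` by a bracketed root search on simulated feasts. When
the targets come from offline measurement tables, `observable = "sampled"`
makes the simulated observable pass through the same 50-min-grid estimator
as the data, so grid bias cancels between target and simulation. Noise-free
round trips recover both parameters within ~1-2%; across 20 replicates at
the default assay noise the true values lie well inside the replicate
mean +/- 2 sd.

## The synthetic measurement generator

`sample_trajectory()` emulates what a wet lab would hand the analysis
path: offline chemistry every 50 min (acetate, PHB, volatile suspended
solids = biomass + polymer, ammonium, in g/L and mmol/L) with
multiplicative Gaussian noise (CVs 3-5%, routine GC/gravimetric
precision), and a 0.5-min DO log with additive sensor noise. It is a pure
function of (trajectory, plan, seed). What it does *not* emulate: real
community heterogeneity beyond two guilds, analytical drift or batch
effects, pH and temperature excursions, sampling dead volumes. Passing
tests on synthetic tables therefore demonstrate that the analysis chain is
correct and noise-robust, not that the two-guild model captures every
behaviour of a real sludge.

The enrichment simulator draws its inoculum per seed: 5.13 +/- 0.25 g
MLSS/L with 3-8% storers. The published start-up (minimum MLSS around
day 4-9, recovery to ~2.2-2.3 g/L, >70 wt% PHB at steady state, settling
selection shaving days off the start-up, and negligible effect of removing
it once steady) is reproduced qualitatively; the absolute 21- vs 33-day
timescale is not a target, since it depends on the unmeasured composition
and adaptation of the real inoculum. Simulated steady state arrives much
sooner (about a week): an idealised two-guild culture has no adaptation
lag.

## Numerical choices

lsoda with rtol = atol = 1e-8; integration restarts at every discrete
event; the closed-loop feast integrates in 8-sample blocks with exact
rollback to a trigger sample, which cuts solver restarts several-fold
without changing the dynamics. Trajectories are emitted on a 0.5-min grid
(5 min for multi-cycle enrichment runs). Concentrations can round off to
-1e-12 inside the solver; rate evaluations and the measurement generator
clip at zero. Problem sizes used by the shipped tests - one 18-h cycle at
0.5-min resolution, 30-day enrichments at 5-min resolution, 10-seed
comparisons, 20 Monte-Carlo replicates - were chosen so the full suite
documents the science while running in minutes.

## Known limitations

* Two rigid guilds; no phenotype continuum, adaptation, or community
  succession (the published 16S community data are out of scope).
* Acetate-to-PHB only; no PHV co-polymer, no mixed substrates.
* pH and temperature are assumed controlled and do not enter the rates.
* The published volumetric productivity of 5.0 g PHB/L/day is not
  reconstructible from the published PHB, volume and cycle time by the
  stated formula (candidate readings give 3-4 g/L/day);
  `volumetric_productivity()` implements the formula as written and this
  discrepancy is left documented rather than resolved.
* The feast length the controller realises is emergent; the cycle keeps
  its fixed 18-h frame regardless (the study is ambiguous on whether the
  frame floats; fixed is the conservative reading).
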