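# ventscore

Multi-criteria bench scoring of pressure-support (non-invasive) ventilators.

During the COVID-19 pandemic, clinicians and engineers needed a standard way
to compare how well different ICU and dedicated NIV ventilators actually
perform — not on one metric, but across the aspects that matter at the
bedside: how stably they pressurize, how fast they react to patient effort,
how quickly they recover tidal volume after a circuit-leak change, how much
volume they deliver, and how accurately they deliver oxygen. `ventscore`
implements such a scoring system end to end for bench recordings from a
lung simulator, and ships its own lung–ventilator simulator so the entire
pipeline can be exercised, tested and demonstrated without hardware.

## What it computes

From a uniformly sampled recording of airway pressure `Paw` (cmH2O), patient-
side flow (L/s) and volume, the package segments breaths and measures, per
breath:

* **trigger time** — from effort onset until `Paw` returns to baseline (EPAP)
  after its downward deflection;
* **Insp T90 / Exp T90** — time to accomplish 90% of the pressure rise toward
  IPAP / 90% of the drop from peak pressure toward EPAP;
* **maximum pressure drop** — depth of the pre-trigger dip below EPAP;
* **IPAP / EPAP error** — |Ppeak − set IPAP| and |end-expiratory pressure −
  set EPAP|;
* **tidal volume** — ∫ positive inspiratory flow dt;
* **peak-flow rising ratio** — peak inspiratory flow / Insp T90 (L/s²);

plus, from dedicated leak-step trials, the **time to settle**: how long until
tidal volume re-enters the band mean ± 2 SD of the settled level after a leak
increase or decrease. Oxygen-delivery accuracy is the deviation of delivered
from set FiO2 at the 60% and 100% settings.

Each measured value `x` is mapped to a score

    s = clamp( (x − worse) / (better − worse), 0, 1 )

using published per-phenotype, per-preset ranges (`default_ranges()`), so a
value at/beyond the *better* bound scores 1 and at/beyond the *worse* bound
scores 0. Node scores are averaged over the tested levels (three IPAP/EPAP
presets × baseline + three leak levels), then aggregated with a two-level
analytic-hierarchy-process (AHP) weight hierarchy:

    overall = Σ_c w_c · Σ_n w_(n|c) · s_n

with five criteria (stability of pressurization 0.223, response to leak
alteration 0.229, volume delivery 0.160, performance of reaction 0.242,
oxygen accuracy 0.146) over 11 leaf nodes (`load_weights()`). The `ahp`
module also re-derives such weights from pairwise-comparison data
(`ahp_priorities()`, power-iteration principal eigenvector with CI/CR
consistency diagnostics, `aggregate_binary_votes()` for binary survey
tallies).

The simulator (`simulate_recording()`, `run_protocol()`) integrates a
single-compartment lung, `flow = (Paw − V/C + Pmus)/R`, against a
pressure-support state machine with configurable imperfections
(`ventilator_profile()`: trigger delay, rise/fall time constants, pressure
biases, pre-trigger dip gain, cycling threshold, leak-compensation time
constant, FiO2 biases, sensor noise) for the four simulated COVID-19
phenotypes: LC (C = 20 ml/cmH2O), IR (R = 10 cmH2O/L/s), LCIE (rate 40/min,
effort 10 cmH2O), HC (C = 50 ml/cmH2O).

## Worked example

Score a deliberately imperfect device (120 ms trigger delay, sluggish
pressurization, −0.5 cmH2O IPAP bias, slow leak compensation, 4-point FiO2
bias at the 60% setting) on two phenotypes:

```r
library(ventscore)
prof <- ventilator_profile(trigger_delay = 120, rise_tau = 120,
                           ipap_bias = -0.5, leak_comp_tau = 3,
                           fio2_bias_60 = 4, seed = 42)
cards <- run_bench(profile = prof, circuit = "single",
                   phenotypes = c("LC", "HC"))
print(cards$LC)
#> <scorecard> LC overall 0.654
#>   pressurization   0.896
#>   leak             0.174
#>   volume           0.734
#>   reaction         0.799
#>   oxygen           0.712
radar_summary(cards$LC)
#> pressure     leak   volume reaction   oxygen
#>    0.896    0.174    0.734    0.799    0.712
```

The radar axes are the five criteria in the fixed clockwise plotting order.
Reading the card: the slow leak compensation (τ = 3 s) is this device's
weakest aspect (leak 0.17), the trigger delay and slow rise cost it about a
fifth of the reaction score, and the 4-point oxygen bias at the 60% setting
maps to 0.712 on the oxygen axis. Underlying per-breath measurements are a
function call away:

```r
so <- simulate_recording("LC", prof, test_condition("LC", 20, 8),
                         duration = 30)
eq <- select_equilibrium_breaths(analyze_recording(so$recording))
round(colMeans(eq[, c("tidal_volume", "trigger_time", "insp_t90")]), 1)
#> tidal_volume trigger_time     insp_t90
#>        374.3        121.9        326.6
```

The measured trigger time recovers the configured 120 ms delay.

Recordings travel as plain CSV (`time_s,paw_cmh2o,flow_lpm,volume_ml
[,pmus_cmh2o]` with a JSON condition sidecar; `read_waveform_csv()` /
`write_waveform_csv()`), scorecards as JSON, and range/weight configurations
as YAML or JSON. A thin CLI over the same functions lives at
`inst/cli/ventscore.R` (subcommands `simulate`, `analyze`, `score`, `ahp`,
`report`).

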