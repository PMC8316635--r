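---
title: "Methods: waveform metrics, range scoring and AHP weighting in ventscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform metrics, range scoring and AHP weighting in ventscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventscore)
```

`ventscore` scores the bench performance of pressure-support ventilators on
five criteria — stability of pressurization, response to leak alteration,
volume delivery, performance of reaction, and accuracy of oxygen delivery —
and aggregates them into a single figure of merit with analytic-hierarchy-
process (AHP) weights. This vignette is the package's own account of the
models and conventions behind each stage, the parameters that matter, and
the choices we made where the methodology is genuinely open.

## 1. Breath segmentation and per-breath parameters

Recordings hold airway pressure (cmH2O), patient-side flow (stored in L/s;
the CSV interface uses L/min, the bench convention), volume (ml) and,
on simulated benches, muscle pressure, all on a uniform grid (default
512 Hz, the acquisition rate of the protocol the package targets).

Inspiration is detected on the flow channel: an upward crossing of
θ = 0.033 L/s (2 L/min) that remains above θ for at least 100 ms. The
threshold-with-hold debounces sensor noise without missing the short breaths
of the high-rate phenotype (1.5 s period); both values are arguments of
`segment_breaths()`. Inspiration ends at the downward crossing of θ;
expiration runs to the next inspiration start. A breath whose expiratory
phase is cut off by the end of the record is discarded rather than measured
incompletely. Segments are kept as 1-based closed index ranges into the
recording.

The effort onset is the first sample of the contiguous muscle-pressure run
(above 2% of the breath's Pmus maximum) containing that maximum; without a
Pmus channel it falls back to the start of the airway-pressure deflection
below baseline. The baseline EPAP itself is the median pressure over the
100 ms preceding the effort onset — the published metric definitions refer
to "baseline (EPAP)" without an estimator, and a short pre-onset median is
robust against both noise and the deflection.

Per breath the package measures: trigger time (effort onset → first sample
at/above baseline − 0.05 cmH2O after the deflection minimum; the 0.05
guard-band prevents an asymptotic approach from never formally reaching
baseline), Insp T90 (upward baseline crossing → 90% of the rise from *set*
EPAP to *set* IPAP), Exp T90 (inspiratory pressure peak → 90% of the drop
from the *measured* peak toward set EPAP), maximum pressure drop (baseline −
pressure minimum in the trigger window), IPAP error (|Ppeak − set IPAP|),
EPAP error (|mean pressure of the final 50 ms of expiration − set EPAP|),
tidal volume (trapezoidal integral of positive inspiratory flow; leak flow
never enters it because the channel is lung-side flow) and the peak-flow
rising ratio (peak inspiratory flow / Insp T90). The T90 asymmetry — set
pressures for the rise target, measured peak for the fall — mirrors the
definitions' wording ("rise to IPAP" vs "drop from peak pressure"). All
timing features are integer multiples of the sample period; for first-order
pressurization with time constant τ they equal τ·ln 10 within a sample, a
property the test suite checks analytically.

A feature whose threshold is never reached within its breath (e.g. Insp T90
when a heavily biased device never comes within 90% of the set rise) is
flagged missing and excluded from that node's mean rather than scored 0:
penalizing a measurement failure would conflate analysis limits with device
behaviour.

## 2. Equilibrium breaths and outliers

Following bench practice, five consecutive equilibrium breaths per trial are
analyzed. Tidal-volume outliers are removed first with the 1.5·IQR rule;
quartiles use linear interpolation between order statistics (R's default
type 7), which makes the filter reproducible to the digit. The filter is a
single pass — refiltering a heavy-tailed sample could remove more points,
so `remove_outliers()` deliberately does not iterate. Among the remaining
breaths, `select_equilibrium_breaths()` picks the window of five consecutive
breaths minimizing the coefficient of variation of tidal volume, breaking
ties toward the latest window so steady recordings yield their final five
breaths.

## 3. Leak settle time

After a leak step, the settled tidal volume for the new level is estimated
from the final `n_ref = 10` post-change breaths; the device has settled at
the first post-change breath inside the band mean ± 2 SD that is followed by
two further consecutive in-band breaths (`m_sustain = 3` — a single
transient crossing during recovery must not count). The settle time is
referenced to that breath's inspiration start, which keeps it deterministic
and sample-grid aligned. Two numerical points deserve note:

* the band half-width is floored at 1 ml (`band_floor`), about the volume
  resolution of a bench measurement; without it a noise-free settled tail
  has SD = 0 and the band degenerates to bit-exact equality, making a
  perfectly compensating device read "unsettled";
* because the band is estimated from the trial's own tail, a sufficiently
  long post-change segment essentially always settles *somewhere* (at most
  a quarter of the reference breaths can lie beyond 2 SD of their own
  mean, so a three-breath in-band run always exists inside the reference
  window). "Unsettled" therefore signals that the sustain requirement could
  not be met within the recorded trial, and such trials score 0 on their
  node.

The detector is direction-agnostic; the direction label only selects which
range applies when scoring (worse bound 20 s after an increase, 12 s after a
decrease). The settle time is invariant under adding a constant to all
tidal volumes, and — on the simulator — never decreases when the device's
leak-compensation time constant grows; both are property-tested.

## 4. Range scoring

`map_score()` implements the published boundary rule: values at/beyond the
better-performance bound score 1, at/beyond the worse bound 0. Within the
range the published rule fixes only the endpoints; we interpolate linearly —
the simplest monotone map consistent with both endpoints, and the choice
most compatible with the continuous-looking criterion scores of published
radar charts — with a step alternative (`method = "step"`) for strictly
binary scoring. Symmetric "± x" ranges (IPAP/EPAP errors, oxygen at the 60%
setting) score the absolute deviation, with better bound 0.

The default range table resolves per parameter from the most specific
matching row: tidal-volume ranges are per phenotype × preset; trigger time,
the T90s, the pressure drop and the peak-flow ratio are per phenotype
(applying to all three presets, matching the published table's blank-cell
layout); IPAP/EPAP error ranges are per preset across phenotypes; settle
times and oxygen ranges are global. Printed thousands separators ("1,025")
are plain numbers here. Node scores are arithmetic means over all tested
levels; unsettled leak trials score 0.

## 5. Weights and aggregation

The default two-level hierarchy carries the published weights — first level
0.223 / 0.229 / 0.160 / 0.242 / 0.146, leaf weights beneath each criterion,
oxygen as a singleton leaf. The printed reaction leaf weights total 0.999
(rounding), so each level is renormalized to sum to exactly 1 at load; raw
values are retained for inspection. The overall score is linear in the node
scores with coefficients equal to the global (criterion × leaf) weights.

A node with no usable measurement is dropped and its criterion renormalized
over the present leaves; a criterion with no nodes at all is dropped from a
renormalized overall. Both situations are flagged on the scorecard rather
than silently scored 0, so an incomplete bench run is visibly incomplete.

The `ahp` module reproduces the weighting process itself: priorities are the
normalized principal right eigenvector (power iteration to relative
tolerance 1e-12, eigenvalue via the Rayleigh quotient), with the standard
consistency index CI = (λmax − n)/(n − 1) and ratio CR = CI/RI using Saaty's
random-index table, so CR is deterministic. The row-geometric-mean method is
available as a cross-check. Binary survey answers are aggregated into
comparison matrices with smoothed odds, a_ij = (v_ij + 0.5)/(v_ji + 0.5)
capped to the Saaty scale [1/9, 9]; published binary-to-matrix
constructions vary, so ours is explicit and configurable, all respondents
weigh equally, and the default hierarchy ships the published weights as
data rather than pretending to re-derive them from unavailable raw replies.

## 6. The simulator

The synthetic bench integrates a single-compartment lung,
flow = (Paw − V/C + Pmus)/R, with explicit Euler steps at the acquisition
rate, so the simulated and analyzed grids coincide; a stability guard
rejects R·C < 4·Δt. Patient effort is a train of half-sine Pmus pulses (the
effort waveform of the hardware lung simulator is not published; a half-sine
is a standard smooth choice). Phenotype presets carry the published
mechanics — LC: C = 20 ml/cmH2O; IR: R = 10 cmH2O/L/s; LCIE: rate 40/min,
effort 10 cmH2O; HC: C = 50 ml/cmH2O — and documented assumptions for the
unspecified fields: R = 5 cmH2O/L/s where resistance is not the phenotype's
defining feature, C = 40 ml/cmH2O for IR, effort rate 15/min with 0.8 s
pulses (0.6 s for LCIE) and amplitude 10 cmH2O for all phenotypes. We chose
10 cmH2O (the effort scale the protocol states for LCIE) rather than a
low-effort 5 cmH2O after checking the single-compartment algebra against
the published tidal-volume ranges: with 5 cmH2O the *better* bounds (e.g.
270 ml under LC at preset 10/4 with C = 20 ml/cmH2O) are unreachable by any
device, which would make the volume criterion uninformative.

The ventilator is a pressure source with a three-state machine: EXHALE
relaxes Paw toward EPAP + bias with the fall time constant; a detected
effort opens a trigger-delay window during which Paw dips below baseline by
`trigger_drop_gain`·Pmus (producing the measurable pressure drop); INHALE
relaxes toward IPAP + bias with the rise time constant and cycles back to
EXHALE when inspiratory flow falls below `cycle_fraction` of its breath
peak. Without patient effort a backup machine breath fires at 10/min
(spontaneous-timed behaviour). Circuit leak follows an orifice law
Q = c·√Paw with c calibrated to deliver the scheduled L/min at the mean
applied pressure; since the controller is a pressure source on the patient
side, a *constant* leak leaves the patient signals unchanged, and leak
*steps* act through the compensation model: the inspiratory target is
depressed by `leak_comp_gain` (0.04 cmH2O per L/min of step) times the step
size, decaying exponentially with the device's `leak_comp_tau` — so the
tidal-volume deficit after a step decays with exactly that time constant.
Delivered oxygen is a deterministic scalar per trial: the setting minus a
setting-specific bias minus a dilution proportional to leak level and
above-ambient concentration.

The full protocol (`run_protocol()`) is 4 phenotypes × 3 presets ×
(baseline + 3 leak levels: 50/70/90 L/min single-circuit, 14/19/25 L/min
double-circuit) as 60 s steady trials, plus one upward and one downward
leak-step trial per preset (90 s, step at 30 s — the hardware protocol's
stepped leak valve timing is not published, so one step per trial at a
configurable time). Gaussian pressure noise is seeded per trial;
identical configuration and seed reproduce recordings bit for bit.

What the simulator does *not* emulate, and what passing tests therefore do
not show about real hardware: flow overshoot and ringing of real blowers
(our first-order pressurization cannot exceed its target, so measured tidal
volumes are conservative — most visible for the IR phenotype, whose
published volume ranges real devices reach via overshoot), two-compartment
or nonlinear lung mechanics, within-breath oxygen dynamics, humidification,
and controller quirks of any specific commercial device.

## 7. Problem sizes and determinism

The test suite and the acceptance script run the analysis end to end on
simulated trials of 10–90 s at 512 Hz (up to ~46k samples per channel), the
full 72-trial protocol for scorecards, 5-point grids per imperfection knob
for degradation monotonicity, and 100 random reciprocal matrices (n ≤ 8)
against a dense eigendecomposition oracle. These sizes keep a complete run
in well under a minute on one core while exercising every code path at the
protocol's native sampling rate. All randomness flows from explicit seeds;
reruns are bit-identical, including serialized scorecards.

## 8. Known limitations

* The published per-device scores cannot be reproduced without the physical
  ventilators; synthetic-data checks validate the pipeline, not the
  hardware ranking.
* Range bounds are taken as given; the package does not re-derive them from
  device populations, and fractional (linear) within-range scoring is a
  documented choice the source text does not fully determine.
* Effort-onset detection without a Pmus channel relies on a visible
  pre-trigger pressure deflection; an extremely sensitive device with no
  measurable dip yields trigger times quantized to the first baseline
  sample.
* The binary-vote-to-matrix construction is a stand-in for an unpublished
  procedure; hierarchies derived from survey tallies should be read with
  that caveat.
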