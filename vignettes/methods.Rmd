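---
title: "Models and methods behind swimstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swimstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swimstate)
```

This vignette documents the generative model, the analysis methods,
the numerical choices, and the limits of what the package's tests
demonstrate. Everything quantitative stated here is computed by the
test suite or by `scripts/acceptance.R`; nothing is asserted beyond
what those runs measure.

## 1. The behavioral paradigm and the swim agent

The virtual environment couples fictive swimming to visual feedback
through `v_stim = v_flow − m·G_ms` (mm/s). Trials alternate Effective
(closed-loop Evoke, gain `G_ms = 8` mm/s per vigor unit) and Futile
(open-loop Evoke, gain 0). The agent swims in bouts (0.3 s, inter-bout
gaps uniform on 0.5–2 s, lognormal vigor). During futile swimming a
futility accumulator integrates vigor with gain 0.65 and decay
`tau_a = 28` s; when it crosses 1 the fish gives up. Passivity is
detected as 5 s without swimming, which triggers a 3 s Pause; on
Effective trials the Pause is 8 s, so pre-Probe quiescence is exactly
8 s on both trial types — this equalization is enforced by
`paradigm_config()` and asserted by the tests.

During the Probe (1 s pulses of slow forward motion at
`v_flow_probe = v_flow_evoke / 2.5`, alternating with 1 s gaps, capped
at 60 s) the agent leakily integrates stimulus velocity with a
state-dependent time constant, `tau(s)` interpolating linearly from
11.2 s (state 0) to 5.9 s (state 1) — linear because no functional
form is established and linearity is minimal. A swim is initiated
when the integral crosses a bound drawn per trial from a lognormal
with median 18.2 mm and coefficient of variation 0.15.

**Calibration.** The bound, its spread, `tau_a`, `gain_k`, and the
Effective Evoke duration range (10–16 s) were fixed once, jointly, so
that (i) default-mode mean latencies bracket the study conditions the
paradigm is designed around (≈21 s Effective, ≈31 s Futile, ≈7% of
Probe epochs censored at the cap); (ii) cumulative visual-motion
exposure during Evoke is approximately matched between trial types —
the experimental design equalizes stimulus history, and an unmatched
emulation leaks a visual-history artifact into every downstream
state comparison; and (iii) the state has largely resolved by the
time of the probe-evoked swim, matching the observation that brain
activity is mostly equalized at recovery.

**Internal state and its manipulations.** The astrocytic state `s`
equals the futility accumulator in normal mode, is clamped to zero in
`calex` mode (calcium extrusion; the accumulator still drives
scripted passivity so trial structure stays matched), and is forced
to 0.9 during Pause and Probe of alternating "capsaicin" trials in
`trpv1` mode, in which all Evoke epochs are closed-loop — state
effects then occur with no futile swimming anywhere in the session.

**Recovery-linked amplification.** Sensory gain grows by
`amp_gain = 0.5` times a readiness ramp rising linearly over the 14 s
before the realized probe-evoked swim. This is a generative stand-in
for the progressive pre-recovery amplification and is deliberately
indexed to the realized recovery time: an evidence-to-bound ratio was
tried first and rejected because the evidence curve is nearly flat at
the bound, so it carried almost no information about time-to-swim and
neither progressive amplification nor latency decoding could be
expressed by the data.

## 2. The neural forward model

Each cell class has a latent rate built from behavior, stimulus and
state, convolved with a difference-of-exponentials indicator kernel
(rise 50 ms, decay 500 ms, unit area — only the decay scale is
anchored in measurements), binned to imaging frames (3 Hz default;
2 Hz supported), scaled by a per-cell lognormal gain (cv 0.2), with
Gaussian noise (SD 0.05 ΔF/F) added last, so indicator convolution is
exactly linear.

- *Sensory-positive* (11% of 200 cells): rate ∝ positive stimulus
  velocity × `(1 − 0.17·s)` × amplification.
- *Sensory-negative* (3%): baseline minus pulse-locked dips scaled by
  `(1 − 0.82·s)`.
- *Sensory-integrative* (30 cells): an equal mixture of the dampened
  sensory drive and its leaky temporal integral with `tau(s)`. The
  mixture (weight `integrator_sensory_mix = 0.5`) reflects that
  sensory encoding and integration form a continuum: immediate pulse
  responses inherit the mild sensory dampening while the accumulated
  component collapses with `tau(s)`. A pure accumulator
  (`integrator_sensory_mix = 0`) is retained for oracle tests; its
  per-pulse increments are nearly independent of `tau`, which is why
  the mixture, not the pure form, is the default.
- *Motor-preparatory* (8 cells, 4% of the population so the top-5%
  selection rule can recover them): linear ramps starting 3 s before
  each swim onset, reset at onset.
- *Motor* (30 cells): rate ∝ vigor.
- *Anti-motor* (10 cells, all labeled L-MO): a slow 8 s oscillation,
  suppressed 5-fold during swimming, with unreliable (probability
  0.5 per pulse) negative pulse responses gated by `(1 − s)`.
- *Untuned* cells (the remainder): noise only.

The state acts on circuits through an effector low-pass (2 s): without
it, bout-locked state increments modulate responses inside the bout
itself and alias into the vigor regressor.

Regions are assigned so sensory cells concentrate in early entries of
an eight-region list and integrators in late ones, giving regions a
gradient of integrator prevalence for the depth-versus-integration
regression; anti-motor cells all sit in "L-MO".

**What the generator does not emulate:** imaging physics (point-spread,
motion artifacts, bleaching), spike-to-calcium nonlinearity,
correlated (shared) noise across cells, neuromodulator sensor traces,
replay-trial stimulus construction, and real regional anatomy. Cells
within a class share one latent up to gain, so across-cell statistics
are far more correlated than in real data; passing tests demonstrate
correctness of the analysis code under the stated model, not
performance guarantees on real recordings.

## 3. Swim detection

Vigor is the SD of the ventral-root signal in a centered 10 ms sliding
window (edges shrink). The envelope is
`x = sqrt(((y − y*ker1)²)*ker2)` with unit-area Gaussian kernels of
sigma 100 ms and 20 ms truncated at ±4 sigma (a boxcar option exists);
kernels are renormalized over in-range samples at the trace edges so
constants are preserved. The threshold estimates the envelope density
by histogram (Freedman–Diaconis width, floor of 200 bins, mode ties
broken toward smaller values), takes the mode `x_max` and the highest
value `x_min` with density above 1% of the mode, and returns
`th = x_max + c·|x_min − x_max|`, with `c = 1.8` by default (up to 5
for noisy recordings). The absolute spread is used because the printed
form of the rule places the threshold below the mode whenever the
upper density edge exceeds it, defeating its purpose. Runs above
threshold closer than 200 ms are merged and runs shorter than 50 ms
dropped — both values are assumptions from typical bout kinematics,
exposed in `bout_params()`, as the source method does not state them.
The ephys default rate is 6 kHz; a 1 kHz mode keeps tests fast, and
all algorithms take the rate as a parameter.

The threshold rule assumes burst samples are either rare or spread
over amplitudes. Synthetic bursts are therefore rhythmically
amplitude-modulated (15 Hz), and dense-swimming sessions additionally
need per-bout amplitude variability (`amp_jitter_sdlog`) — with
constant-amplitude tones the burst envelope mass concentrates into a
few histogram bins and drags `x_min` into the burst range.

## 4. Trials and classification

All times are seconds from session start; intervals are half-open
`[onset, offset)`. Effective trials are Engaged when every inter-swim
interval through the Evoke epoch, including the final gap to the
Evoke end, is at most 3 s (a 3.3 s end-gap variant implements the
imaging-analysis selection rule), and Excluded otherwise — the
mid-epoch gaps are folded into the same rule so the four labels
partition all trials. Futile trials are Disengaged when the no-swim
interval at the Evoke end reached the 5 s passivity window, else
Perseverant. The latency boundary at Probe onset is inclusive;
censored latencies carry the cap value, and summaries report both
censored-included and censored-excluded means because the source
treatment is not stated. Dual-aligned analyses keep trials with
latency ≥ 20 s and an observed swim.

## 5. Tuning classification

Spearman correlations use average ranks for ties; p-values use the
exact tie-free small-sample null where available and the
t-approximation otherwise (full permutation enumeration is factorial
and infeasible even at moderate n). Sensory tuning correlates each
cell with the stimulus over the first six pulses (12 s) concatenated
across non-swimming trials; flags at p < 0.05 with no multiplicity
correction, since population statistics are formed across fish.
Motor tuning is computed in open-loop Evoke windows restricted to
actively swimming samples (m > 0) and skipping the first 1.5 s after
the epoch transition — the passive tail (state at its peak) and the
shared onset transient otherwise correlate every state-modulated cell
with vigor — against a vigor regressor passed through the indicator
kernel so regressor and trace share the measurement lag.
Motor-preparatory cells must, for every window length 3–7 s before
the probe-evoked swim on Engaged trials, correlate positively
(p < 0.05, samples concatenated across trials against time relative
to the swim) and sit within the top 5% of the population by
correlation; both thresholds are exposed. Ramp onset is the latest
pre-swim time where the swim-aligned average first exceeds baseline
mean + 2 SD and stays above — "starts to rise" is not otherwise
defined.

## 6. Integration metrics

The leaky integral uses exact exponential-hold updates (not Euler),
so recovery oracles are exact and the large-`tau` limit is a clean
staircase. The fit minimizes squared error over
`ΔF/F = β·I_tau + sens·v + init·e^(−t/tau) + offset`: for each `tau`
on a 64-point log grid (0.1–100 s) the linear coefficients have a
closed-form solution, and the grid optimum is refined by bounded
golden-section search — deterministic, no random starts. The
velocity term absorbs instantaneous sensory responses so `tau` is
identified from the accumulated component; the initial-condition term
carries activity accumulated before the window, which opens 8 s
before Probe onset so the largely drive-free quiescence pins it down.
Indicator kinetics are deliberately ignored in interpreting `tau`
(0.5 s against multi-second time constants), but the velocity
regressor is indicator-convolved because convolution and leaky
integration commute. Pure leaky-integral traces are recovered exactly
(`sens = init = 0`); noiseless recovery is within 5% for
`tau ∈ {2, 5, 10, 20}` s and the median relative error at noise SD
0.05 is about 1%. On condition-averaged session data `tau` is ordinal
only: Engaged fits often rail at the 100 s grid edge because a 12 s
probe window cannot separate an 11 s time constant from near-perfect
integration, while Disengaged fits land near the generating effective
value.

Pulse endpoints take the last frame inside each half-open ON/OFF
interval. Inverse leakiness is `off_6 / Σ(on_i − off_{i−1})`, with a
near-zero denominator returning a sentinel that excludes the cell
from leakiness summaries. Pulse-response areas integrate the trace
from pulse onset over one 2 s pulse period (the window is
configurable; the source does not state 1 s versus the full period)
after subtracting the local linear trend through the three pre-onset
frames — a plain pre-frame baseline lets slowly decaying carried-over
activity masquerade as state modulation, which shows up as a spurious
non-zero discriminability in state-clamped control sessions. The
template-subtraction pulse-integration area uses the Engaged-trial
first-pulse response (least contaminated by accumulation) truncated
to one period; on noisy session averages the robust headline summary
is instead the fitted accumulated-component area (`model_auc`).

## 7. State modulation and recovery

`d′` uses sample SDs and returns signed-infinity or zero sentinels on
degenerate input. Modulation duration runs a rank-sum test per pulse
index (exact below combined n = 20 without ties, normal approximation
with continuity correction otherwise) and requires
indistinguishability to be *sustained* through all later pulses, to
avoid flicker from isolated significant pulses; the time base is the
pulse index (onset at 2(i−1) s), the simplest reading of an unstated
rule. Regional aggregates use only sensory-flagged cells. The
two-way ANOVA is the fixed-effects `measure ~ fish * type` model; a
zero-variance measure returns p = 1 for every term by convention and
an empty cell raises a rank-deficiency error.

Time warping copies Probe-onset- and last-pulse-aligned segments
verbatim and linearly resamples the middle to 20 scaled-time-unit
bins (linear because the interpolant is unstated); warping and
averaging commute for equal-length trials, which the tests verify
exactly. The latency decoder is gradient-boosted regression at the
reference library's defaults (100 trees, learning rate 0.1, depth 3),
trained per fish per condition on a seeded, condition-stratified half
split of trials (stratification is a choice; the split rule only
states halves) with features from behavior-predictive cells — those
whose single-pulse responses correlate negatively with the latency
from that pulse to the swim, selected at p < 0.05. Decoding is
per-fish; predictions are pooled across fish for cohort-level rank
correlations.

## 8. Problem sizes and reproducibility

Default study conditions: cohorts of 5 fish × 20 trials × 200 cells
at 3 Hz imaging and a 100 Hz behavioral grid; swim-detection checks
use ten 300 s sessions at the 1 kHz test rate; statistical
calibration uses 500 null simulations (ANOVA) and 1000 replicates
(rank-sum, Spearman). All randomness descends from a single session
seed through named substreams (behavior, ephys noise, calcium noise),
and identical seeds reproduce sessions bitwise. Session containers
are directories of CSV arrays with a JSON manifest carrying the
schema version and resolved configuration; every results table
declares units in a header comment and round-trips exactly.

## 9. Known limitations

Fitted time constants saturate at the grid edge for slow cells (see
§6). The envelope threshold degrades when swimming is dense and
burst amplitudes homogeneous (§3). Per-cell `d′` estimates are
strongly correlated within a session because class members share one
latent, so cohort medians move more between seeds than independent
cells would suggest. The latency distribution of passivity and
recovery durations is a lognormal placeholder — no empirical
distribution is established — and is configurable. The Perseverant
label is supported by the classifier but default agent parameters
always reach passivity; perseverant patterns are exercised through
constructed bout trains in the tests.
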