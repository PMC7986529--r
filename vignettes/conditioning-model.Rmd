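---
title: "An integrate-and-fire network model of stimulation-induced cortical plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrate-and-fire network model of stimulation-induced cortical plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdpnet)
```

## The model

`stdpnet` simulates how closed- and open-loop stimulation protocols
reshape synaptic connectivity between groups of motor-cortical neurons.
The network contains three cortical "columns" — A (the recorded site),
B (the stimulated site), and C (a control) — each with 40 excitatory and
40 inhibitory integrate-and-fire units, plus a 40-motoneuron pool per
column that turns cortical output into simulated EMG.

### Unit dynamics

Each unit carries two leaky accumulators, a slow one with time constant
$\tau_s = 3.2$ ms and a fast one with $\tau_f = 0.8$ ms. Both receive the
same synaptic input $A_i(t)$, and the membrane potential is their
difference,

$$V_i(t) = V^s_i(t) - V^f_i(t),$$

so a single presynaptic spike through a connection of weight $w$ evokes a
PSP shaped as a difference of exponentials,
$w\,(e^{-t/\tau_s} - e^{-t/\tau_f})$, rising in about 1.48 ms to a peak of
$k^* w$ with $k^* = 0.4725$. Connection *strength* — what the package
reports — is this PSP maximum in microvolts. Decays are integrated with
forward Euler at a step of $h = 0.1$ ms; a unit fires when $V_i$ strictly
exceeds its threshold (5 mV for cortical units) and both accumulators are
reset to zero on the next step, which is the only refractory mechanism.
Spikes reach other cortical units after a 3-ms conduction delay and
motoneurons after 10 ms.

Within a step the engine (1) gathers delayed spikes and external events
into $A_i(t)$, (2) evaluates spikes from the current $V_i(t)$, (3) applies
plasticity with the trace values from before this step's increments,
(4) advances traces, (5) advances the accumulators with reset taking
precedence over input, and (6) applies stimulus steps. Because stimulation
is applied after the reset, a stimulus that coincides with a spike is
never silently swallowed.

### Background input

Every cortical unit receives excitatory bias events at 1800/s with
350-µV PSPs. Thirty percent arrive as *correlated* column-wide events:
the column event time is drawn per step, and each unit receives one
delivery jittered by a Gaussian with 3-ms SD (truncated at ±4 SD; the
engine decides each event 4 SD ahead of its delivery center so the
closed loop never looks into the future). The remaining 70% are
independent per unit. The correlated fraction controls within-column
synchrony, which is what most conditioning protocols feed on. Bias
probabilities can be modulated in time; cycle-triggered runs impose
20-Hz sinusoidal episodes (six cycles, four per 10-s block, evenly
spaced, depth 0.5) on column B. The depth is not prescribed by the
experimental literature; 0.5 was chosen once so the 15–25-Hz filtered
LFP shows episodes clearly above the 2-SD arming level, and is exposed
in `episode_spec()`.

### Plasticity

Spike-timing-dependent plasticity follows an asymmetric double-exponential
curve: potentiation $r(e^{-\Delta t/a_s} - e^{-\Delta t/a_f})$ for a
postsynaptic spike $\Delta t \ge 0$ after presynaptic arrival, depression
$-c\,r(e^{\Delta t/b_s} - e^{\Delta t/b_f})$ for $\Delta t < 0$, with
$r = 100$, $c = 0.55$, $a_s, a_f = 15.4, 2$ ms and $b_s, b_f = 33.3, 2$ ms.
The depression side is shallower but wider (area $1721.5$ versus $1340$),
so untargeted weights drift to small values — the preconditioned steady
state from which conditioning effects stand out. Rather than scanning
spike pairs, the engine maintains per-unit strengthening and weakening
traces (the same difference-of-exponentials recursions, without reset) and
applies
$\Delta w_{ij} = r\,\mathrm{sgn}(w_{ij})\,(S_j U_i - c\,T_i U_j^{(d)})$
at spike and arrival events; `r` and `c` scale only the update, and the
traces accumulate unit impulses, so an isolated pair reproduces the curve
exactly. Weights are hard-clipped to $[w_{min}, w_{max}]$ (excitatory) or
its mirror (inhibitory), with $w_{min} = 1$ and $w_{max}$ set by a 500-µV
maximum strength; the clip floor means no weight ever changes sign. A
graded "squashing" alternative exists in the configuration surface but is
intentionally not implemented. The same curve serves excitatory and
inhibitory connections.

### Connectivity

Excitatory units connect to every other cortical unit (any column) with
probability 1/6; inhibitory units connect within their column with
probability 1/3; no self-connections. Initial strengths are uniform in
20–60% of the maximum (100–300 µV), signed by source type, and plastic.
Each motor pool receives corticomotoneuronal input from its column's
excitatory units with probability 1/3; these connections are fixed at
350 µV — they are absent from every plastic-weight analysis in the
source experiments, and no strength is stated, so the external-input PSP
strength is reused. Motoneuron thresholds rise linearly from 5 to 6 mV
while motor-unit potentials rise from 0.5 to 1.5 mV, an explicit size
principle: small units recruit first and contribute small EMG spikes.

Motoneurons also receive uncorrelated background drive standing in for
all their non-cortical input. No rate is stated for it anywhere; it was
set (once) to 1500 events/s at 350 µV, which produces sparse motor-unit
firing (~1.5 Hz) comparable to the published raster figures and — the
operational constraint that matters — makes the documented EMG-trigger
rate of ~6/s reachable by threshold calibration. At 1000/s the pools are
essentially silent and no threshold achieves that trigger rate.

### Signals and the EP measure

The LFP of a column is the running sum of all PSPs arriving at its
cortical units, including bias PSPs but *excluding* direct stimulus steps:
an evoked potential should measure synaptic transmission, and the 2–3-mV
stimulus artifacts would swamp it. EMG is the same superposition over a
pool's motor-unit potentials, band-passed 100–2500 Hz.

Connectivity between columns is probed with 3-mV test pulses. The EP for
a directed pair is measured on the stimulus-aligned *average* LFP:
segments are baseline-subtracted (mean over −20–0 ms) and averaged, and
the EP is the signed extremum in the 3–18-ms post-stimulus window (start
past the 3-ms conduction delay). Averaging before the peak pick matters:
single-trial LFP fluctuations driven by correlated bias volleys are tens
of millivolts, far larger than a baseline EP, and a per-trial extremum
would measure the noise envelope instead of transmission. Percent change
is $100\,(\text{post} - \text{pre})/\text{pre}$.

During testing periods one column is stimulated every 0.4 s (rotating
A, B, C), so each directed pair accumulates an average every 1.2 s —
dense enough that the reduced 80–100-s testing periods used in the test
suite average 60–80 trials per pair. Cycle-triggered runs instead use
fixed per-block test times that fall outside the oscillatory episodes,
keeping test responses clear of episode-locked activity; the same
schedule is used for all columns so B→A EPs are measured concurrently.

## Conditioning protocols

All protocols run inside the standard four-period schedule
(settle / test / condition / test, plasticity on/off/on/off):

* **Spike-triggered** — every spike of unit Ae1 triggers a 2-mV stimulus
  to all of column B at a configurable delay. Delays near 10 ms let the
  A volley arrive just before the stimulus-evoked B spikes (potentiation);
  at 0 ms the stimulus beats the 3-ms conduction delay and the pairing
  reverses (depression). Negative amplitudes give spike-triggered
  inhibition.
* **EMG-triggered** — rising threshold crossings of the band-passed
  column-A EMG trigger B stimuli (20-ms lockout). The threshold is
  calibrated by bisection on the preconditioning-test recording to ~6
  triggers/s, matching the stimulation rates of the other protocols.
* **Gamma-triggered** — like EMG triggering but from band-passed LFP A
  (default 50–80 Hz, falling edge, 10-ms lockout). Falling crossings
  follow the coincident Ae volley that generated the gamma deflection.
* **Cycle-triggered** — the column-B LFP is filtered 15–25 Hz with a
  causal second-order Butterworth filter running sample-by-sample inside
  the loop; when it exceeds an arming level (2 SD of the filtered
  baseline recording) the next zero crossing defines phase 0° (rising) or
  180° (falling), and the stimulus to column A is delivered at the
  crossing plus (phase mod 180)/360 of the 50-ms period, with a 35-ms
  lockout so each beta cycle triggers once. The filter's group delay is
  deliberately part of the loop — it is why the measured optimum sits
  near −15° rather than 0°.
* **Paired-pulse** — open-loop A-then-B pulse pairs (or 33-ms triplet
  trains) at 1.4 Hz, the rate that reproduces ~700 pairs per 500-s
  period; the signed delay sets which column leads.
* **Tetanic** — open-loop Poisson stimulation (default 10 Hz) with an
  imposed 10-ms refractory period, the activity-independent control.
  Intervals are drawn as refractory + exponential with mean chosen so the
  empirical rate equals the nominal rate exactly.

The disynaptic experiments condition A→C→B in networks whose direct A–B
connections were deleted before conditioning; `disynaptic_comparison()`
runs matched intact/lesioned twins from identical seeds and recovers the
intact network's disynaptic component by re-testing after deleting the
direct pathway. These comparisons exploit a structural property of the
engine: bias generation consumes the RNG independently of network state,
so different weight states re-tested under the same seed experience the
*identical* external input realization. The disynaptic EPs are therefore
measured as matched differences against the unconditioned baseline state
under one shared input stream, cancelling the background-LFP sampling
noise that would otherwise swamp a millivolt-scale disynaptic component
in reduced testing periods. The conditioning period itself is kept at
the full 500 s (the ~700-pair dose); shortening it to 100 s (~140 pairs)
does not reliably build the relay pathway. `configure_fic()` builds the fixed-intracolumn variant:
complete, non-plastic 200–300-µV connections inside each column with the
correlated bias share removed (the full 1800/s is then delivered
uncorrelated), making recurrent activity the synchrony source.

## Numerical choices and reproducibility

* $h = 0.1$ ms balances cost and accuracy; the constructor accepts the
  supported set {0.1, 0.05, 0.025, 0.02, 0.01}. Euler integration
  overshoots the continuous kernel peak by ~3% at $h = 0.1$; weight/
  strength conversion deliberately uses the continuous-time $k^*$ so
  configured bounds do not depend on $h$.
* The engine's trace-based weight updates match brute-force pairwise
  summation of the STDP curve within 1% of the gross pairwise magnitude
  at $h = 0.1$, converging as $h$ shrinks (verified in the tests).
* Thresholds compare strictly (`>`); a potential exactly at threshold
  does not fire.
* All randomness flows through R's RNG: a master seed spawns named
  substream seeds for topology, each period, and calibration, so a
  lesioned twin shares every common connection with its intact original
  and protocol changes do not perturb the build. Engine state persists
  across calls, so split runs are bit-identical to whole runs.
* Trigger-path filters are causal (closed-loop constraint); offline
  analysis filters (EMG band-pass in `synthesize_emg()`) may be
  zero-phase.

## Problem sizes used in the checks

The test suite and the acceptance script run the full 360-unit network at
reduced durations: 80–100-s periods instead of 500 s, which the settling
analysis justifies (the unconditioned steady state is reached in under
60 s). The cycle-trigger phase sweep uses 24 phases at 15° spacing with
three replicate networks and 100-s periods, sharing each network's
settle/baseline across phases so phase comparisons are exactly matched.
The disynaptic comparison uses five matched seed pairs. These scales are
the package's validation choices; longer runs only narrow the EP
sampling noise.

## What the simulations do and do not show

The generator *is* the study system here — there is no external data.
Passing checks demonstrate that the implemented mechanisms (twin-integrator
units, trace STDP, correlated bias, closed-loop triggering) reproduce the
documented conditioning phenomenology at the stated parameters. They do
not speak to biological completeness: units have no conductances or
intrinsic refractoriness beyond the reset, depolarization-dependent (non-
spike) plasticity is absent, inhibitory STDP uses the same curve as
excitatory, and each column is an idealized, cleanly separated population
whose synchrony is imposed by the bias input rather than emerging from
recurrence (except in the fixed-intracolumn variant). The known
in-vivo/model discrepancy in the optimal beta phase (experiments report
roughly −90°, the model family −15°) is a property of this model class
and is reproduced, not resolved, here.

## Session info

```{r}
sessionInfo()
```
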