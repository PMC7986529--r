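# stdpnet

Closed-loop brain-computer interfaces can strengthen or weaken specific
synaptic pathways in motor cortex: stimulating site B each time a neuron at
site A fires, each time the muscle of site A contracts, or at a chosen phase
of spontaneous beta oscillations all produce targeted connectivity changes,
as does open-loop paired stimulation of two sites. `stdpnet` is a simulator
for this family of conditioning experiments, intended for computational and
systems neuroscientists who want to explore why these protocols work, how
their efficacy depends on delays, phases, intensities and network synchrony,
and what novel protocols (spike-triggered inhibition, gamma-triggered
stimulation, disynaptic conditioning) should do before running them in vivo.

## The model in brief

A 360-unit network: three cortical columns (A recorded, B stimulated,
C control) of 40 excitatory + 40 inhibitory integrate-and-fire units each,
plus a 40-motoneuron pool per column. Each unit keeps twin leaky
integrators, V(t) = Vˢ(t) − Vᶠ(t) with τₛ = 3.2 ms, τ_f = 0.8 ms, so one
spike evokes a difference-of-exponentials PSP; a unit fires when V strictly
exceeds threshold (5 mV) and resets. Spikes conduct in 3 ms between
cortical units and 10 ms to motoneurons. Background bias input (1800
events/s per unit, 30% as jittered column-wide volleys) sets the operating
point and the within-column synchrony.

Plasticity is trace-based STDP:

    Δw_ij = r · sgn(w_ij) · ( S_j(t) · U_i(t) − c · T_i(t) · U_j(t − d) )

with potentiation/depression curves r(e^(−Δt/aₛ) − e^(−Δt/a_f)) and
−c·r(e^(Δt/bₛ) − e^(Δt/b_f)), r = 100, c = 0.55, aₛ, a_f = 15.4, 2 ms,
bₛ, b_f = 33.3, 2 ms, and hard clipping of |w| to [1, w_max] where w_max
corresponds to a 500-µV PSP maximum. Inter-column connectivity is probed by
evoked potentials (EPs): the stimulus-aligned average LFP deflection in the
recorded column after a 3-mV test pulse to another column, with conditioning
quantified as 100·(post − pre)/pre.

Protocols: `spike_triggered`, `spike_triggered_inhibition`,
`emg_triggered`, `gamma_triggered`, `cycle_triggered` (closed-loop, with
causal Butterworth trigger filters running inside the simulation loop),
`paired_pulse` (including triplet trains) and `tetanic` (open-loop
controls). The stepping core is C++ (via Rcpp); a 100-s, 360-unit
simulation takes a few seconds on one core, and every run is reproducible
from a single seed.

## Worked example

Spike-triggered conditioning at the standard 10-ms spike–stimulus delay,
with reduced 80–100-s periods (the full-scale experiment uses 500 s per
period; the network reaches its unconditioned steady state in under a
minute, so reduced runs show the same effects with wider error bars):

```r
library(stdpnet)
res <- run_conditioning("spike_triggered", seed = 1,
                        periods = c(80, 80, 100, 80))
res$n_triggers
#> [1] 986
round(res$ep_increase, 1)
#>      A     B     C
#> A   NA 132.1 -47.8
#> B -4.2    NA -49.4
#> C 79.5  78.2    NA
round(res$strength_conditioned["A", "B"], 1)  # from 52.4 uV settled
#> [1] 136.2
```

The 986 trigger spikes of unit Ae1 each delivered a 2-mV stimulus to
column B 10 ms later. The A→B evoked potential grew by 132% while the
other directed pairs fluctuate within the measurement noise of these
reduced testing periods, and the mean A→B connection strength grew
2.6-fold — only the targeted pathway's underlying weights changed
appreciably. Re-running with `delay = 0` *decreases* the A→B EP (the
stimulus then precedes the 3-ms spike arrival, reversing the STDP
pairing), and `protocol_spec("cycle_triggered", phase = 0)` versus
`phase = 180` flips which of A→B / B→A strengthens.

`run_conditioning()` returns the pre/post EP matrices, mean-strength
matrices, weight snapshots and a manifest; `cycle_phase_sweep()`,
`disynaptic_comparison()`, `track_weights()` and the signal-level tools
(`measure_ep()`, `trigger_aligned_histogram()`, `synthesize_emg()`)
support the derived analyses. A command-line front end is installed at
`inst/scripts/simulate.R`.

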