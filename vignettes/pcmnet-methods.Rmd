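---
title: "Modeling STDP in 1T1R phase-change synapses and unsupervised pattern learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling STDP in 1T1R phase-change synapses and unsupervised pattern learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmnet)
```

`pcmnet` simulates synaptic arrays built from one-transistor/one-resistor
(1T1R) cells with a phase-change-memory (PCM) element, the rectangular-pulse
protocol that gives them spike-timing dependent plasticity (STDP), and
fully connected leaky-integrate-and-fire (LIF) networks that learn binary
visual patterns without supervision. This vignette explains the models,
the parameters that matter, and the design choices made where the
underlying physics or the published behavior left the implementation open.

## The PCM compact model

A PCM cell switches between a low-resistance crystalline phase and a
high-resistance amorphous phase. We reduce the cell to a single state
variable: the *equivalent cumulative crystallization time* `t_eff`, with
resistance a pure function of the state through a master curve.

The master curve is a two-segment log-linear interpolant:

* from the full-reset resistance (20 MΩ) at `t_eff = 0` down to 10 MΩ at
  the incubation time `t_inc = 80 ns` (slow nucleation), then
* down to the full-set resistance (10 kΩ) at the completion time
  `t_c = 200 ns` (fast growth), constant beyond.

A set pulse whose amplitude lies in the window `[V_T, V_m)` (defaults
0.9 V and 1.2 V) advances `t_eff` by its width, which makes
crystallization exactly additive: n pulses of width `t_P` equal one pulse
of width `n·t_P`, and the state is a single serializable scalar. A pulse
above the melting voltage `V_m` amorphizes: the new resistance is given
by the reset characteristic alone (log-linear in voltage from 10 kΩ at
`V_m` to 20 MΩ at 1.75 V, clamped above), independent of prior state and
pulse width — amorphization is quench-limited, so history is erased.

The curve anchors are a *calibration*, not a transcription: they are
chosen so that, from the nearly amorphized 10 MΩ state, five 40 ns set
pulses at 1.05 V recover the full set state (a conductance gain of 10³)
while a single pulse yields only a ten-fold change, and so that a reset
at 1.75 V lands exactly on 20 MΩ. With these anchors three 40 ns pulses
from *full* reset are needed before any appreciable potentiation, which
is the behavior that makes background depression robust in the network.
All anchors live in `device_params()` and can be refit.

## The 1T1R synapse and the STDP protocol

The series transistor is a binary switch plus a constant on-state
resistance `R_MOS = 2.4 kΩ`; no saturation or subthreshold behavior is
modeled. With the gate on, the synapse conducts `V_TE/(R + R_MOS)`; the
standing top-electrode read bias of −30 mV converts a presynaptic gate
pulse into a communication current without disturbing the PCM state.

The PRE spike is a 10 ms gate pulse followed by a 10 ms after-pulse at
zero volts. The POST spike spans 20 ms and carries two 40 ns sub-pulses
on the top electrode: a set pulse (1.05 V) at its start and a reset
pulse (1.75 V) delayed by 10 ms. Plasticity is then pure geometry: for
delays `0 ≤ Δt < 10 ms` the set pulse falls inside the gate window
(potentiation); for `−10 ms < Δt < 0` the reset pulse does
(depression); otherwise nothing overlaps. Two conventions close the
zero-measure cases: `Δt = 0` potentiates (the set pulse enjoys its full
width of overlap), and `|Δt| = 10 ms` does nothing. A brute-force
waveform renderer (`waveform_overlap_oracle()`) is kept as an
independent oracle for the arithmetic classification; the two agree
everywhere except within one sub-pulse width of the boundaries, where
the renderer sees the sliver of overlap the convention discards.

## Network timing semantics

The engine is epoch-granular: each clock period (`t_ck = 10 ms`) one
input frame — a pattern or a noise instance — gates its PREs for the
whole epoch. Within an epoch each layer, in order:

1. applies **pending depression**: a POST that fired in the previous
   epoch emitted a 20 ms spike whose reset sub-pulse lands in the
   current epoch, depressing synapses gated on *now* (`Δt < 0`);
2. **integrates** the read currents onto the membrane capacitance;
3. **fires** neurons that cross threshold, in index order, at most once
   per epoch: each fire potentiates the synapses of the PREs active in
   this epoch (`Δt ≥ 0`), partially discharges all siblings when lateral
   inhibition is enabled (immediately, so earlier fires can veto later
   ones), and arms depression for the next epoch. In 3-layer networks
   the fires gate the next layer within the same epoch.

Two refinements, both read off the waveforms themselves, determine which
synapses the stale reset pulse can actually strike:

* **The after-pulse exclusion.** A PRE active in consecutive epochs is
  still inside its 10 ms zero-volt after-pulse when the previous
  epoch's reset sub-pulse arrives, so its gate is off and it is spared.
  Depression therefore only strikes PREs that are *freshly* active —
  exactly the uncorrelated (noise) inputs. Without this exclusion a
  learned pattern would be erased every time two pattern presentations
  bracket a fire, and no stable learning is possible at a 50/50
  pattern/noise schedule.
* **Spike retriggering.** Fire times are tracked as within-epoch phases
  (the fraction of the epoch at which the membrane crossed threshold).
  If a neuron re-crosses in the current epoch at a phase no later than
  its previous fire, its spike generator restarts before the stale
  reset pulse is due, superseding it entirely. Repeated recognition of
  the same input is therefore self-stabilizing, while a spike landing
  after an uncorrelated fire is depressed — which is precisely the
  failure mode that limits the 2-layer network (below).

## Neurons

Each neuron integrates `|I|·t_ck/C` per epoch (the inverting integrator
makes the negative read current a positive potential step) and fires when
`V_int` strictly exceeds `V_th = 0.5 V`, discharging to zero.

**Capacitance.** The design rule `C ≈ ΔQ/V_th` sizes the capacitance so
that one clock of current from ~10% of the fan-in, potentiated at 15 kΩ
under the 30 mV bias, reaches threshold. For a 784-input neuron this
gives 3.1 µF; the engine scales `C` linearly with fan-in from that
anchor, so a 256-input third-layer neuron gets 1.01 µF and fires when
roughly 8% of its inputs deliver potentiated current simultaneously.

**Leak.** The network default is `tau_leak = 0.15 s` (15 clocks). A pure
integrator accumulates the sub-threshold noise drizzle over unbounded
time; in long runs the blocked neurons then fire perpetually on noise,
and in 3-layer networks their correlated drizzle teaches the output
neuron the *noise-firing* cohort instead of the pattern cohort. A leak
of a few tens of clock periods suppresses multi-epoch accumulation while
leaving single-epoch crossings from a learned pattern (ΔV ≈ 0.59 V per
epoch) untouched. The value was calibrated once, on a coarse grid,
against the reported spurious-fire statistics of the 2-layer baseline;
it was then frozen and the 3-layer results are predictions. The
standalone `lif_neuron()` constructor keeps the ideal-integrator default
(`tau_leak = Inf`) for protocol-level work.

**Inhibition** is a fixed fractional discharge (default 20%) of every
sibling's membrane on a successful fire, used in the parallel
multi-pattern experiment; the single-pattern and recognition experiments
run without it.

## Stimuli

The fixtures are deterministic digit-like bitmaps on the 28×28 retina;
the "1" has exactly 76 active pixels (708 background), matching the
pattern/background split of the single-pattern experiments. Noise frames
activate each PRE independently with probability `noise_density`
(default 51/784 ≈ 6.5%; a fixed-count mode exists). Readers for PGM,
CSV, and IDX bitmaps let real handwritten digits be substituted, but
nothing in the package requires a download.

The generator emulates binarized digit frames with spatially white,
temporally independent noise. It does not emulate writer-to-writer shape
variability, gray levels or rate coding, correlated noise, or
device-to-device variability in the array — passing tests therefore
demonstrate the learning dynamics under the stated idealized conditions,
not recognition performance on a real handwritten-digit corpus.

## What the simulations show

With the defaults (50/50 pattern/noise, 6.5% noise, 7 s), pattern
synapses potentiate to the full-set conductance (10⁻⁴ S) within a few
hundred milliseconds — a handful of pattern-coincident fires — while the
background depresses to the full-reset conductance (5×10⁻⁸ S) over a few
seconds of noise-after-fire events: fast learning, slow forgetting.

Learning can fail absorbingly: a noise-induced fire followed by a
pattern presentation depresses the freshly active pattern synapses in
one shot (the reset transition is abrupt), after which pattern current
is too small to fire the neuron and recovery is unlikely. Averaged over
independent 2 s runs this blockade keeps the 2-layer recognition
probability near 50% in this implementation (the published figure for
the equivalent experiment is lower, about a third; in our engine the
noise-driven repotentiation of the few pattern pixels inside each noise
frame lets some runs relearn, which raises the average). The error
probability — spurious fires on noise frames — is a few percent and is
the quantity the leak constant was calibrated against.

The 3-layer network (784 → M → 1) fixes the blockade by parallelism:
each hidden neuron is an independent 2-layer learner, the output neuron
needs only ~8% of them to fire together, and the hidden neurons that
specialize on noise are pruned from the output weights by the same STDP
rule. Recognition rises with M (≈65% at M = 4 to ≈90% at M = 256 at
6.5% noise) while errors fall; at the reduced 5.5% noise density the
256-neuron network reaches ≈90% recognition with under 1% error in 2 s.
The sweeps use common random numbers across conditions — every M (or
noise density) sees the same per-run seeds — so the comparisons are not
blurred by between-condition sampling noise; note that the recognition
curve is effectively flat between M = 128 and M = 256, so orderings
there are at the edge of 100-run resolution.

Sequential updating (switching the pattern after learning) shows robust
directional behavior — old-pattern-exclusive pixels depress by an order
of magnitude, new-pattern pixels potentiate from the reset floor — but
full re-specialization within 7 s succeeds only for some seeds: the
overlap pixels that bridge current onto the new pattern are themselves
exposed to the noise-fire-then-pattern depression mechanism, and with
the leaky defaults the noise-fire rate that drives relearning is low.

## Energy accounting

Per epoch, the communication energy per synapse is
`E_syn,c = t_ck · Σ V_TE²/(R_i + R_MOS) / (N·M)` over the gated
synapses. After learning, pattern frames dissipate ≈70 pJ per synapse
per clock (group I), noise frames touching a few potentiated pattern
pixels ≈1–5 pJ (group II), and noise frames over the depressed
background <100 fJ (group III); the histogram edges (0.1 pJ, 20 pJ)
separate these levels. Because the learned pattern stays pristine in
this engine, noise frames almost always touch at least one potentiated
pixel and group III is sparsely populated. Fire energy uses
`V²·t_P/(R + R_MOS)` per set/reset event with the resistance at pulse
start; both the per-event values and the array-normalized sum are
reported, since the published per-fire figure does not state its
normalization. The pulsed-read scheme (1 µs pulses every 1 ms) scales
communication energy, power, and the required integrator capacitance by
the duty-cycle factor 10⁻³.

## Numerical choices

* Initial weights are drawn log-uniformly in resistance across the full
  window, emulating a random-set initialization; all draws and epoch
  schedules are reproducible from a single seed per run.
* Master-curve endpoints are snapped exactly (no `10^log10` rounding), so
  full reset is exactly 20 MΩ and endpoint round-trips are bit-clean.
* Fires are resolved in ascending neuron index with immediate
  inhibition; ties at threshold are broken by the strict inequality.
* Problem sizes: the single-pattern experiment runs 700 epochs
  (7 s); recognition statistics average 100 independent 200-epoch runs
  per condition, the sizes used for all reported numbers.

## Known limitations

No electrothermal I–V or threshold-switching dynamics, no resistance
drift, no device-to-device variability, no wire parasitics; the
transistor is a switch with series resistance; time is epoch-granular
(sub-clock spike timing appears only through the fire-phase bookkeeping
described above). The leak constant is a behavioral calibration, not a
circuit measurement. Within those bounds, every quantity reported by the
acceptance script — device anchors, capacitance and power-density design
values, learned-state energies, and the recognition statistics — is
recomputed from simulation at run time.
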