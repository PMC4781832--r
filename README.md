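# pcmnet

Simulation of spike-timing dependent plasticity (STDP) in
one-transistor/one-resistor (1T1R) phase-change-memory (PCM) synapses,
and of fully connected spiking networks that use those synapses to
learn, forget, and update 28×28 visual patterns without supervision.

It is aimed at neuromorphic-hardware researchers who want to explore how
a bistable, abruptly depressing and gradually potentiating memory
element behaves as a synapse: how waveform overlap implements the STDP
rule, how input noise depresses background synapses, why learning can
block, how a hidden layer repairs it, and what the scheme costs in
energy and power.

## The model

**Device.** A PCM cell is one scalar state, the equivalent
crystallization time `t_eff ∈ [0, t_c]`, mapped to resistance by a
two-segment log-linear master curve from 20 MΩ (full reset) through
10 MΩ at the incubation time (80 ns) to 10 kΩ (full set) at 200 ns. Set
pulses with `V_T ≤ V < V_m` add their width to `t_eff` (gradual,
additive crystallization); pulses above the melting voltage `V_m` reset
the cell along a log-linear reset characteristic, erasing history
(abrupt amorphization).

**Synapse and protocol.** The PCM sits in series with a transistor
(`R_MOS = 2.4 kΩ`) gated by the presynaptic neuron; a −30 mV
top-electrode bias turns each 10 ms PRE gate pulse into a read current.
When the postsynaptic neuron fires, it returns a 20 ms spike carrying a
40 ns set pulse (1.05 V) at its start and a 40 ns reset pulse (1.75 V)
10 ms later, so the relative delay `Δt = t_post − t_pre` selects the
outcome:

    0 ≤ Δt < 10 ms   → potentiation (set pulse inside the gate window)
    −10 ms < Δt < 0  → depression  (reset pulse inside the gate window)
    otherwise        → no change

**Network.** LIF neurons integrate `|I|·t_ck/C` per clock
(`C ≈ ΔQ/V_th`, 3.1 µF per 784 inputs, scaled with fan-in; leak
τ = 0.15 s) and fire above 0.5 V. Patterns alternate with Bernoulli
noise frames; noise arriving just after a fire (Δt < 0) depresses the
background, while pattern-coincident fires potentiate the pattern.
Per-synapse communication energy is accounted as
`E_syn,c = t_ck · Σ V_TE²/(R_i + R_MOS)/(N·M)`.

## A worked example

```r
library(pcmnet)

# gradual potentiation from the nearly amorphized state (10 MOhm)
s <- pcm_state(state_from_resistance(1e7))
for (n in c(1, 3, 5)) {
  st <- Reduce(function(x, i) apply_set_pulse(x, 1.05, 40e-9),
               seq_len(n), init = s)
  cat(sprintf("%d spikes: R = %.3g ohm (R0/R = %.3g)\n",
              n, master_curve(st$t_eff), 1e7 / master_curve(st$t_eff)))
}
#> 1 spikes: R = 1e+06 ohm (R0/R = 10)
#> 3 spikes: R = 1e+04 ohm (R0/R = 1e+03)
#> 5 spikes: R = 1e+04 ohm (R0/R = 1e+03)

# unsupervised learning of the 76-pixel "1" on the 784-PRE retina
sp <- run_single_pattern(duration = 7, seed = 2)
tail(sp$trace$G_pattern_1, 1)     # 1e-04  : pattern at full-set conductance
tail(sp$trace$G_background_1, 1)  # 5e-08  : background at full reset
max(sp$trace$E_syn_c) * 1e12      # 70.4   : peak pJ per synapse per clock
sp$report
#> recognition report: n = 700 (pattern 345, noise 355)
#>   P_learn = 0.977 (337/345)   P_err = 0.003 (1/355)
```

One spike barely moves the amorphized cell while five restore the full
10³ conductance window — the cumulative-crystallization signature. In
the network run, the pattern synapses reach the full-set conductance
(10⁻⁴ S) while uncorrelated noise drives the 708 background synapses to
full reset, after which nearly every pattern frame fires the output
(`P_learn`) and noise frames almost never do (`P_err`). The peak
communication energy of ~70 pJ per synapse per clock corresponds to
~7 nW per synapse during a pattern frame.

Other experiment runners: `run_stdp_map()` (per-state STDP
characterization), `run_random_delay()`, `run_sequential()` (forget and
update), `run_parallel()` (multiple patterns with lateral inhibition),
`run_multilayer_sweep()` and `run_noise_sweep()` (recognition
statistics of 2- and 3-layer networks). A command-line wrapper with one
subcommand per experiment is in `inst/cli/pcmnet.R`; YAML configuration
handling is in `read_config()` / `write_default_config()`.

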