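device:
  R_set_full: 10000.0
  R_reset_full: 20000000.0
  V_m: 1.2
  V_T: 0.9
  V_reset_full: 1.75
  t_inc: 8.0e-08
  t_c: 2.0e-07
  R_inc: 10000000.0
synapse:
  R_MOS: 2400.0
  V_TE_read: -0.03
protocol:
  t_ck: 0.01
  V_G: 0.87
  pre_width: 0.01
  V_set: 1.05
  V_reset: 1.75
  t_P: 4.0e-08
  post_reset_offset: 0.01
  post_total: 0.02
neuron:
  V_th: 0.5
  tau_leak: 0.15
network:
  'N': 784
  M: 1
  layers: 2
  inhibition_on: no
inhibition:
  discharge_fraction: 0.2
schedule:
  patterns:
  - '1'
  pattern_probs:
  - 0.5
  noise_density: 0.065051020408
  mode: bernoulli
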