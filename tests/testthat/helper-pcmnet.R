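# shared fixtures: default parameter sets and a tiny hand-built network

dev <- device_params()
syn_par <- synapse_params()
prot <- protocol_params()

# synapse prepared at a given resistance on the master curve
syn_at <- function(R) {
  synapse_1t1r(pcm_state(state_from_resistance(R, dev), dev),
               params = syn_par, device_params = dev)
}

# small fully specified network for step-semantics tests: N inputs, M
# posts, all synapses full set, capacitance chosen so that `n_cross`
# simultaneous full-set synapses cross threshold in one epoch
tiny_net <- function(N = 4, M = 1, n_cross = 2, layers = 2,
                     tau_leak = Inf, inhibition_on = FALSE) {
  i1 <- abs(syn_par$V_TE_read) / (dev$R_set_full + syn_par$R_MOS)
  C <- (n_cross - 0.5) * i1 * prot$t_ck / 0.5
  cfg <- network_config(N = N, M = M, layers = layers,
                        C_hidden = C, C_out = C, tau_leak = tau_leak,
                        inhibition_on = inhibition_on, seed = 1)
  build_network(cfg, init = "full_set")
}
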