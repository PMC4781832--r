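#' Network configuration
#'
#' Describes a fully connected 2- or 3-layer network of 1T1R synapses and
#' LIF neurons: an N-neuron input retina, M second-layer neurons, and (for
#' 3 layers) a single output neuron. Per-neuron capacitance follows the
#' design rule `C ~ dQ / V_th` and scales linearly with fan-in, anchored
#' at 3.1 uF for a 784-input neuron (10% of inputs potentiated at 15 kohm
#' under the 30 mV read bias for one 10 ms clock); explicit values
#' override the rule.
#'
#' @param N First-layer (retina) size.
#' @param M Second-layer size.
#' @param layers 2 or 3 (a third layer has one output neuron).
#' @param device A [device_params()] object.
#' @param synapse A [synapse_params()] object.
#' @param protocol A [protocol_params()] object.
#' @param V_th Comparator threshold shared by all neurons, volts.
#' @param C_hidden Capacitance of the second-layer neurons, farads
#'   (default: fan-in rule).
#' @param C_out Capacitance of the output neuron (3-layer only), farads
#'   (default: fan-in rule).
#' @param tau_leak Membrane leak time constant, seconds (`Inf` = ideal
#'   integrator). The default of a few tens of clock periods lets a
#'   neuron cross threshold on the strong within-epoch current of a
#'   learned pattern while damping multi-epoch accumulation of
#'   sub-threshold noise drizzle; it is calibrated so the spurious-fire
#'   rate of the 2-layer baseline matches the reported error probability.
#' @param inhibition An [inhibition_config()].
#' @param inhibition_on Logical; apply lateral inhibition among
#'   second-layer neurons on each fire?
#' @param seed Optional RNG seed used by [build_network()].
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 784, M = 1, layers = 2,
                           device = device_params(),
                           synapse = synapse_params(),
                           protocol = protocol_params(),
                           V_th = 0.5,
                           C_hidden = NULL,
                           C_out = NULL,
                           tau_leak = 0.15,
                           inhibition = inhibition_config(),
                           inhibition_on = FALSE,
                           seed = NULL) {
  stopifnot(N >= 1, M >= 1, layers %in% c(2, 3))
  C_base <- 3.1e-6 # 784-input anchor of the C ~ dQ/V_th sizing rule
  if (is.null(C_hidden)) C_hidden <- C_base * N / 784
  if (is.null(C_out)) C_out <- C_base * M / 784
  structure(list(N = N, M = M, layers = layers, device = device,
                 synapse = synapse, protocol = protocol, V_th = V_th,
                 C_hidden = C_hidden, C_out = C_out, tau_leak = tau_leak,
                 inhibition = inhibition, inhibition_on = inhibition_on,
                 seed = seed),
            class = "network_config")
}

#' Build a network simulation state
#'
#' Synapse states are stored as matrices of the device state variable
#' `t_eff` (one entry per synapse); neurons start discharged. With
#' `init = "random"` each synapse resistance is drawn log-uniformly on
#' `[R_set_full, R_reset_full]`, emulating the random-set initialization
#' that spreads initial conductances across the full device window.
#' Deterministic under a fixed `config$seed`.
#'
#' @param config A [network_config()].
#' @param init `"random"`, `"full_reset"`, or `"full_set"`.
#' @return An object of class `pcm_network`.
#' @export
build_network <- function(config, init = c("random", "full_reset", "full_set")) {
  init <- match.arg(init)
  if (!is.null(config$seed)) set.seed(config$seed)
  dev <- config$device
  draw <- function(n) {
    switch(init,
      random = {
        R <- 10^stats::runif(n, log10(dev$R_set_full), log10(dev$R_reset_full))
        state_from_resistance(R, dev)
      },
      full_reset = rep(0, n),
      full_set = rep(dev$t_c, n))
  }
  st <- list(
    config = config,
    W1 = matrix(draw(config$N * config$M), config$N, config$M),
    V1 = numeric(config$M),
    pend1 = logical(config$M),
    phase1 = numeric(config$M),
    epoch = 0L)
  if (config$layers == 3) {
    st$W2 <- matrix(draw(config$M), config$M, 1)
    st$V2 <- 0
    st$pend2 <- FALSE
    st$phase2 <- 0
  }
  class(st) <- "pcm_network"
  st
}

#' @export
print.pcm_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("PCM network: %d -> %d%s, epoch %d\n", cfg$N, cfg$M,
              if (cfg$layers == 3) " -> 1" else "", x$epoch))
  invisible(x)
}

# One layer of the epoch update. W is n_in x n_out (t_eff), `active` the
# gated input indices, `active_prev` the previous epoch's. Implements, in
# order: (1) pending depression from last epoch's POST spikes; (2) charge
# integration; (3) threshold fires in index order with same-epoch
# potentiation, immediate lateral inhibition and the pending-depression
# flag for the next epoch. Returns updated arrays plus raw (unnormalized)
# communication and fire energies.
.step_layer <- function(W, V, pend, phase, active, active_prev, C, V_th,
                        dev, syn, prot, inhibit_frac, t_reset,
                        tau_leak = Inf) {
  n_out <- ncol(W)
  na <- length(active)
  Vte <- abs(syn$V_TE_read)
  E_f_raw <- 0; n_set <- 0L; n_reset <- 0L
  V <- V * exp(-prot$t_ck / tau_leak) # leak applied first
  if (na > 0) {
    Ra <- matrix(master_curve(W[active, , drop = FALSE], dev), nrow = na)
    G <- 1 / (Ra + syn$R_MOS)
    dV <- Vte * .colSums(G, na, n_out) * prot$t_ck / C
  } else {
    Ra <- NULL
    dV <- numeric(n_out)
  }

  # LTD from last epoch's fires: the reset sub-pulse of the 20 ms POST
  # spike lands one clock after the fire. It can only strike PREs whose
  # gate is freshly on this epoch: a PRE that also spiked in the fire
  # epoch is still in its 10 ms zero-volt after-pulse, so its gate is off
  # when the stale reset pulse arrives. In addition, if the neuron's
  # membrane re-crosses threshold this epoch at a phase no later than its
  # fire phase of last epoch, the spike generator retriggers first and
  # the stale reset pulse is superseded entirely.
  f_cross <- ifelse(dV > 0, (V_th - V) / dV, Inf)
  retrig <- pend & f_cross <= phase & f_cross <= 1
  ltd <- which(pend & !retrig)
  ltd_rows <- match(setdiff(active, active_prev), active)
  if (length(ltd) > 0 && length(ltd_rows) > 0) {
    Rstart <- Ra[ltd_rows, ltd, drop = FALSE]
    E_f_raw <- E_f_raw + sum(prot$V_reset^2 * prot$t_P / (Rstart + syn$R_MOS))
    n_reset <- n_reset + length(Rstart)
    W[active[ltd_rows], ltd] <- t_reset
    Rnew <- matrix(master_curve(W[active[ltd_rows], ltd, drop = FALSE], dev),
                   nrow = length(ltd_rows))
    Ra[ltd_rows, ltd] <- Rnew
    G[ltd_rows, ltd] <- 1 / (Rnew + syn$R_MOS)
    dV[ltd] <- Vte * .colSums(G[, ltd, drop = FALSE], na, length(ltd)) *
      prot$t_ck / C
  }
  pend[] <- FALSE

  E_c_raw <- if (na > 0) prot$t_ck * Vte^2 * sum(G) else 0

  V0 <- V
  V <- V + dV
  fired <- integer(0)
  for (j in which(V > V_th)) {
    if (V[j] <= V_th) next # discharged below threshold by an earlier sibling
    phase[j] <- min(1, max(0, (V_th - V0[j]) / dV[j]))
    V[j] <- 0
    pend[j] <- TRUE
    fired <- c(fired, j)
    if (na > 0) {
      E_f_raw <- E_f_raw + sum(prot$V_set^2 * prot$t_P / (Ra[, j] + syn$R_MOS))
      n_set <- n_set + na
      W[active, j] <- pmin(W[active, j] + prot$t_P, dev$t_c)
    }
    if (inhibit_frac > 0 && n_out > 1)
      V[-j] <- V[-j] * (1 - inhibit_frac)
  }

  list(W = W, V = V, pend = pend, phase = phase, fired = fired,
       E_c_raw = E_c_raw, E_f_raw = E_f_raw, n_set = n_set,
       n_reset = n_reset)
}

#' Advance the network by one epoch
#'
#' One clock period: the given PRE set is gated on for the whole epoch.
#' In order, each layer applies pending depression from the previous
#' epoch's POST spikes (the reset sub-pulse lands one clock after the
#' fire, so it depresses the synapses whose PRE spike is freshly active
#' *this* epoch; a PRE that also spiked in the fire epoch is still in its
#' 10 ms zero-volt after-pulse and is spared), integrates the synaptic
#' read currents, and fires neurons that cross threshold -- each fire
#' potentiating the synapses of this epoch's active PREs, partially
#' discharging siblings when lateral inhibition is on, and arming
#' depression for the next epoch. A neuron that re-fires this epoch no
#' later (in within-epoch phase) than it fired last epoch retriggers its
#' spike generator, superseding the stale reset sub-pulse: repeated
#' recognition of the same input is therefore stable, while a spike
#' falling after an *uncorrelated* fire is depressed. In 3-layer networks
#' the second-layer fires gate the third layer within the same epoch.
#'
#' @param state A [build_network()] state.
#' @param active Integer vector of active PRE indices (possibly empty).
#' @param kind,label Optional annotations stored in the epoch record.
#' @return A list with `state` (updated) and `record` (named list: fires,
#'   per-synapse communication and fire energy, event counts).
#' @export
step_epoch <- function(state, active, kind = "pattern", label = "") {
  cfg <- state$config
  prot <- cfg$protocol
  t_reset <- if (prot$V_reset > cfg$device$V_m) {
    state_from_resistance(reset_characteristic(prot$V_reset, cfg$device),
                          cfg$device)
  } else NA_real_
  l1 <- .step_layer(state$W1, state$V1, state$pend1, state$phase1, active,
                    state$prev_active %||% integer(0),
                    cfg$C_hidden, cfg$V_th, cfg$device, cfg$synapse, prot,
                    if (cfg$inhibition_on) cfg$inhibition$discharge_fraction else 0,
                    t_reset, cfg$tau_leak)
  state$W1 <- l1$W; state$V1 <- l1$V
  state$pend1 <- l1$pend; state$phase1 <- l1$phase
  state$prev_active <- active
  n_syn <- cfg$N * cfg$M
  E_c_raw <- l1$E_c_raw; E_f_raw <- l1$E_f_raw
  n_set <- l1$n_set; n_reset <- l1$n_reset
  out_fired <- length(l1$fired) > 0
  if (cfg$layers == 3) {
    l2 <- .step_layer(state$W2, state$V2, state$pend2, state$phase2,
                      l1$fired, state$prev_active2 %||% integer(0),
                      cfg$C_out, cfg$V_th, cfg$device,
                      cfg$synapse, prot, 0, t_reset, cfg$tau_leak)
    state$W2 <- l2$W; state$V2 <- l2$V
    state$pend2 <- l2$pend; state$phase2 <- l2$phase
    state$prev_active2 <- l1$fired
    n_syn <- n_syn + cfg$M
    E_c_raw <- E_c_raw + l2$E_c_raw; E_f_raw <- E_f_raw + l2$E_f_raw
    n_set <- n_set + l2$n_set; n_reset <- n_reset + l2$n_reset
    out_fired <- length(l2$fired) > 0
  }
  state$epoch <- state$epoch + 1L
  record <- list(epoch = state$epoch, kind = kind, label = label,
                 n_active = length(active),
                 n_fired_hidden = length(l1$fired),
                 out_fired = out_fired,
                 E_syn_c = E_c_raw / n_syn,
                 E_syn_f = E_f_raw / n_syn,
                 n_set = n_set, n_reset = n_reset)
  list(state = state, record = record)
}

#' Run a schedule of epochs
#'
#' Draws one input per epoch from the schedule (using the ambient RNG
#' state; seed for reproducibility), steps the network, and accumulates a
#' per-epoch trace. Optionally monitors the mean conductance of named PRE
#' index sets (e.g. pattern versus background pixels) for each
#' second-layer neuron.
#'
#' @param state A [build_network()] state.
#' @param schedule An [make_schedule()] object.
#' @param n_epochs Number of epochs (e.g. `duration / t_ck`).
#' @param monitor Optional named list of PRE index vectors whose mean
#'   synapse conductance is recorded each epoch.
#' @return A list with `state` and `trace` (a data frame, one row per
#'   epoch; monitored conductances in columns `G_<name>_<post>`).
#' @export
run_epochs <- function(state, schedule, n_epochs, monitor = NULL) {
  n_epochs <- as.integer(n_epochs)
  cfg <- state$config
  kind <- character(n_epochs); label <- character(n_epochs)
  n_active <- integer(n_epochs); n_fired <- integer(n_epochs)
  out_fired <- logical(n_epochs)
  E_c <- numeric(n_epochs); E_f <- numeric(n_epochs)
  n_set <- integer(n_epochs); n_reset <- integer(n_epochs)
  mon <- NULL
  if (!is.null(monitor)) {
    mon <- array(NA_real_, c(n_epochs, length(monitor), cfg$M),
                 dimnames = list(NULL, names(monitor), NULL))
  }
  for (e in seq_len(n_epochs)) {
    inp <- sample_epoch(schedule, cfg$N)
    res <- step_epoch(state, inp$active, inp$kind, inp$label)
    state <- res$state
    r <- res$record
    kind[e] <- r$kind; label[e] <- r$label
    n_active[e] <- r$n_active; n_fired[e] <- r$n_fired_hidden
    out_fired[e] <- r$out_fired
    E_c[e] <- r$E_syn_c; E_f[e] <- r$E_syn_f
    n_set[e] <- r$n_set; n_reset[e] <- r$n_reset
    if (!is.null(mon)) {
      for (s in seq_along(monitor)) {
        idx <- monitor[[s]]
        G <- 1 / master_curve(state$W1[idx, , drop = FALSE], cfg$device)
        mon[e, s, ] <- .colMeans(G, length(idx), cfg$M)
      }
    }
  }
  trace <- data.frame(epoch = seq_len(n_epochs), kind = kind, label = label,
                      n_active = n_active, n_fired_hidden = n_fired,
                      out_fired = out_fired, E_syn_c = E_c, E_syn_f = E_f,
                      n_set = n_set, n_reset = n_reset,
                      stringsAsFactors = FALSE)
  if (!is.null(mon)) {
    for (s in seq_along(monitor)) {
      for (m in seq_len(cfg$M)) {
        trace[[sprintf("G_%s_%d", names(monitor)[s], m)]] <- mon[, s, m]
      }
    }
  }
  list(state = state, trace = trace)
}

#' Synapse weight map of one second-layer neuron
#'
#' The conductances of the N input synapses of POST `j`, reshaped to the
#' 28x28 retina grid (or a vector when N is not 784).
#'
#' @param state A [build_network()] state.
#' @param j Second-layer neuron index.
#' @return A 28x28 numeric matrix of conductances in siemens (or a length
#'   N vector).
#' @export
weight_map <- function(state, j = 1) {
  G <- 1 / master_curve(state$W1[, j], state$config$device)
  if (state$config$N == 784) matrix(G, 28, 28) else G
}
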