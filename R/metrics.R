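#' Per-synapse communication energy of one epoch
#'
#' Energy dissipated by the constant TE read bias across the synapses
#' gated on by a PRE spike, averaged over the whole array:
#' `E_syn_c = t_ck * sum_i V_TE^2 / (R_i + R_MOS) / (N * M)`.
#'
#' @param active_resistances PCM resistances of the gated synapses, ohms.
#' @param V_TE TE read bias, volts.
#' @param t_ck Clock period, seconds.
#' @param N,M Array dimensions (PRE and POST counts).
#' @param R_MOS Transistor series resistance, ohms.
#' @return Energy in joules (0 for an empty active set).
#' @export
communication_energy <- function(active_resistances, V_TE = -0.030,
                                 t_ck = 10e-3, N = 784, M = 1,
                                 R_MOS = 2.4e3) {
  if (length(active_resistances) == 0) return(0)
  stopifnot(all(active_resistances > 0))
  t_ck * sum(V_TE^2 / (active_resistances + R_MOS)) / (N * M)
}

#' Per-synapse fire energy of one epoch
#'
#' Energy of the set/reset sub-pulses delivered by POST spikes. Each
#' plasticity event dissipates `V^2 * t_P / (R + R_MOS)` with `V` the
#' applied amplitude and `R` the synapse resistance at pulse start
#' (before the transition); the total is normalized by the array size
#' like the communication energy. The unnormalized per-event energies are
#' returned as an attribute, since per-event and array-averaged
#' conventions differ by orders of magnitude.
#'
#' @param events A data frame (or list) with columns `V` (pulse amplitude,
#'   volts) and `R_start` (resistance at pulse start, ohms); one row per
#'   plasticity event.
#' @param t_P Sub-pulse width, seconds.
#' @param N,M Array dimensions.
#' @param R_MOS Transistor series resistance, ohms.
#' @return Array-normalized energy in joules, with attribute
#'   `"per_event"` holding the raw event energies.
#' @export
fire_energy <- function(events, t_P = 40e-9, N = 784, M = 1, R_MOS = 2.4e3) {
  if (is.null(events) || length(events$V) == 0) {
    out <- 0
    attr(out, "per_event") <- numeric(0)
    return(out)
  }
  per_event <- events$V^2 * t_P / (events$R_start + R_MOS)
  out <- sum(per_event) / (N * M)
  attr(out, "per_event") <- per_event
  out
}

#' Integrator capacitance from the charge-balance design rule
#'
#' `C ~ dQ / V_th`, with `dQ` the charge delivered in one integration
#' window by `n_active` potentiated synapses under the TE read bias. The
#' nominal sizing uses the synapse resistance alone; set
#' `include_R_MOS = TRUE` to add the transistor series resistance as in
#' the network engine. An optional read duty cycle (see
#' [duty_cycle_factor()]) scales the charge, and hence the capacitance,
#' down.
#'
#' @param n_active Number of active potentiated synapses (may be
#'   fractional, e.g. 10% of 784).
#' @param R_syn Potentiated synapse resistance, ohms.
#' @param V_TE TE read bias magnitude, volts.
#' @param duration Integration window, seconds.
#' @param V_th Comparator threshold, volts.
#' @param R_MOS Transistor series resistance, ohms.
#' @param include_R_MOS Include `R_MOS` in the current path?
#' @param duty_cycle Read duty-cycle factor in `(0, 1]`.
#' @return Capacitance in farads.
#' @export
capacitance_estimate <- function(n_active = 78.4, R_syn = 1.5e4,
                                 V_TE = 0.030, duration = 10e-3,
                                 V_th = 0.5, R_MOS = 2.4e3,
                                 include_R_MOS = FALSE, duty_cycle = 1) {
  stopifnot(V_th > 0, duty_cycle > 0, duty_cycle <= 1)
  R <- R_syn + if (include_R_MOS) R_MOS else 0
  dQ <- n_active * abs(V_TE) / R * duration * duty_cycle
  dQ / V_th
}

#' Pulsed-read configuration and duty-cycle factor
#'
#' Replacing the constant TE bias by short periodic read pulses of width
#' `t_spike` every `T_spike` cuts communication energy, power, and the
#' required integrator capacitance by the duty-cycle factor
#' `t_spike / T_spike`.
#'
#' @param t_spike Read pulse width, seconds.
#' @param T_spike Read pulse period, seconds.
#' @return An object of class `pulsed_read_config`.
#' @export
pulsed_read_config <- function(t_spike = 1e-6, T_spike = 1e-3) {
  stopifnot(t_spike > 0, t_spike <= T_spike)
  structure(list(t_spike = t_spike, T_spike = T_spike),
            class = "pulsed_read_config")
}

#' @rdname pulsed_read_config
#' @param cfg A `pulsed_read_config`.
#' @return `duty_cycle_factor`: the dimensionless ratio
#'   `t_spike / T_spike`.
#' @export
duty_cycle_factor <- function(cfg = pulsed_read_config()) {
  cfg$t_spike / cfg$T_spike
}

#' Recognition statistics from a simulation trace
#'
#' Splits the epochs of a trace into pattern and noise presentations and
#' counts output-neuron fires in each class: the recognition probability
#' `P_learn = n_p_f / n_p` (pattern epochs with an output fire) and the
#' error probability `P_err = n_n_f / n_n` (noise epochs with a spurious
#' fire). A class with no epochs yields an `NA` probability together with
#' a warning, never a silent zero.
#'
#' @param trace A trace data frame from [run_epochs()] (columns `kind` and
#'   `out_fired`).
#' @param pattern_label Optionally restrict the pattern count to epochs
#'   with this label.
#' @return An object of class `recognition_report`: counts `n`, `n_p`,
#'   `n_n`, `n_p_f`, `n_p_0`, `n_n_f`, `n_n_0` and probabilities
#'   `P_learn`, `P_err`.
#' @export
recognition_report <- function(trace, pattern_label = NULL) {
  stopifnot(nrow(trace) > 0)
  is_p <- trace$kind == "pattern"
  if (!is.null(pattern_label)) is_p <- is_p & trace$label == pattern_label
  is_n <- trace$kind == "noise"
  n_p <- sum(is_p); n_n <- sum(is_n)
  n_p_f <- sum(is_p & trace$out_fired)
  n_n_f <- sum(is_n & trace$out_fired)
  if (n_p == 0) warning("no pattern epochs: P_learn undefined")
  if (n_n == 0) warning("no noise epochs: P_err undefined")
  structure(list(n = n_p + n_n, n_p = n_p, n_n = n_n,
                 n_p_f = n_p_f, n_p_0 = n_p - n_p_f,
                 n_n_f = n_n_f, n_n_0 = n_n - n_n_f,
                 P_learn = if (n_p > 0) n_p_f / n_p else NA_real_,
                 P_err = if (n_n > 0) n_n_f / n_n else NA_real_),
            class = "recognition_report")
}

#' @export
print.recognition_report <- function(x, ...) {
  cat(sprintf("recognition report: n = %d (pattern %d, noise %d)\n",
              x$n, x$n_p, x$n_n))
  cat(sprintf("  P_learn = %.3f (%d/%d)   P_err = %.3f (%d/%d)\n",
              x$P_learn, x$n_p_f, x$n_p, x$P_err, x$n_n_f, x$n_n))
  invisible(x)
}

#' Group per-epoch communication energies into the three energy levels
#'
#' Bins epochs by two energy edges into the three characteristic groups
#' of the learned network: group I (pattern spikes through potentiated
#' synapses, highest), group II (noise spikes touching a few potentiated
#' synapses, intermediate), and group III (noise spikes over the
#' depressed background, lowest). Default edges separate the ~80 pJ,
#' ~5 pJ and <100 fJ levels.
#'
#' @param per_epoch_E Per-epoch `E_syn_c` values, joules.
#' @param edges Ascending pair of bin edges, joules.
#' @return Named integer vector of counts (`III`, `II`, `I`); counts sum
#'   to `length(per_epoch_E)`.
#' @export
energy_histogram <- function(per_epoch_E, edges = c(1e-13, 2e-11)) {
  stopifnot(length(edges) == 2, diff(edges) > 0, all(per_epoch_E >= 0))
  grp <- cut(per_epoch_E, breaks = c(-Inf, edges, Inf),
             labels = c("III", "II", "I"), right = FALSE)
  table(grp)
}

#' Areal power density of the synaptic array
#'
#' Per-synapse communication power `P_syn = E_syn_c / t_ck` multiplied by
#' an areal synapse density (the cortical figure of 1e11 synapses per
#' square centimeter by default).
#'
#' @param E_syn_c Per-synapse communication energy per clock, joules.
#' @param t_ck Clock period, seconds.
#' @param density Synapses per square centimeter.
#' @return Power density in watts per square centimeter.
#' @export
power_density <- function(E_syn_c, t_ck = 10e-3, density = 1e11) {
  E_syn_c / t_ck * density
}
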