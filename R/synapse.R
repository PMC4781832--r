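#' 1T1R synapse parameters
#'
#' The series transistor is modeled as a binary switch (driven by the
#' pre-synaptic gate voltage) plus a constant on-state series resistance;
#' the constant negative top-electrode (TE) read bias drives the
#' communication current without disturbing the PCM state.
#'
#' @param R_MOS On-state transistor series resistance, ohms.
#' @param V_TE_read Constant TE read bias, volts (small and negative so it
#'   never satisfies the device set/reset voltage gates).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(R_MOS = 2.4e3, V_TE_read = -0.030) {
  stopifnot(R_MOS > 0)
  structure(list(R_MOS = R_MOS, V_TE_read = V_TE_read),
            class = "synapse_params")
}

#' Construct a 1T1R synapse
#'
#' Composes a PCM device state with the series-transistor parameters into
#' a 3-terminal synapse. When the gate is on, the synapse conducts with
#' conductance `1 / (R_device + R_MOS)`; when off it is an open circuit.
#'
#' @param device A [pcm_state()] for the PCM cell.
#' @param params A [synapse_params()] object.
#' @param device_params A [device_params()] object.
#' @return An object of class `synapse_1t1r`.
#' @export
synapse_1t1r <- function(device = pcm_state(0),
                         params = synapse_params(),
                         device_params = pcmnet::device_params()) {
  structure(list(device = device, params = params,
                 device_params = device_params),
            class = "synapse_1t1r")
}

#' @export
print.synapse_1t1r <- function(x, ...) {
  cat(sprintf("1T1R synapse: R_PCM = %.4g ohm, R_MOS = %.4g ohm\n",
              pcm_resistance(x$device, x$device_params), x$params$R_MOS))
  invisible(x)
}

#' Read current through a gated synapse
#'
#' Ohmic communication current at the TE bias: `V_TE / (R_device + R_MOS)`
#' when the gate is on, zero otherwise. With the negative read bias a
#' negative current spike is produced for every pre-synaptic spike.
#' Reading never mutates the device state.
#'
#' @param syn A [synapse_1t1r()].
#' @param gate_on Logical; is the transistor gated on?
#' @param V_TE Top-electrode voltage, volts (defaults to the read bias).
#' @return Current in amperes.
#' @export
read_current <- function(syn, gate_on = TRUE, V_TE = syn$params$V_TE_read) {
  if (!gate_on) return(0)
  V_TE / (pcm_resistance(syn$device, syn$device_params) + syn$params$R_MOS)
}

#' Apply a TE write pulse to a gated synapse
#'
#' Routes a top-electrode pulse to the device operation selected by the
#' voltage gates: amplitudes in the set window crystallize
#' ([apply_set_pulse()]), amplitudes above the melting voltage amorphize
#' ([apply_reset_pulse()]), and anything below the set threshold (e.g. the
#' read bias) is a no-op. Writes are only meaningful while the gate is on
#' (PRE/POST overlap); the caller guarantees that.
#'
#' @param syn A [synapse_1t1r()].
#' @param V_TE Pulse amplitude at the top electrode, volts.
#' @param t_P Pulse width, seconds.
#' @return The updated synapse.
#' @export
write_pulse <- function(syn, V_TE, t_P) {
  dp <- syn$device_params
  if (V_TE > dp$V_m) {
    syn$device <- apply_reset_pulse(syn$device, V_TE, t_P, dp)
  } else if (V_TE >= dp$V_T) {
    syn$device <- apply_set_pulse(syn$device, V_TE, t_P, dp)
  }
  syn
}
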