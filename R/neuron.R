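#' Leaky integrate-and-fire neuron
#'
#' POST neuron model: an inverting integrator stage that accumulates the
#' (negative) synaptic current onto a capacitance, raising the internal
#' potential `V_int`, followed by a comparator with threshold `V_th`. The
#' default is a pure integrator (`tau_leak = Inf`); a finite leak time
#' constant applies exponential decay at the start of each integration
#' window.
#'
#' @param V_th Comparator threshold, volts.
#' @param C Integrating capacitance, farads. The default corresponds to
#'   the design rule `C ~ dQ / V_th` for a 784-input neuron with 10% of
#'   synapses potentiated at 15 kohm under a 30 mV read bias for one
#'   10 ms clock.
#' @param tau_leak Leak time constant, seconds (`Inf` = no leak).
#' @param V_int Initial internal potential, volts.
#' @return An object of class `lif_neuron`.
#' @export
lif_neuron <- function(V_th = 0.5, C = 3.1e-6, tau_leak = Inf, V_int = 0) {
  stopifnot(V_th > 0, C > 0, tau_leak > 0, V_int >= 0)
  structure(list(V_int = V_int, V_th = V_th, C = C, tau_leak = tau_leak),
            class = "lif_neuron")
}

#' @export
print.lif_neuron <- function(x, ...) {
  cat(sprintf("LIF neuron: V_int = %.4g V (V_th = %.3g V, C = %.3g F)\n",
              x$V_int, x$V_th, x$C))
  invisible(x)
}

#' Integrate synaptic current over one epoch
#'
#' Applies the leak first, then adds the charge contributed by the total
#' synaptic current: `V_int <- V_int * exp(-duration / tau_leak) +
#' |I| * duration / C`. The magnitude is used because the inverting
#' integrator turns the negative read current into a positive potential
#' increase.
#'
#' @param neuron A [lif_neuron()].
#' @param total_current Summed synaptic current, amperes.
#' @param duration Integration window, seconds (> 0).
#' @return The updated neuron.
#' @export
integrate_epoch <- function(neuron, total_current, duration) {
  stopifnot(inherits(neuron, "lif_neuron"), duration > 0)
  neuron$V_int <- neuron$V_int * exp(-duration / neuron$tau_leak) +
    abs(total_current) * duration / neuron$C
  neuron
}

#' Threshold check and fire
#'
#' Fires when `V_int` strictly exceeds `V_th`; firing discharges the
#' integrator to zero. On a fire the caller owes the synapse array a POST
#' spike (the set/reset waveform of the STDP protocol).
#'
#' @param neuron A [lif_neuron()].
#' @return A list with `fired` (logical) and `neuron` (updated).
#' @export
check_fire <- function(neuron) {
  fired <- neuron$V_int > neuron$V_th
  if (fired) neuron$V_int <- 0
  list(fired = fired, neuron = neuron)
}

#' Lateral inhibition configuration
#'
#' A successful fire in one neuron partially discharges the integrators
#' of its siblings; the fraction of capacitance discharged is fixed
#' (inhibitory synapses have constant weight, implementable as plain
#' resistors).
#'
#' @param discharge_fraction Fraction of the internal potential removed by
#'   one inhibitory event, in `[0, 1]`.
#' @return An object of class `inhibition_config`.
#' @export
inhibition_config <- function(discharge_fraction = 0.2) {
  stopifnot(discharge_fraction >= 0, discharge_fraction <= 1)
  structure(list(discharge_fraction = discharge_fraction),
            class = "inhibition_config")
}

#' Apply lateral inhibition to a neuron
#'
#' `V_int <- V_int * (1 - discharge_fraction)`.
#'
#' @param neuron A [lif_neuron()].
#' @param cfg An [inhibition_config()].
#' @return The updated neuron.
#' @export
inhibit <- function(neuron, cfg = inhibition_config()) {
  neuron$V_int <- neuron$V_int * (1 - cfg$discharge_fraction)
  neuron
}
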