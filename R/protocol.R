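#' STDP protocol parameters
#'
#' Rectangular-waveform STDP protocol. The PRE spike is a gate pulse of
#' width `pre_width` (followed by an equally long after-pulse at zero
#' volts). The POST spike spans `post_total = 2 * pre_width` and carries
#' two short sub-pulses of width `t_P` on the top electrode: a set pulse
#' of amplitude `V_set` at the POST start, and a reset pulse of amplitude
#' `V_reset` delayed by `post_reset_offset = pre_width`. Plasticity is
#' decided purely by which sub-pulse falls inside the PRE gate window.
#'
#' @param t_ck Clock/epoch duration, seconds.
#' @param V_G PRE gate amplitude, volts.
#' @param pre_width PRE gate pulse width, seconds.
#' @param V_set POST set sub-pulse amplitude, volts.
#' @param V_reset POST reset sub-pulse amplitude, volts.
#' @param t_P POST sub-pulse width, seconds.
#' @param post_reset_offset Delay of the reset sub-pulse from POST start,
#'   seconds.
#' @param post_total Total POST spike duration, seconds.
#' @return An object of class `protocol_params`.
#' @export
protocol_params <- function(t_ck = 10e-3,
                            V_G = 0.87,
                            pre_width = 10e-3,
                            V_set = 1.05,
                            V_reset = 1.75,
                            t_P = 40e-9,
                            post_reset_offset = pre_width,
                            post_total = 2 * pre_width) {
  stopifnot(t_P < pre_width, post_reset_offset == pre_width,
            post_total == 2 * pre_width)
  structure(list(t_ck = t_ck, V_G = V_G, pre_width = pre_width,
                 V_set = V_set, V_reset = V_reset, t_P = t_P,
                 post_reset_offset = post_reset_offset,
                 post_total = post_total),
            class = "protocol_params")
}

#' An STDP timing event
#'
#' Relative timing of one PRE/POST spike pair; `delta_t = t_post - t_pre`.
#'
#' @param t_pre PRE spike start time, seconds.
#' @param t_post POST spike start time, seconds.
#' @return An object of class `stdp_event` with fields `t_pre`, `t_post`,
#'   `delta_t`.
#' @export
stdp_event <- function(t_pre = 0, t_post = 0) {
  structure(list(t_pre = t_pre, t_post = t_post, delta_t = t_post - t_pre),
            class = "stdp_event")
}

#' Classify a PRE/POST delay into a plasticity outcome
#'
#' For `0 <= delta_t < pre_width` the set sub-pulse falls inside the PRE
#' gate window: potentiation. For `-pre_width < delta_t < 0` the reset
#' sub-pulse falls inside the gate window: depression. For delays of
#' magnitude `pre_width` or larger there is no overlap and no plasticity.
#' `delta_t = 0` potentiates (the set sub-pulse starts exactly at gate
#' onset and overlaps for its full width).
#'
#' @param delta_t Delay(s) `t_post - t_pre`, seconds. Vectorized.
#' @param params A [protocol_params()] object.
#' @return Character vector with values `"POTENTIATE"`, `"DEPRESS"`,
#'   `"NONE"`.
#' @export
classify_overlap <- function(delta_t, params = protocol_params()) {
  ifelse(delta_t >= 0 & delta_t < params$pre_width, "POTENTIATE",
  ifelse(delta_t < 0 & delta_t > -params$pre_width, "DEPRESS", "NONE"))
}

#' Apply one STDP event to a synapse
#'
#' Resolves the event timing with [classify_overlap()] and applies the
#' corresponding TE sub-pulse: the set pulse (`V_set`, width `t_P`) on
#' potentiation, the reset pulse (`V_reset`, width `t_P`) on depression,
#' nothing otherwise. Potentiation is gradual (cumulative crystallization)
#' while depression is abrupt (one-shot amorphization).
#'
#' @param syn A [synapse_1t1r()].
#' @param event An [stdp_event()].
#' @param params A [protocol_params()] object.
#' @return The updated synapse.
#' @export
apply_stdp <- function(syn, event, params = protocol_params()) {
  outcome <- classify_overlap(event$delta_t, params)
  switch(outcome,
         POTENTIATE = write_pulse(syn, params$V_set, params$t_P),
         DEPRESS    = write_pulse(syn, params$V_reset, params$t_P),
         NONE       = syn)
}

#' Brute-force waveform overlap oracle
#'
#' Independent reference for [classify_overlap()]: renders the PRE gate
#' window and the two POST sub-pulses on the time axis and samples each
#' sub-pulse at resolution `dt_resolution` (midpoint sampling) to find
#' which one, if any, coincides with gate-on time. Intended as a test
#' oracle; it agrees with the arithmetic classification except within one
#' sub-pulse width of the window boundaries, where the zero-measure
#' convention of [classify_overlap()] applies.
#'
#' @param event An [stdp_event()].
#' @param params A [protocol_params()] object.
#' @param dt_resolution Sampling step, seconds (at most `t_P`).
#' @return `"POTENTIATE"`, `"DEPRESS"`, or `"NONE"`.
#' @export
waveform_overlap_oracle <- function(event, params = protocol_params(),
                                    dt_resolution = 10e-9) {
  stopifnot(dt_resolution <= params$t_P)
  gate_on <- function(t) t >= event$t_pre & t < event$t_pre + params$pre_width
  sample_pulse <- function(start) {
    n <- ceiling(params$t_P / dt_resolution)
    start + (seq_len(n) - 0.5) * params$t_P / n
  }
  set_ts <- sample_pulse(event$t_post)
  reset_ts <- sample_pulse(event$t_post + params$post_reset_offset)
  if (any(gate_on(set_ts))) return("POTENTIATE")
  if (any(gate_on(reset_ts))) return("DEPRESS")
  "NONE"
}
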