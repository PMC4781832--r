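#' Device parameters for the PCM compact model
#'
#' Parameter set for a single phase-change-memory (PCM) cell. The cell is
#' described by a scalar internal state, the equivalent cumulative
#' crystallization time `t_eff`, and by a master curve mapping that state to
#' resistance (see [master_curve()]). Crystallization (set) is enabled for
#' top-electrode voltages in the window `[V_T, V_m)`; amorphization (reset)
#' occurs above the melting voltage `V_m` and follows the reset
#' characteristic up to the full-reset voltage `V_reset_full`.
#'
#' @param R_set_full Full-set (crystalline) resistance, ohms.
#' @param R_reset_full Full-reset (amorphous) resistance, ohms.
#' @param V_m Melting voltage above which amorphization occurs, volts.
#' @param V_T Effective set-enable threshold voltage, volts.
#' @param V_reset_full Voltage producing a full reset, volts.
#' @param t_inc Incubation (slow-nucleation) time of the set transition,
#'   seconds.
#' @param t_c Crystallization completion time, seconds.
#' @param R_inc Resistance reached at the end of the incubation segment,
#'   ohms. Together with the other anchors this fixes the two-segment
#'   log-linear master curve.
#' @return An object of class `device_params`.
#' @examples
#' p <- device_params()
#' master_curve(c(0, 140e-9, 250e-9), p)
#' @export
device_params <- function(R_set_full = 1.0e4,
                          R_reset_full = 2.0e7,
                          V_m = 1.2,
                          V_T = 0.9,
                          V_reset_full = 1.75,
                          t_inc = 80e-9,
                          t_c = 200e-9,
                          R_inc = 1.0e7) {
  stopifnot(R_set_full > 0, R_set_full < R_inc, R_inc <= R_reset_full,
            0 < V_T, V_T < V_m, V_m < V_reset_full,
            0 < t_inc, t_inc < t_c)
  structure(list(R_set_full = R_set_full, R_reset_full = R_reset_full,
                 V_m = V_m, V_T = V_T, V_reset_full = V_reset_full,
                 t_inc = t_inc, t_c = t_c, R_inc = R_inc),
            class = "device_params")
}

#' @export
print.device_params <- function(x, ...) {
  cat("PCM device parameters\n")
  cat(sprintf("  resistance window : %.3g - %.3g ohm\n",
              x$R_set_full, x$R_reset_full))
  cat(sprintf("  voltage gates     : V_T = %.3g V, V_m = %.3g V, V_reset_full = %.3g V\n",
              x$V_T, x$V_m, x$V_reset_full))
  cat(sprintf("  set dynamics      : t_inc = %.3g s, t_c = %.3g s\n",
              x$t_inc, x$t_c))
  invisible(x)
}

#' PCM cell state
#'
#' The internal state of one PCM cell: the equivalent cumulative
#' crystallization time `t_eff` in `[0, t_c]`. `t_eff = 0` is the
#' full-reset (amorphous) state, `t_eff = t_c` the full-set (crystalline)
#' state. Resistance is a pure function of `t_eff` through
#' [master_curve()], which makes set-pulse additivity exact.
#'
#' @param t_eff Equivalent cumulative crystallization time, seconds.
#' @param params A [device_params()] object.
#' @return An object of class `pcm_state`.
#' @export
pcm_state <- function(t_eff = 0, params = device_params()) {
  stopifnot(is.numeric(t_eff), length(t_eff) == 1L, t_eff >= 0)
  structure(list(t_eff = min(t_eff, params$t_c)), class = "pcm_state")
}

#' @export
print.pcm_state <- function(x, ...) {
  cat(sprintf("PCM state: t_eff = %.3g s (R = %.4g ohm)\n",
              x$t_eff, master_curve(x$t_eff)))
  invisible(x)
}

#' Set-transition master curve: resistance versus crystallization time
#'
#' Piecewise log-linear interpolant of the set characteristic. From the
#' full-reset resistance at `t_eff = 0` the curve falls slowly to `R_inc`
#' (10 Mohm by default) at the incubation time `t_inc` (nucleation), then
#' fast to the full-set resistance at the completion time `t_c` (growth),
#' and is constant beyond. Strictly decreasing on `(0, t_c)`, so it has a
#' well-defined inverse ([state_from_resistance()]).
#'
#' @param t_eff Equivalent crystallization time(s), seconds. Vectorized.
#' @param params A [device_params()] object.
#' @return Resistance(s) in ohms.
#' @export
master_curve <- function(t_eff, params = device_params()) {
  if (any(t_eff < 0)) stop("t_eff must be non-negative")
  lset <- log10(params$R_set_full)
  lrst <- log10(params$R_reset_full)
  linc <- log10(params$R_inc)
  lr <- ifelse(t_eff >= params$t_c, lset,
        ifelse(t_eff <= params$t_inc,
               lrst + (linc - lrst) * t_eff / params$t_inc,
               linc + (lset - linc) * (t_eff - params$t_inc) /
                 (params$t_c - params$t_inc)))
  R <- 10^lr
  # exact anchor values at the curve knots (no 10^log10 rounding)
  R[t_eff == 0] <- params$R_reset_full
  R[t_eff == params$t_inc] <- params$R_inc
  R[t_eff >= params$t_c] <- params$R_set_full
  R
}

#' Invert the master curve
#'
#' Returns the crystallization state whose resistance equals `R`. Unique by
#' strict monotonicity of [master_curve()] on `(0, t_c)`; used to place a
#' device in a prescribed initial state (e.g. the partially crystallized
#' states of an STDP characterization) and to map a reset pulse back onto
#' the master curve.
#'
#' @param R Resistance(s), ohms, within `[R_set_full, R_reset_full]`.
#' @param params A [device_params()] object.
#' @return `t_eff` value(s) in seconds (numeric; wrap with [pcm_state()] if
#'   a state object is needed).
#' @export
state_from_resistance <- function(R, params = device_params()) {
  # tolerate round-trip rounding at the window edges (one part in 1e9)
  tol <- 1e-9
  if (any(R < params$R_set_full * (1 - tol)) ||
      any(R > params$R_reset_full * (1 + tol)))
    stop("R outside the device resistance window")
  R <- pmin(pmax(R, params$R_set_full), params$R_reset_full)
  # snap to the window endpoints so the endpoint round-trips are exact
  R[R >= params$R_reset_full * (1 - 1e-12)] <- params$R_reset_full
  R[R <= params$R_set_full * (1 + 1e-12)] <- params$R_set_full
  lset <- log10(params$R_set_full)
  lrst <- log10(params$R_reset_full)
  linc <- log10(params$R_inc)
  lr <- log10(R)
  t_eff <- ifelse(lr >= linc,
                  params$t_inc * (lr - lrst) / (linc - lrst),
                  params$t_inc + (params$t_c - params$t_inc) *
                    (lr - linc) / (lset - linc))
  t_eff[R == params$R_reset_full] <- 0
  t_eff[R == params$R_set_full] <- params$t_c
  t_eff[R == params$R_inc] <- params$t_inc
  pmin(pmax(t_eff, 0), params$t_c)
}

#' Apply a set (crystallization) pulse
#'
#' A rectangular pulse of amplitude `V` and width `t_P` advances the
#' crystallization state by `t_P` when `V` lies in the set window
#' `[V_T, V_m)`; the state saturates at `t_c` (full set). Voltages outside
#' the window (the read bias, or melting amplitudes handled by
#' [apply_reset_pulse()]) leave the state unchanged. Crystallization is
#' cumulative: n pulses of width `t_P` are equivalent to one pulse of
#' width `n * t_P`.
#'
#' @param state A [pcm_state()].
#' @param V Pulse amplitude, volts.
#' @param t_P Pulse width, seconds (> 0).
#' @param params A [device_params()] object.
#' @return The updated `pcm_state`.
#' @export
apply_set_pulse <- function(state, V, t_P, params = device_params()) {
  stopifnot(inherits(state, "pcm_state"), t_P > 0)
  if (V >= params$V_T && V < params$V_m)
    state$t_eff <- min(state$t_eff + t_P, params$t_c)
  state
}

#' Apply a reset (amorphization) pulse
#'
#' Below the melting voltage `V_m` the state is unchanged. Above it, the
#' melt-quench erases the crystallization history: the new resistance is
#' given by the reset characteristic alone ([reset_characteristic()]),
#' independent of the prior state and of the pulse width (amorphization is
#' set by the quenching, not the duration).
#'
#' @inheritParams apply_set_pulse
#' @return The updated `pcm_state`.
#' @export
apply_reset_pulse <- function(state, V, t_P, params = device_params()) {
  stopifnot(inherits(state, "pcm_state"), t_P > 0)
  if (V > params$V_m) {
    R <- reset_characteristic(V, params)
    state$t_eff <- state_from_resistance(R, params)
  }
  state
}

#' Reset characteristic: resistance after a melt-quench pulse
#'
#' Log-linear monotone increase of the post-pulse resistance with the
#' write amplitude, from the full-set resistance at `V_m` to the
#' full-reset resistance at `V_reset_full`; clamped above. The amorphous
#' volume grows with the applied voltage, hence the resistance grows with
#' `V`. Only defined above `V_m` (callers gate on the melting voltage).
#'
#' @param V Write amplitude(s), volts, strictly above `V_m`.
#' @param params A [device_params()] object.
#' @return Resistance(s) in ohms.
#' @export
reset_characteristic <- function(V, params = device_params()) {
  if (any(V <= params$V_m)) stop("reset characteristic defined only above V_m")
  lset <- log10(params$R_set_full)
  lrst <- log10(params$R_reset_full)
  frac <- pmin((V - params$V_m) / (params$V_reset_full - params$V_m), 1)
  10^(lset + (lrst - lset) * frac)
}

#' Resistance of a PCM state
#'
#' Convenience accessor: `master_curve(state$t_eff)`.
#'
#' @param state A [pcm_state()].
#' @param params A [device_params()] object.
#' @return Resistance in ohms.
#' @export
pcm_resistance <- function(state, params = device_params()) {
  master_curve(state$t_eff, params)
}
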