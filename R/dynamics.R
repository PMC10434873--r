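#' Output-neuron parameters
#'
#' The postsynaptic neuron is a rectified-linear rate unit: its firing rate
#' relaxes with time constant `tau_y` toward
#' \deqn{\alpha\,[\,w_{ref} \sum_i w_i r_i + w_I r_I\,]_+ ,}
#' where the bracket is rectified at zero.  Excitatory synapses enter as
#' dimensionless weights \eqn{w_i} scaled by the reference weight
#' \eqn{w_{ref}}; inhibition is a single untuned source with fixed weight
#' \eqn{w_I \le 0} and rate \eqn{r_I}.
#'
#' @param tau_y Rate time constant, ms (default 1).
#' @param alpha Transfer-function slope, 1/nA (default 0.1).
#' @param w_ref Reference excitatory weight, nA (default 16).
#' @param w_inh Inhibitory weight, nA (default -1.7, i.e. -1700 pA).
#' @param r_inh Inhibitory rate, Hz (default 100).
#' @return An object of class `"output_neuron_params"`.
#' @export
output_neuron_params <- function(tau_y = 1, alpha = 0.1, w_ref = 16,
                                 w_inh = -1.7, r_inh = 100) {
  if (tau_y <= 0) stop("`tau_y` must be > 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (w_ref <= 0) stop("`w_ref` must be > 0", call. = FALSE)
  if (w_inh > 0) stop("`w_inh` must be <= 0 (inhibitory)", call. = FALSE)
  if (r_inh < 0) stop("`r_inh` must be >= 0", call. = FALSE)
  structure(
    list(tau_y = tau_y, alpha = alpha, w_ref = w_ref,
         w_inh = w_inh, r_inh = r_inh),
    class = "output_neuron_params"
  )
}

#' Rectified input drive to the output neuron
#'
#' The steady-state target of the output rate equation:
#' \eqn{\alpha\,\max(0,\; w_{ref}\sum_i w_i r_i + w_I r_I)}.  Under the
#' model's unit convention (weights dimensionless, `w_ref`/`w_inh` in nA,
#' rates in Hz, `alpha` in 1/nA) the result is in Hz.
#'
#' @param weights Per-synapse dimensionless weights.
#' @param rates Per-synapse presynaptic rates, Hz (same length as
#'   `weights`).
#' @param params An `"output_neuron_params"` object.
#' @return The drive in Hz (\eqn{\ge 0}).
#' @export
drive <- function(weights, rates, params = output_neuron_params()) {
  if (length(weights) != length(rates) || length(weights) < 1) {
    stop("`weights` and `rates` must have equal length >= 1", call. = FALSE)
  }
  params$alpha *
    max(0, params$w_ref * sum(weights * rates) + params$w_inh * params$r_inh)
}

#' One forward-Euler step of the output rate
#'
#' Relaxes the rate `y` toward `target` with time constant `tau_y`:
#' \eqn{y \leftarrow y + (dt/\tau_y)(-y + \mathrm{target})}, clamped at 0.
#'
#' @param y Current rate, Hz.
#' @param target Drive value (Hz), e.g. from [drive()].
#' @param dt Time step, ms (> 0).
#' @param params An `"output_neuron_params"`.
#' @return Updated rate, Hz (\eqn{\ge 0}).
#' @export
step_rate <- function(y, target, dt, params = output_neuron_params()) {
  stopifnot(dt > 0)
  max(0, y + dt / params$tau_y * (target - y))
}

#' Steady-state output rate
#'
#' The fixed point of the output rate equation equals the drive itself.
#' Because `tau_y` (1 ms) is much shorter than the stimulus duration
#' (200 ms), the output rate is effectively always at this fixed point; the
#' fast simulation mode uses it once per stimulus instead of integrating.
#'
#' @inheritParams drive
#' @return Rate in Hz.
#' @export
steady_state_rate <- function(weights, rates, params = output_neuron_params()) {
  drive(weights, rates, params)
}
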