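#' Activation-energy switch parameters and state
#'
#' Each of the write and read modules is gated by an activation-energy (AE)
#' switch: every CS spike increments the energy by 1, between spikes the
#' energy decays passively toward its baseline with time constant `tau`, and
#' when it reaches `ae_thresh` (outside the refractory period) the module
#' turns ON, the energy resets to baseline, and a refractory timer starts.
#'
#' @param tau decay time constant in ms.
#' @param ae0 baseline energy.
#' @param ae_thresh threshold energy (> `ae0`).
#' @param refractory refractory period in ms.
#' @return `switch_params()` returns a `switch_params` object;
#'   `switch_state()` the corresponding initial state.
#' @examples
#' sp <- switch_params(tau = 70)
#' st <- switch_state(sp)
#' step_switch(st, sp, cs_spike = 1, dt = 1)$activated
#' @export
switch_params <- function(tau, ae0 = 0, ae_thresh = 2, refractory = 1000) {
  stopifnot(tau > 0, ae_thresh > ae0, refractory > 0)
  structure(list(tau = tau, ae0 = ae0, ae_thresh = ae_thresh,
                 refractory = refractory),
            class = "switch_params")
}

#' @rdname switch_params
#' @param params a `switch_params` object.
#' @export
switch_state <- function(params) {
  structure(list(ae = params$ae0, on = FALSE, refractory_remaining = 0),
            class = "switch_state")
}

#' Advance a switch by one time step
#'
#' Update order within a step (fixed convention): exact exponential decay of
#' the energy toward baseline, then `+1` if a CS spike arrives on this step,
#' then the threshold test. With the published constants (threshold 2,
#' 100 Hz CS), the energy after the second spike is `exp(-10/70) + 1 = 1.867`
#' for the write switch (and 1.951 for the read switch), so both modules
#' activate on the *third* spike, 20 ms after CS onset.
#'
#' On activation the energy resets to baseline and the refractory timer is
#' set; while the timer is positive no activation can occur (the energy still
#' accumulates and decays).
#'
#' @param state a `switch_state`.
#' @param params a `switch_params`.
#' @param cs_spike 0/1, CS spike on this step.
#' @param dt step size in ms.
#' @return The updated state, with an extra logical field `activated`.
#' @export
step_switch <- function(state, params, cs_spike, dt) {
  stopifnot(dt > 0)
  ae <- params$ae0 + (state$ae - params$ae0) * exp(-dt / params$tau)
  refr <- max(0, state$refractory_remaining - dt)
  if (cs_spike > 0) ae <- ae + 1
  activated <- FALSE
  if (ae >= params$ae_thresh && refr == 0) {
    activated <- TRUE
    ae <- params$ae0
    refr <- params$refractory
    state$on <- TRUE
  }
  structure(list(ae = ae, on = state$on, refractory_remaining = refr,
                 activated = activated),
            class = "switch_state")
}

#' Advance a switch analytically through a stimulus-free interval
#'
#' Closed-form equivalent of `elapsed/dt` zero-input [step_switch()] calls:
#' the energy relaxes exponentially toward baseline, the refractory timer is
#' reduced (floored at zero), and the module returns to OFF.
#'
#' @inheritParams step_switch
#' @param elapsed stimulus-free time in ms.
#' @export
fast_forward_switch <- function(state, params, elapsed) {
  stopifnot(elapsed >= 0)
  structure(list(
    ae = params$ae0 + (state$ae - params$ae0) * exp(-elapsed / params$tau),
    on = FALSE,
    refractory_remaining = max(0, state$refractory_remaining - elapsed)
  ), class = "switch_state")
}

# event-driven activation time over a vector of CS spike times (ms), starting
# from a relaxed switch. Returns the first activation time, or NA. Equivalent
# to stepping the switch through the trial because the energy only ever
# crosses threshold on a spike step (decay is monotone toward baseline).
switch_activation_time <- function(spike_times, params) {
  ae <- params$ae0
  t_prev <- NA_real_
  for (t in spike_times) {
    if (!is.na(t_prev)) {
      ae <- params$ae0 + (ae - params$ae0) * exp(-(t - t_prev) / params$tau)
    }
    ae <- ae + 1
    t_prev <- t
    if (ae >= params$ae_thresh) return(t)
  }
  NA_real_
}
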