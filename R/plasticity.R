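#' Parameters of the sequentially neuromodulated plasticity rule
#'
#' The sn-Plast rule combines a symmetric STDP coincidence window
#' `W(dt) = exp(-|dt|/tau_stdp)` with neuromodulatory gating: while the agent
#' explores, tonic acetylcholine makes every coincidence an immediate
#' depression (`-eta_ach * W`); every coincidence is also written, with decay
#' `tau_e`, into a per-synapse eligibility trace that dopamine reads out once
#' at reward time as a retroactive potentiation (`+eta_da * eligibility`).
#' Weights are clipped to `[w_min, w_max]` after every update.
#'
#' @param eta_ach Acetylcholine (depression) learning rate, >= 0.
#' @param eta_da Dopamine (potentiation) learning rate, >= 0.
#' @param tau_stdp STDP window time constant, ms.
#' @param tau_e Eligibility-trace time constant, ms.
#' @param w_in Initial feedforward weight.
#' @param w_min,w_max Weight bounds.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(eta_ach = 0.000345, eta_da = 0.00115,
                              tau_stdp = 10, tau_e = 2000,
                              w_in = 2, w_min = 1, w_max = 3) {
  if (eta_ach < 0 || eta_da < 0) {
    abort("learning rates must be nonnegative",
          class = "snplastr_invalid_parameter")
  }
  stopifnot(tau_stdp > 0, tau_e > 0, w_min <= w_in, w_in <= w_max)
  structure(
    list(eta_ach = eta_ach, eta_da = eta_da, tau_stdp = tau_stdp,
         tau_e = tau_e, w_in = w_in, w_min = w_min, w_max = w_max),
    class = "plasticity_params"
  )
}

#' Symmetric STDP coincidence window
#'
#' `W(dt) = exp(-|dt|/tau)`: positive, equal to one at coincidence, and
#' symmetric in the sign of the pre/post lag.  The neuromodulator, not the
#' spike order, sets the sign of the weight change.
#'
#' @param delta_t Post-minus-pre spike lag, ms (vectorised).
#' @param tau Window time constant, ms.
#' @return Window values in (0, 1].
#' @export
stdp_window <- function(delta_t, tau = 10) {
  exp(-abs(delta_t) / tau)
}

#' Initial feedforward weight matrix
#'
#' All synapses start at `w_in`; masked boundary synapses are held at exactly
#' zero (an explicit exception to the `w_min` bound).
#'
#' @param n_place,n_actions Layer sizes.
#' @param mask Logical mask of excluded synapses (see [boundary_mask()]).
#' @param params A [plasticity_params()].
#' @return n_place x N weight matrix.
#' @export
init_weights <- function(n_place = 121, n_actions = 40,
                         mask = NULL, params = plasticity_params()) {
  w <- matrix(params$w_in, n_place, n_actions)
  if (!is.null(mask)) w[mask] <- 0
  w
}

#' Fresh plasticity state
#'
#' Pre/post exponential spike traces (time constant `tau_stdp`), the
#' eligibility matrix (time constant `tau_e`) and the dopamine-delivery flag.
#'
#' @param n_pre,n_post Layer sizes.
#' @return An object of class `plasticity_state`.
#' @export
new_plasticity_state <- function(n_pre = 121, n_post = 40) {
  structure(
    list(pre_trace = numeric(n_pre), post_trace = numeric(n_post),
         eligibility = matrix(0, n_pre, n_post), da_delivered = FALSE),
    class = "plasticity_state"
  )
}

#' One time step of the sn-Plast rule during exploration
#'
#' Implements the acetylcholine branch.  The coincidence mass assigned to
#' synapse (i, j) at this step is the all-pairs exponentially discounted
#' pairing: `pre_trace_i * post_spike_j + post_trace_j * pre_spike_i`, where
#' the pre trace already includes this step's pre spikes (so a simultaneous
#' pre/post pair is counted exactly once with window value 1) and the post
#' trace does not yet include this step's post spikes.  Summed over a trial
#' this equals the explicit double sum over spike pairs of
#' `W(t_post - t_pre)`.
#'
#' The mass depresses the weights immediately (`-eta_ach * mass`, clipped)
#' and is accumulated into the eligibility trace, which decays with `tau_e`
#' and is read out only by [deliver_dopamine()].  With `eta_ach = 0`
#' (cholinergic silencing) weights are untouched but eligibility still
#' accumulates.
#'
#' @param state A [new_plasticity_state()].
#' @param pre_spikes,post_spikes Logical spike vectors for this step.
#' @param weights Feedforward weight matrix, updated in the return value.
#' @param params A [plasticity_params()].
#' @param mask Optional logical mask of synapses excluded from plasticity.
#' @param dt Time step, ms.
#' @return List with updated `state`, `weights`, and the step's coincidence
#'   `mass` matrix.
#' @export
step_plasticity <- function(state, pre_spikes, post_spikes, weights,
                            params = plasticity_params(), mask = NULL,
                            dt = 1) {
  state$pre_trace <- state$pre_trace * exp(-dt / params$tau_stdp)
  state$post_trace <- state$post_trace * exp(-dt / params$tau_stdp)
  state$eligibility <- state$eligibility * exp(-dt / params$tau_e)

  state$pre_trace <- state$pre_trace + as.numeric(pre_spikes)
  mass <- outer(state$pre_trace, as.numeric(post_spikes)) +
    outer(as.numeric(pre_spikes), state$post_trace)
  state$post_trace <- state$post_trace + as.numeric(post_spikes)

  if (!is.null(mask)) mass[mask] <- 0
  state$eligibility <- state$eligibility + mass
  if (params$eta_ach > 0) {
    weights <- weights - params$eta_ach * mass
    weights <- pmin(pmax(weights, params$w_min), params$w_max)
    if (!is.null(mask)) weights[mask] <- 0
  }
  list(state = state, weights = weights, mass = mass)
}

#' Dopamine delivery at reward
#'
#' Called once, at the moment the reward is found: every synapse is
#' potentiated by `eta_da` times its eligibility (each past coincidence
#' discounted by `exp(-(t_reward - t_coincidence)/tau_e)`), weights are
#' clipped, and the eligibility trace is cleared.
#'
#' @inheritParams step_plasticity
#' @return List with updated `state` and `weights`.
#' @export
deliver_dopamine <- function(state, weights, params = plasticity_params(),
                             mask = NULL) {
  if (isTRUE(state$da_delivered)) {
    abort("dopamine already delivered this trial",
          class = "snplastr_protocol_error")
  }
  weights <- weights + params$eta_da * state$eligibility
  weights <- pmin(pmax(weights, params$w_min), params$w_max)
  if (!is.null(mask)) weights[mask] <- 0
  state$eligibility[] <- 0
  state$da_delivered <- TRUE
  list(state = state, weights = weights)
}
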