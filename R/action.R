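#' Parameters of the action-neuron ring
#'
#' Forty stochastic Spike Response Model neurons, each preferring one movement
#' direction, with fixed lateral connectivity that excites similarly tuned
#' neurons and inhibits dissimilar ones (soft winner-take-all).  Membrane
#' potentials are sums of EPSP kernels `eps(t) = eps0/(tau_m - tau_s) *
#' (exp(-t/tau_m) - exp(-t/tau_s))` over afferent spikes arriving after the
#' neuron's own last spike, plus a refractory kernel
#' `chi * exp(-(t - t_hat)/tau_m)`.  Spiking is an exponential escape process:
#' `lambda(u) = lambda0 * exp((u - theta)/delta_u)`.
#'
#' @param n_actions Number of action neurons N.
#' @param a0 Speed scale: each preferred direction has norm `a0` (a.u./step).
#' @param chi Refractory amplitude, mV (negative).
#' @param tau_m,tau_s Membrane and synaptic kernel time constants, ms.
#' @param eps0 EPSP kernel scale.
#' @param lambda0 Maximum (threshold) firing rate, Hz.
#' @param delta_u Escape-noise sharpness, mV.
#' @param theta Soft threshold, mV.
#' @param w_minus,w_plus Lateral inhibition / excitation scales.
#' @param psi_lat Von Mises concentration of the lateral similarity profile.
#' @param tau_gamma,nu_gamma Time constants of the rate-estimation kernel, ms.
#' @return An object of class `action_params`.
#' @export
action_params <- function(n_actions = 40, a0 = 0.08, chi = -5,
                          tau_m = 20, tau_s = 5, eps0 = 20,
                          lambda0 = 60, delta_u = 2, theta = 16,
                          w_minus = -300, w_plus = 100, psi_lat = 20,
                          tau_gamma = 50, nu_gamma = 20) {
  stopifnot(n_actions >= 2, n_actions %% 2 == 0, a0 > 0, tau_m > 0,
            tau_s > 0, tau_m != tau_s, lambda0 > 0, delta_u > 0, theta > 0,
            tau_gamma > 0, nu_gamma > 0, tau_gamma != nu_gamma)
  structure(
    list(n_actions = n_actions, a0 = a0, chi = chi, tau_m = tau_m,
         tau_s = tau_s, eps0 = eps0, lambda0 = lambda0, delta_u = delta_u,
         theta = theta, w_minus = w_minus, w_plus = w_plus,
         psi_lat = psi_lat, tau_gamma = tau_gamma, nu_gamma = nu_gamma),
    class = "action_params"
  )
}

#' Preferred movement directions of the action ring
#'
#' Neuron j (j = 1..N) encodes direction `a_j = a0 * (sin(theta_j),
#' cos(theta_j))` with `theta_j = 2 * j * pi / N`: equally spaced directions
#' of norm `a0` that sum to the zero vector.
#'
#' @param params An [action_params()].
#' @return N x 2 matrix of direction vectors.
#' @export
preferred_directions <- function(params = action_params()) {
  j <- seq_len(params$n_actions)
  th <- 2 * j * pi / params$n_actions
  params$a0 * cbind(sin(th), cos(th))
}

#' Fixed lateral weights of the action ring
#'
#' `w_lat[j, k] = w_minus / N + w_plus * f(j, k) / N`, where `f` is a
#' symmetric, positive similarity profile of the angular difference between
#' preferred directions, zero on the diagonal.  With `normalise = TRUE`
#' (default) the von Mises profile `exp(psi * cos(dtheta))` is row-normalised
#' to mean one (`f = N * exp(psi cos) / sum_k exp(psi cos)`), which keeps the
#' printed `w_minus`/`w_plus` scales commensurate with millivolt potentials;
#' `normalise = FALSE` uses the raw exponential profile.
#'
#' @param params An [action_params()].
#' @param normalise Row-normalise the similarity profile (default).
#' @return N x N symmetric matrix.
#' @export
build_lateral_weights <- function(params = action_params(), normalise = TRUE) {
  n <- params$n_actions
  th <- 2 * seq_len(n) * pi / n
  dth <- outer(th, th, "-")
  g <- exp(params$psi_lat * cos(dth))
  if (normalise) g <- n * g / sum(g[1, ])  # row sums equal by ring symmetry
  f <- g * (1 - diag(n))
  params$w_minus / n + params$w_plus * f / n
}

#' EPSP and rate-estimation kernels
#'
#' `epsp_kernel` is the double-exponential postsynaptic potential
#' `eps0/(tau_m - tau_s) * (exp(-t/tau_m) - exp(-t/tau_s))` for `t >= 0`,
#' zero for `t < 0`.  `rate_kernel` is the normalised filter
#' `(exp(-t/tau_gamma) - exp(-t/nu_gamma)) / (tau_gamma - nu_gamma)`, which
#' integrates to one so that filtering a spike train yields an instantaneous
#' rate in spikes per millisecond.
#'
#' @param t Time since the spike, ms (vectorised).
#' @param params An [action_params()].
#' @return Kernel values.
#' @export
epsp_kernel <- function(t, params = action_params()) {
  ifelse(t >= 0,
         params$eps0 / (params$tau_m - params$tau_s) *
           (exp(-t / params$tau_m) - exp(-t / params$tau_s)),
         0)
}

#' @rdname epsp_kernel
#' @export
rate_kernel <- function(t, params = action_params()) {
  ifelse(t >= 0,
         (exp(-t / params$tau_gamma) - exp(-t / params$nu_gamma)) /
           (params$tau_gamma - params$nu_gamma),
         0)
}

#' Escape rate of the stochastic spike response neuron
#'
#' @param u Membrane potential(s), mV.
#' @param params An [action_params()].
#' @return Instantaneous firing rate(s), Hz.
#' @export
escape_rate <- function(u, params = action_params()) {
  params$lambda0 * exp((u - params$theta) / params$delta_u)
}

#' Sample one time step of action-neuron spikes
#'
#' Each neuron spikes with probability `lambda(u) * dt`; probabilities above
#' one are clipped with a saturation warning.
#'
#' @param u Membrane potentials, mV.
#' @param params An [action_params()].
#' @param dt Time step, ms.
#' @return Logical vector of spike events.
#' @export
sample_action_spikes <- function(u, params = action_params(), dt = 1) {
  p <- escape_rate(u, params) * dt / 1000
  if (any(p > 1)) {
    warn("escape probability saturated (lambda * dt > 1); clipped to 1",
         class = "snplastr_rate_saturation")
    p <- pmin(p, 1)
  }
  runif(length(p)) < p
}

#' Membrane potentials reconstructed from spike rasters
#'
#' Online-accumulator reference implementation of the Spike Response Model
#' membrane: two exponential accumulators per neuron (time constants `tau_m`,
#' `tau_s`) hold the weighted afferent input; a neuron's own spike clears its
#' accumulators so that only arrivals strictly after its last spike
#' contribute, and starts the refractory kernel.
#'
#' Per step: accumulators decay; `u_before` is read (the potential the live
#' simulation samples spikes from); the step's own spikes reset the spiking
#' neurons and restart their refractory kernels; the step's afferent spikes
#' are then added (a same-step arrival contributes zero since the EPSP kernel
#' vanishes at lag 0, and is excluded entirely for a neuron that spiked this
#' step); `u_after` is read (equal to `chi` for a neuron at its own spike
#' time).
#'
#' @param place_raster T x n_place logical matrix of input spikes.
#' @param action_raster T x N logical matrix of the ring's own spikes.
#' @param w_ff n_place x N feedforward weight matrix.
#' @param w_lat N x N lateral weight matrix.
#' @param params An [action_params()].
#' @param dt Time step, ms.
#' @return List with T x N matrices `u_before` and `u_after`.
#' @export
membrane_from_rasters <- function(place_raster, action_raster, w_ff, w_lat,
                                  params = action_params(), dt = 1) {
  Tn <- nrow(place_raster)
  n <- ncol(action_raster)
  stopifnot(nrow(action_raster) == Tn, nrow(w_ff) == ncol(place_raster),
            ncol(w_ff) == n, nrow(w_lat) == n, ncol(w_lat) == n)
  dm <- exp(-dt / params$tau_m)
  ds <- exp(-dt / params$tau_s)
  c_eps <- params$eps0 / (params$tau_m - params$tau_s)
  am <- as_ <- numeric(n)
  last <- rep(-Inf, n)
  u_before <- u_after <- matrix(0, Tn, n)
  for (t in seq_len(Tn)) {
    am <- am * dm
    as_ <- as_ * ds
    refr <- ifelse(is.finite(last), params$chi * exp(-((t - 1) * dt - last) /
                                                       params$tau_m), 0)
    u_before[t, ] <- c_eps * (am - as_) + refr
    spk <- action_raster[t, ] != 0
    if (any(spk)) {
      am[spk] <- 0
      as_[spk] <- 0
      last[spk] <- (t - 1) * dt
    }
    pre <- place_raster[t, ] != 0
    if (any(pre)) {
      add <- colSums(w_ff[pre, , drop = FALSE])
      am[!spk] <- am[!spk] + add[!spk]
      as_[!spk] <- as_[!spk] + add[!spk]
    }
    if (any(spk)) {
      addl <- colSums(w_lat[spk, , drop = FALSE])
      am[!spk] <- am[!spk] + addl[!spk]
      as_[!spk] <- as_[!spk] + addl[!spk]
      refr <- ifelse(is.finite(last), params$chi * exp(-((t - 1) * dt - last) /
                                                         params$tau_m), 0)
    }
    u_after[t, ] <- c_eps * (am - as_) + refr
  }
  list(u_before = u_before, u_after = u_after)
}

#' Instantaneous firing-rate estimate from a spike raster
#'
#' Filters each neuron's spike train with the normalised double-exponential
#' kernel of [rate_kernel()], maintained online as a difference of two
#' exponential accumulators.  The kernel integrates to one, so values are
#' rates in spikes per millisecond.
#'
#' @param raster T x N logical spike matrix.
#' @param params An [action_params()].
#' @param dt Time step, ms.
#' @return T x N matrix of rate estimates (spikes/ms); the value at step t
#'   includes spikes up to and including t (a spike contributes zero at its
#'   own step since the kernel vanishes at lag 0).
#' @export
rates_from_raster <- function(raster, params = action_params(), dt = 1) {
  dg <- exp(-dt / params$tau_gamma)
  dn <- exp(-dt / params$nu_gamma)
  denom <- params$tau_gamma - params$nu_gamma
  rg <- rn <- numeric(ncol(raster))
  out <- matrix(0, nrow(raster), ncol(raster))
  for (t in seq_len(nrow(raster))) {
    rg <- rg * dg
    rn <- rn * dn
    s <- raster[t, ]
    rg <- rg + s
    rn <- rn + s
    out[t, ] <- (rg - rn) / denom
  }
  out
}
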