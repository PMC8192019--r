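# Independent brute-force oracles, kept deliberately naive: direct summation
# over full spike histories, explicit pair enumeration, and grid search.

# Membrane potential by direct summation over the spike history:
# u_j(t) = sum over arrivals s with t_hat_j < s <= t of w * eps(t - s)
#        + chi * exp(-(t - t_hat_j)/tau_m),
# evaluated after the step's own spikes (so u = chi at a neuron's spike time).
oracle_membrane <- function(place_raster, action_raster, w_ff, w_lat, params,
                            dt = 1) {
  Tn <- nrow(place_raster)
  n <- ncol(action_raster)
  eps <- function(t) epsp_kernel(t, params)
  u <- matrix(0, Tn, n)
  for (j in seq_len(n)) {
    own <- which(action_raster[, j] != 0)
    for (t in seq_len(Tn)) {
      t_hat <- if (any(own <= t)) max(own[own <= t]) else -Inf
      tot <- 0
      for (s in seq_len(t)) {
        if (s <= t_hat) next
        lag <- (t - s) * dt
        pre <- which(place_raster[s, ] != 0)
        if (length(pre) > 0) tot <- tot + sum(w_ff[pre, j]) * eps(lag)
        lat <- setdiff(which(action_raster[s, ] != 0), j)
        if (length(lat) > 0) tot <- tot + sum(w_lat[lat, j]) * eps(lag)
      }
      if (is.finite(t_hat)) {
        tot <- tot + params$chi * exp(-(t - t_hat) * dt / params$tau_m)
      }
      u[t, j] <- tot
    }
  }
  u
}

# Rate estimate by direct convolution with the normalised kernel.
oracle_rates <- function(raster, params, dt = 1) {
  Tn <- nrow(raster)
  out <- matrix(0, Tn, ncol(raster))
  for (j in seq_len(ncol(raster))) {
    spikes <- which(raster[, j] != 0)
    for (t in seq_len(Tn)) {
      lags <- (t - spikes[spikes <= t]) * dt
      out[t, j] <- sum(rate_kernel(lags, params))
    }
  }
  out
}

# Total STDP coincidence mass per synapse by explicit double sum over all
# pre/post spike pairs: sum_{t_pre} sum_{t_post} W(t_post - t_pre).
oracle_coincidence <- function(pre_raster, post_raster, tau, dt = 1) {
  mass <- matrix(0, ncol(pre_raster), ncol(post_raster))
  for (i in seq_len(ncol(pre_raster))) {
    t_pre <- which(pre_raster[, i] != 0) * dt
    if (length(t_pre) == 0) next
    for (j in seq_len(ncol(post_raster))) {
      t_post <- which(post_raster[, j] != 0) * dt
      if (length(t_post) == 0) next
      mass[i, j] <- sum(stdp_window(outer(t_post, t_pre, "-"), tau))
    }
  }
  mass
}

# Bernoulli logistic log-likelihood.
oracle_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# Two-parameter maximum likelihood by iterated grid refinement.
oracle_grid_logistic <- function(X, y, lower = c(-5, -5), upper = c(5, 5),
                                 rounds = 8, n_pts = 41) {
  lo <- lower
  hi <- upper
  best <- c(0, 0)
  for (r in seq_len(rounds)) {
    g1 <- seq(lo[1], hi[1], length.out = n_pts)
    g2 <- seq(lo[2], hi[2], length.out = n_pts)
    ll <- outer(g1, g2, Vectorize(function(a, b) oracle_loglik(c(a, b), X, y)))
    ix <- arrayInd(which.max(ll), dim(ll))
    best <- c(g1[ix[1]], g2[ix[2]])
    span <- c(g1[2] - g1[1], g2[2] - g2[1])
    lo <- best - 2 * span
    hi <- best + 2 * span
  }
  best
}

# Shared simulations for the acceptance tests: computed once per test run,
# reused across criteria.
.acc_cache <- new.env(parent = emptyenv())

acc_ratio_sweep <- function() {
  if (!is.null(.acc_cache$sweep)) return(.acc_cache$sweep)
  eta_da <- 0.00115
  ratios <- c(0, 0.1, 0.16, 0.2, 0.3)  # 0.16 and 0.3 give the two published
  n_seeds <- 20                        # acetylcholine levels at this eta_da
  rows <- list()
  for (r in ratios) {
    for (seed in seq_len(n_seeds)) {
      s <- run_session(eta_ach = r * eta_da, eta_da = eta_da,
                       seed = 7000 + seed)
      ini <- s$daily$pct_correct[s$daily$stage == "initial"]
      rev <- s$daily$pct_correct[s$daily$stage == "reversal"]
      rows[[length(rows) + 1]] <- tibble::tibble(
        ratio = r, seed = seed,
        d2c_initial = as.integer(days_to_criterion(ini)),
        d2c_reversal = as.integer(days_to_criterion(rev))
      )
    }
  }
  .acc_cache$sweep <- dplyr::bind_rows(rows)
  .acc_cache$sweep
}

acc_standard_session <- function() {
  if (is.null(.acc_cache$session)) {
    .acc_cache$session <- run_session(eta_ach = 0.000345, eta_da = 0.00115,
                                      seed = 42, daily_weights = TRUE)
  }
  .acc_cache$session
}
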