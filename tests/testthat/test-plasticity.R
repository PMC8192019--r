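test_that("STDP window is symmetric, positive, and unit at coincidence", {
  expect_equal(stdp_window(0), 1)
  expect_equal(stdp_window(10, tau = 10), exp(-1))
  expect_equal(stdp_window(-10, tau = 10), exp(-1))
  expect_equal(stdp_window(5), stdp_window(-5))
  dts <- seq(-50, 50, by = 0.5)
  expect_true(all(stdp_window(dts) > 0 & stdp_window(dts) <= 1))
})

test_that("trace-based coincidence mass equals the explicit double sum", {
  # 500 ms random rasters; total mass per synapse must match the brute-force
  # sum over all pre/post spike pairs of W(t_post - t_pre) to 1e-9 relative
  plast <- plasticity_params(0, 0)
  set.seed(23)
  Tn <- 500
  pre <- matrix(runif(Tn * 8) < 0.06, Tn, 8)
  post <- matrix(runif(Tn * 5) < 0.04, Tn, 5)
  st <- new_plasticity_state(8, 5)
  w <- matrix(2, 8, 5)
  total <- matrix(0, 8, 5)
  for (t in seq_len(Tn)) {
    sp <- step_plasticity(st, pre[t, ], post[t, ], w, plast)
    st <- sp$state
    total <- total + sp$mass
  }
  oracle <- oracle_coincidence(pre, post, plast$tau_stdp)
  expect_lt(max(abs(total - oracle)) / max(oracle), 1e-9)
})

test_that("a single pre/post pair depresses by the windowed learning rate", {
  plast <- plasticity_params(eta_ach = 1e-3, eta_da = 0)
  st <- new_plasticity_state(1, 1)
  w <- matrix(2, 1, 1)
  pre <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  post <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)  # post 5 ms after pre
  for (t in 1:6) {
    sp <- step_plasticity(st, pre[t], post[t], w, plast)
    st <- sp$state
    w <- sp$weights
  }
  expect_equal(w[1, 1], 2 - 1e-3 * exp(-0.5), tolerance = 1e-12)
})

test_that("cholinergic silencing freezes weights but not eligibility", {
  plast <- plasticity_params(eta_ach = 0, eta_da = 1e-3)
  st <- new_plasticity_state(3, 3)
  w <- matrix(2, 3, 3)
  set.seed(5)
  for (t in 1:100) {
    sp <- step_plasticity(st, runif(3) < 0.3, runif(3) < 0.3, w, plast)
    st <- sp$state
    w <- sp$weights
  }
  expect_true(all(w == 2))
  expect_gt(sum(st$eligibility), 0)
})

test_that("dopamine reads the eligibility trace with its exponential decay", {
  plast <- plasticity_params(eta_ach = 0, eta_da = 1e-3)
  # empty eligibility: no change
  st <- new_plasticity_state(2, 2)
  w0 <- matrix(2, 2, 2)
  expect_equal(deliver_dopamine(st, w0, plast)$weights, w0)
  # one unit coincidence exactly tau_e before the reward
  st <- new_plasticity_state(1, 1)
  w <- matrix(2, 1, 1)
  sp <- step_plasticity(st, TRUE, TRUE, w, plast)  # simultaneous pair, mass 1
  st <- sp$state
  expect_equal(sp$mass[1, 1], 1)
  for (t in seq_len(2000)) {  # tau_e = 2000 ms of decay
    sp <- step_plasticity(st, FALSE, FALSE, sp$weights, plast)
    st <- sp$state
  }
  out <- deliver_dopamine(st, sp$weights, plast)
  expect_equal(out$weights[1, 1], 2 + 1e-3 * exp(-1), tolerance = 1e-9)
  # calling dopamine twice in a trial is a protocol error
  expect_error(deliver_dopamine(out$state, out$weights, plast),
               class = "snplastr_protocol_error")
})

test_that("dopamine soon after a coincidence converts depression to potentiation", {
  plast <- plasticity_params(eta_ach = 1e-3, eta_da = 3e-3)
  st <- new_plasticity_state(1, 1)
  w <- matrix(2, 1, 1)
  sp <- step_plasticity(st, TRUE, TRUE, w, plast)
  st <- sp$state
  w <- sp$weights
  expect_equal(w[1, 1], 2 - 1e-3)  # immediate ACh depression
  for (t in 1:100) {
    sp <- step_plasticity(st, FALSE, FALSE, w, plast)
    st <- sp$state
    w <- sp$weights
  }
  w <- deliver_dopamine(st, w, plast)$weights
  # net change m * (eta_da * exp(-delta/tau_e) - eta_ach) > 0
  expect_gt(w[1, 1], 2)
  expect_equal(w[1, 1], 2 - 1e-3 + 3e-3 * exp(-100 / 2000), tolerance = 1e-9)
})

test_that("weights stay bounded and gated under random bombardment", {
  plast <- plasticity_params(eta_ach = 0.05, eta_da = 0.1)
  st <- new_plasticity_state(6, 6)
  w <- init_weights(6, 6, NULL, plast)
  set.seed(42)
  for (t in 1:300) {
    sp <- step_plasticity(st, runif(6) < 0.4, runif(6) < 0.4, w, plast)
    st <- sp$state
    w <- sp$weights
    # ACh-phase updates are depressions: never above the previous value
    expect_true(all(w >= plast$w_min - 1e-12))
  }
  expect_true(all(w >= 1 & w <= 3))
  w2 <- deliver_dopamine(st, w, plast)$weights
  expect_true(all(w2 >= w - 1e-12))  # dopamine only potentiates
  expect_true(all(w2 <= 3))
  # with both neuromodulators absent nothing changes
  off <- plasticity_params(0, 0)
  st0 <- new_plasticity_state(6, 6)
  w0 <- init_weights(6, 6, NULL, off)
  for (t in 1:100) {
    sp <- step_plasticity(st0, runif(6) < 0.5, runif(6) < 0.5, w0, off)
    st0 <- sp$state
    w0 <- sp$weights
  }
  expect_true(all(w0 == 2))
})

test_that("initial weights honour w_in and the mask", {
  plast <- plasticity_params()
  w <- init_weights(121, 40, NULL, plast)
  expect_true(all(w == 2))
  m <- matrix(TRUE, 4, 4)
  expect_true(all(init_weights(4, 4, m, plast) == 0))
  expect_error(plasticity_params(eta_ach = -1),
               class = "snplastr_invalid_parameter")
})
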