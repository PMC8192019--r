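test_that("degenerate trials terminate by the protocol rules", {
  net <- build_network()
  plast <- plasticity_params()
  proto <- protocol_spec()
  # fully disconnected network (feedforward masked and lateral ring silenced,
  # since escape noise can ignite a self-sustaining bump through the lateral
  # weights alone): the trial times out at exactly 15 s
  net0 <- net
  net0$w_lat[] <- 0
  w0 <- matrix(0, 121, 40)
  set.seed(1)
  tr <- run_trial(w0, plast, net0, baited = 1, start = "left", proto)
  expect_equal(tr$outcome, "timeout")
  expect_equal(tr$latency, 15)
  # starting on the baited well: reward at t = 0, trial ends at 300 ms
  w <- init_weights(121, 40, net$mask, plast)
  set.seed(1)
  tr2 <- run_trial(w, plast, net, baited = 1,
                   start = net$arena$well_centers[1, ], proto)
  expect_equal(tr2$outcome, "reward")
  expect_equal(tr2$latency, 0)
  expect_equal(tr2$duration, 0.3)
  # starting on the other well: wrong-well, immediate unrewarded end
  set.seed(1)
  tr3 <- run_trial(w, plast, net, baited = 1,
                   start = net$arena$well_centers[2, ], proto)
  expect_equal(tr3$outcome, "wrong_well")
  expect_equal(tr3$weights, w)
})

test_that("the compiled trial loop replays exactly through the R primitives", {
  # one recorded trial; rate estimates, trajectory, membrane potentials and
  # final weights are all reproduced from the rasters by the R reference
  # implementations of the individual operations
  net <- build_network()
  plast <- plasticity_params(0.002, 0.003)  # exaggerated rates hit the bounds
  w0 <- init_weights(121, 40, net$mask, plast)
  proto <- protocol_spec(t_max = 4)
  set.seed(21)
  tr <- run_trial(w0, plast, net, baited = 1, start = "right", proto,
                  record = TRUE)
  steps <- nrow(tr$rho)
  expect_gt(steps, 100)

  rho_r <- rates_from_raster(tr$action_raster, net$action)
  expect_lt(max(abs(rho_r - tr$rho)), 1e-12)

  x <- as.numeric(net$arena$start_positions["right", ])
  traj <- matrix(0, steps, 2)
  for (t in seq_len(steps)) {
    x <- update_position(x, select_action(pmax(tr$rho[t, ], 0),
                                          net$directions), net$arena)
    traj[t, ] <- x
  }
  expect_lt(max(abs(traj - tr$trajectory)), 1e-10)

  st <- new_plasticity_state(121, 40)
  w <- w0
  for (t in seq_len(steps)) {
    sp <- step_plasticity(st, tr$place_raster[t, ] > 0,
                          tr$action_raster[t, ] > 0, w, plast, net$mask)
    st <- sp$state
    w <- sp$weights
  }
  if (tr$outcome == "reward") {
    w <- deliver_dopamine(st, w, plast, net$mask)$weights
  }
  expect_lt(max(abs(w - tr$weights)), 1e-8)

  # membrane check on a plasticity-free trial (constant weights)
  off <- plasticity_params(0, 0)
  set.seed(5)
  tr0 <- run_trial(w0, off, net, baited = 1, start = "left",
                   protocol_spec(t_max = 3), record = TRUE)
  m0 <- membrane_from_rasters(tr0$place_raster, tr0$action_raster, w0,
                              net$w_lat, net$action)
  expect_lt(max(abs(m0$u_before - tr0$u)), 1e-8)
})

test_that("sessions have the protocol bookkeeping and are deterministic", {
  s <- run_session(eta_ach = 0, eta_da = 0, seed = 31, daily_weights = TRUE)
  expect_equal(nrow(s$trials), 200)
  expect_equal(nrow(s$daily), 20)
  expect_equal(sum(s$daily$stage == "initial"), 8)
  expect_equal(sum(s$daily$stage == "reversal"), 12)
  # daily success is exactly 100 * rewards / trials_per_day
  agg <- tapply(s$trials$outcome == "reward",
                paste(s$trials$stage, s$trials$day), mean) * 100
  expect_equal(sort(as.numeric(agg)), sort(s$daily$pct_correct))
  # 5 left / 5 right per day
  sides <- tapply(s$trials$start_side == "left",
                  paste(s$trials$stage, s$trials$day), sum)
  expect_true(all(sides == 5))
  # without plasticity the weights never move
  expect_true(all(s$final_weights[!s$network$mask] == 2))
  # weight persistence: the last daily snapshot is the final matrix
  expect_identical(s$weights_by_day[[20]], s$final_weights)
  # determinism under the master seed
  s2 <- run_session(eta_ach = 0, eta_da = 0, seed = 31)
  expect_identical(s$trials, s2$trials)
  expect_identical(s$final_weights, s2$final_weights)
})

test_that("tidiers summarise sessions", {
  s <- run_session(eta_ach = 0.000345, eta_da = 0.00115, seed = 8)
  expect_identical(tidy(s), s$trials)
  g <- glance(s)
  expect_equal(g$n_trials, 200)
  expect_equal(g$eta_da, 0.00115)
  expect_true(g$pct_initial >= 0 && g$pct_initial <= 100)
})

test_that("policy map is zero under uniform weights and tracks potentiation", {
  net <- build_network()
  d <- net$directions
  g <- net$grid
  w <- matrix(2, 121, 40)
  pm <- policy_map(w, g, d)
  expect_lt(max(abs(c(pm$vx, pm$vy))), 1e-15)
  # potentiating one synapse tilts that cell's vector along the action
  w[61, 5] <- 3
  pm2 <- policy_map(w, g, d)
  v <- c(pm2$vx[61], pm2$vy[61])
  expect_equal(v, d[5, ] / 40, tolerance = 1e-12)
  expect_gt(sum(v * d[5, ]), 0)
})
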