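#' Assemble the static network for the navigation task
#'
#' Bundles the arena, the place-cell lattice, the action ring's preferred
#' directions and lateral weights, and the boundary synapse mask.  These are
#' fixed for the whole experiment; only the feedforward weights change.
#'
#' @param arena An [arena_spec()].
#' @param grid A [place_cell_grid()].
#' @param action An [action_params()].
#' @param normalise_lateral Passed to [build_lateral_weights()].
#' @return An object of class `snplast_network`.
#' @export
build_network <- function(arena = default_arena(),
                          grid = place_cell_grid(),
                          action = action_params(),
                          normalise_lateral = TRUE) {
  directions <- preferred_directions(action)
  structure(
    list(arena = arena, grid = grid, action = action,
         directions = directions,
         w_lat = build_lateral_weights(action, normalise = normalise_lateral),
         mask = boundary_mask(grid, directions, arena)),
    class = "snplast_network"
  )
}

outcome_labels <- c("timeout", "reward", "wrong_well")

#' Simulate one trial
#'
#' Runs the millisecond loop: place-cell spikes, membrane update, action
#' spikes, rate estimation, population-vector action selection, position
#' update with wall reflection, sn-Plast step, and well check.  Finding the
#' baited well delivers dopamine and ends the trial after a 300 ms
#' consummatory pause with all place-cell activity silenced; touching the
#' wrong well ends the trial immediately with no dopamine; otherwise the
#' trial times out at `t_max`.
#'
#' @param weights Current feedforward weight matrix.
#' @param plast A [plasticity_params()].
#' @param network A [build_network()].
#' @param baited Index of the baited well (1 initial, 2 reversal).
#' @param start `"left"`, `"right"`, or a length-2 position.
#' @param protocol A [protocol_spec()].
#' @param record Keep spike rasters, trajectory and rate traces (memory-heavy;
#'   intended for figures and debugging).
#' @return List with `outcome` (`"reward"`, `"wrong_well"` or `"timeout"`),
#'   `latency` (s, time of well contact), `duration` (s, including the
#'   consummatory pause after reward), the updated `weights`, and the
#'   recorded traces when `record = TRUE`.
#' @export
run_trial <- function(weights, plast = plasticity_params(),
                      network = build_network(), baited = 1L,
                      start = "left", protocol = protocol_spec(),
                      record = FALSE) {
  if (is.character(start)) {
    start <- network$arena$start_positions[match(start, c("left", "right")), ]
  }
  stopifnot(length(start) == 2)
  neuron <- network$action[c("chi", "tau_m", "tau_s", "eps0",
                             "lambda0", "delta_u", "theta")]
  res <- run_trial_cpp(
    weights, network$mask, network$grid$centers, network$grid$sigma,
    network$grid$peak_rate, network$arena$radius, network$arena$well_centers,
    network$arena$well_radius, as.integer(baited), as.numeric(start),
    network$directions, network$w_lat, neuron,
    plast[c("eta_ach", "eta_da", "tau_stdp", "tau_e", "w_min", "w_max")],
    network$action$tau_gamma, network$action$nu_gamma,
    protocol$dt, protocol$t_max * 1000, record
  )
  out <- list(
    outcome = outcome_labels[res$outcome + 1L],
    latency = res$latency_ms / 1000,
    duration = res$latency_ms / 1000 +
      if (res$outcome == 1L) protocol$consummatory / 1000 else 0,
    weights = res$weights
  )
  if (record) {
    out$place_raster <- res$place_raster
    out$action_raster <- res$action_raster
    out$trajectory <- res$trajectory
    out$rho <- res$rho
    out$u <- res$u
  }
  out
}

#' Simulate a full two-stage session
#'
#' Runs the complete protocol: `days_initial` x `trials_per_day` trials with
#' well 1 baited, then `days_reversal` x `trials_per_day` trials with well 2
#' baited.  Feedforward weights persist across trials and across the stage
#' switch; all neural activity, spike traces and the eligibility trace are
#' reset between trials.  Start sides are balanced within each day (5 left /
#' 5 right, no more than 3 consecutive from one side).
#'
#' One master seed spawns an independent substream per trial, so any trial is
#' reproducible in isolation given the weights it started from.
#'
#' @param eta_ach,eta_da sn-Plast learning rates.
#' @param seed Master seed (optional; uses the current RNG state if `NULL`).
#' @param protocol A [protocol_spec()].
#' @param network A [build_network()].
#' @param plast Optional full [plasticity_params()]; overrides the two rates.
#' @param daily_weights Keep a copy of the weight matrix at the end of every
#'   day (for policy-map figures).
#' @return An object of class `snplast_session`: a list with `params`,
#'   `seed`, `trials` (tibble: stage, day, trial, start_side, outcome,
#'   latency), `daily` (tibble: stage, day, pct_correct, mean_latency),
#'   `final_weights`, and optionally `weights_by_day`.
#' @examples
#' \donttest{
#' s <- run_session(eta_ach = 0.000345, eta_da = 0.00115, seed = 1)
#' s$daily
#' }
#' @export
run_session <- function(eta_ach = 0.000345, eta_da = 0.00115, seed = NULL,
                        protocol = protocol_spec(),
                        network = build_network(),
                        plast = NULL, daily_weights = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(plast)) {
    plast <- plasticity_params(eta_ach = eta_ach, eta_da = eta_da)
  } else {
    eta_ach <- plast$eta_ach
    eta_da <- plast$eta_da
  }
  n_pc <- nrow(network$grid$centers)
  n_act <- network$action$n_actions
  weights <- init_weights(n_pc, n_act, network$mask, plast)

  stages <- c(rep("initial", protocol$days_initial),
              rep("reversal", protocol$days_reversal))
  day_in_stage <- c(seq_len(protocol$days_initial),
                    seq_len(protocol$days_reversal))
  n_days <- length(stages)
  n_trials <- n_days * protocol$trials_per_day
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)

  rows <- vector("list", n_trials)
  weights_by_day <- if (daily_weights) vector("list", n_days) else NULL
  k <- 0L
  for (d in seq_len(n_days)) {
    baited <- protocol$baited_well_by_stage[[stages[d]]]
    sides <- start_schedule(protocol)
    for (tr in seq_len(protocol$trials_per_day)) {
      k <- k + 1L
      set.seed(trial_seeds[k])
      res <- run_trial(weights, plast, network, baited, sides[tr], protocol)
      weights <- res$weights
      rows[[k]] <- tibble(
        stage = stages[d], day = day_in_stage[d], trial = tr,
        start_side = sides[tr], outcome = res$outcome, latency = res$latency
      )
    }
    if (daily_weights) weights_by_day[[d]] <- weights
  }
  trials <- dplyr::bind_rows(rows)
  daily <- trials |>
    dplyr::group_by(.data$stage, .data$day) |>
    dplyr::summarise(
      pct_correct = 100 * mean(.data$outcome == "reward"),
      mean_latency = mean(.data$latency), .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$stage, c("initial", "reversal")), .data$day)

  structure(
    list(params = c(eta_ach = eta_ach, eta_da = eta_da), seed = seed,
         trials = trials, daily = daily, final_weights = weights,
         weights_by_day = weights_by_day, network = network,
         protocol = protocol),
    class = "snplast_session"
  )
}

#' Daily success curve of a session as a plain vector
#'
#' @param session A [run_session()] result.
#' @return Numeric vector of per-day success percentages, initial stage first.
#' @export
session_curve <- function(session) {
  session$daily$pct_correct
}

#' Policy preference map
#'
#' The agent's policy at each place-field centre, read from the feedforward
#' weights: `v_i = (1/N) * sum_j w_ji * a_j`, the weight-averaged preferred
#' direction.  With uniform weights the ring symmetry makes every vector
#' exactly zero; learning tilts vectors toward the rewarded well.
#'
#' @param weights Feedforward weight matrix (n_place x N).
#' @param grid A [place_cell_grid()].
#' @param directions N x 2 matrix of preferred directions.
#' @return Tibble with columns `x`, `y`, `vx`, `vy`.
#' @export
policy_map <- function(weights, grid = place_cell_grid(),
                       directions = preferred_directions()) {
  v <- weights %*% directions / nrow(directions)
  tibble(x = grid$centers[, 1], y = grid$centers[, 2],
         vx = v[, 1], vy = v[, 2])
}

#' @export
print.snplast_session <- function(x, ...) {
  cat("<snplast_session>\n")
  cat(sprintf("  eta_ACh = %g, eta_DA = %g\n",
              x$params["eta_ach"], x$params["eta_da"]))
  cat(sprintf("  %d trials over %d days (initial %d d, reversal %d d)\n",
              nrow(x$trials), nrow(x$daily),
              x$protocol$days_initial, x$protocol$days_reversal))
  ini <- x$daily$pct_correct[x$daily$stage == "initial"]
  rev <- x$daily$pct_correct[x$daily$stage == "reversal"]
  cat(sprintf("  mean %% correct: initial %.1f, reversal %.1f\n",
              mean(ini), mean(rev)))
  invisible(x)
}

#' @rdname run_session
#' @param x A `snplast_session`.
#' @param ... Unused.
#' @export
tidy.snplast_session <- function(x, ...) {
  x$trials
}

#' @rdname run_session
#' @export
glance.snplast_session <- function(x, ...) {
  ini <- x$daily$pct_correct[x$daily$stage == "initial"]
  rev <- x$daily$pct_correct[x$daily$stage == "reversal"]
  tibble(
    eta_ach = unname(x$params["eta_ach"]),
    eta_da = unname(x$params["eta_da"]),
    n_trials = nrow(x$trials),
    pct_initial = mean(ini),
    pct_reversal = mean(rev),
    days_to_criterion_initial = days_to_criterion(ini),
    days_to_criterion_reversal = days_to_criterion(rev)
  )
}
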