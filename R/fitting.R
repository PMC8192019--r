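#' Parameter grid for model fitting
#'
#' The dopamine rate `eta_da` is varied over an ascending set of levels
#' (default 7.5e-4 to 2.75e-3 in steps of 2e-4, 11 levels) and at each level
#' the acetylcholine rate is set as a ratio `eta_ach / eta_da` in \[0, 1\]
#' (default steps of 0.02, 51 levels), giving 561 parameter combinations by
#' default.  `iterations` is the number of independent simulations per grid
#' point used for fitting.
#'
#' @param eta_da_levels Ascending dopamine learning-rate levels.
#' @param ratio_levels Ascending `eta_ach/eta_da` ratios in \[0, 1\].
#' @param iterations Simulations per grid point.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(eta_da_levels = seq(7.5e-4, 2.75e-3, by = 2e-4),
                      ratio_levels = seq(0, 1, by = 0.02),
                      iterations = 100) {
  stopifnot(all(diff(eta_da_levels) > 0), all(diff(ratio_levels) > 0),
            all(ratio_levels >= 0), all(ratio_levels <= 1), iterations >= 1)
  structure(
    list(eta_da_levels = eta_da_levels, ratio_levels = ratio_levels,
         iterations = iterations),
    class = "grid_spec"
  )
}

#' Reduced grid for desk-scale fitting and recovery runs
#'
#' Every fifth ratio level and every second dopamine level of the default
#' grid, with few iterations: the scale used by the package's own recovery
#' checks.  The full 561-point, 100-iteration grid is available through
#' [grid_spec()] defaults for long-running production fits.
#'
#' @param iterations Simulations per grid point.
#' @return A `grid_spec`.
#' @export
reduced_grid <- function(iterations = 3) {
  grid_spec(eta_da_levels = seq(7.5e-4, 2.75e-3, by = 4e-4),
            ratio_levels = seq(0, 1, by = 0.1),
            iterations = iterations)
}

#' Enumerate all grid points
#'
#' Deterministic dopamine-major ordering: for each `eta_da` level, all ratio
#' levels in ascending order, with `eta_ach = ratio * eta_da`.
#'
#' @param spec A [grid_spec()].
#' @return Tibble with `point_id`, `eta_da`, `ratio`, `eta_ach`.
#' @export
enumerate_grid <- function(spec = grid_spec()) {
  g <- expand.grid(ratio = spec$ratio_levels, eta_da = spec$eta_da_levels,
                   KEEP.OUT.ATTRS = FALSE)
  tibble(point_id = seq_len(nrow(g)), eta_da = g$eta_da, ratio = g$ratio,
         eta_ach = g$ratio * g$eta_da)
}

#' RMSE between two daily success curves
#'
#' Root mean squared difference of the per-day success percentages, in
#' percentage points.
#'
#' @param subject_curve,agent_curve Equal-length numeric vectors.
#' @return Nonnegative scalar.
#' @export
rmse_daily <- function(subject_curve, agent_curve) {
  if (length(subject_curve) != length(agent_curve)) {
    abort("curves must have equal length", class = "snplastr_shape_error")
  }
  sqrt(mean((subject_curve - agent_curve)^2))
}

#' Simulation bank over the parameter grid
#'
#' Runs `iterations` independent sessions at every grid point and stores the
#' daily success curves.  The bank is computed once and shared across all
#' subjects of a cohort: each fitting iteration compares a subject's curve
#' against the same simulated curves.
#'
#' @param spec A [grid_spec()].
#' @param seed Master seed; session seeds are derived per (point, iteration).
#' @param protocol,network Simulation configuration.
#' @param verbose Print a progress line per dopamine level.
#' @return An object of class `snplast_bank`: tibble with `point_id`,
#'   `eta_ach`, `eta_da`, `iteration`, `curve` (list of daily percentage
#'   vectors), carrying the grid as attribute `grid`.
#' @export
build_simulation_bank <- function(spec = reduced_grid(), seed = 1,
                                  protocol = protocol_spec(),
                                  network = build_network(),
                                  verbose = FALSE) {
  points <- enumerate_grid(spec)
  set.seed(seed)
  session_seeds <- matrix(
    sample.int(.Machine$integer.max, nrow(points) * spec$iterations),
    nrow = nrow(points)
  )
  rows <- vector("list", nrow(points) * spec$iterations)
  k <- 0L
  for (p in seq_len(nrow(points))) {
    for (it in seq_len(spec$iterations)) {
      s <- run_session(points$eta_ach[p], points$eta_da[p],
                       seed = session_seeds[p, it],
                       protocol = protocol, network = network)
      k <- k + 1L
      rows[[k]] <- tibble(
        point_id = points$point_id[p], eta_ach = points$eta_ach[p],
        eta_da = points$eta_da[p], iteration = it,
        curve = list(session_curve(s))
      )
    }
    if (verbose && points$ratio[p] == max(spec$ratio_levels)) {
      message(sprintf("bank: eta_da = %g done", points$eta_da[p]))
    }
  }
  bank <- dplyr::bind_rows(rows)
  attr(bank, "grid") <- spec
  class(bank) <- c("snplast_bank", class(bank))
  bank
}

#' Fit the model to one subject's learning curve
#'
#' For each iteration of the simulation bank, selects the grid point whose
#' simulated daily success curve minimises the RMSE against the subject's
#' curve (ties broken to the lowest `eta_ach`, then the lowest `eta_da`).
#' The per-iteration winners are averaged to give the subject's parameter
#' estimate, and their curves averaged to give the fitted curve.
#'
#' @param subject_curve Daily success percentages (initial stage then
#'   reversal; length must match the bank's curves).
#' @param bank A [build_simulation_bank()].
#' @param stage_days Optional integer vector of curve indices to fit on
#'   (e.g. `1:8` to fit the initial stage only).
#' @return An object of class `snplast_fit` with `estimate` (named vector),
#'   `per_iteration` (tibble of winners), `fitted_curve`, `subject_curve`.
#' @export
fit_subject <- function(subject_curve, bank, stage_days = NULL) {
  if (nrow(bank) == 0) {
    abort("empty simulation bank", class = "snplastr_configuration_error")
  }
  idx <- stage_days %||% seq_along(bank$curve[[1]])
  winners <- bank |>
    dplyr::group_by(.data$iteration) |>
    dplyr::group_modify(function(d, key) {
      err <- vapply(d$curve,
                    function(cv) rmse_daily(subject_curve[idx], cv[idx]),
                    numeric(1))
      best <- order(err, d$eta_ach, d$eta_da)[1]
      tibble(point_id = d$point_id[best], eta_ach = d$eta_ach[best],
             eta_da = d$eta_da[best], rmse = err[best],
             curve = d$curve[best])
    }) |>
    dplyr::ungroup()
  structure(
    list(
      estimate = c(eta_ach = mean(winners$eta_ach),
                   eta_da = mean(winners$eta_da)),
      per_iteration = winners,
      fitted_curve = colMeans(do.call(rbind, winners$curve)),
      subject_curve = subject_curve
    ),
    class = "snplast_fit"
  )
}

#' @export
print.snplast_fit <- function(x, ...) {
  cat("<snplast_fit>\n")
  cat(sprintf("  estimate: eta_ACh = %g, eta_DA = %g (%d iterations, mean RMSE %.2f)\n",
              x$estimate["eta_ach"], x$estimate["eta_da"],
              nrow(x$per_iteration), mean(x$per_iteration$rmse)))
  invisible(x)
}

#' @rdname fit_subject
#' @param x An `snplast_fit`.
#' @param ... Unused.
#' @export
tidy.snplast_fit <- function(x, ...) {
  x$per_iteration |> dplyr::select(-"curve")
}

#' @rdname fit_subject
#' @export
glance.snplast_fit <- function(x, ...) {
  tibble(eta_ach = unname(x$estimate["eta_ach"]),
         eta_da = unname(x$estimate["eta_da"]),
         mean_rmse = mean(x$per_iteration$rmse),
         iterations = nrow(x$per_iteration))
}

#' Rectangular region of parameter space
#'
#' Regions are axis-aligned rectangles in (`eta_da`, ratio) coordinates, used
#' to draw group-level parameter sets (e.g. a control region and a
#' reduced-acetylcholine region).  Degenerate (single-point) regions are
#' allowed.
#'
#' @param eta_da_range,ratio_range Length-2 numeric ranges (min, max).
#' @return An object of class `param_region`.
#' @export
param_region <- function(eta_da_range, ratio_range) {
  stopifnot(length(eta_da_range) == 2, length(ratio_range) == 2,
            diff(eta_da_range) >= 0, diff(ratio_range) >= 0)
  structure(list(eta_da_range = eta_da_range, ratio_range = ratio_range),
            class = "param_region")
}

#' Draw group parameter sets from a region of the grid
#'
#' Uniform draws from the region in (`eta_da`, ratio) space, snapped to the
#' nearest grid point.  Errors if the region does not intersect the grid's
#' bounding box.
#'
#' @param region A [param_region()].
#' @param n Number of draws.
#' @param spec The [grid_spec()] whose points the draws snap to.
#' @return Tibble with `eta_da`, `ratio`, `eta_ach`.
#' @export
sample_group_parameters <- function(region, n, spec = grid_spec()) {
  da_ok <- region$eta_da_range[1] <= max(spec$eta_da_levels) &&
    region$eta_da_range[2] >= min(spec$eta_da_levels)
  r_ok <- region$ratio_range[1] <= max(spec$ratio_levels) &&
    region$ratio_range[2] >= min(spec$ratio_levels)
  if (!da_ok || !r_ok) {
    abort("region does not intersect the parameter grid",
          class = "snplastr_configuration_error")
  }
  snap <- function(x, levels) levels[
    vapply(x, function(v) which.min(abs(levels - v)), integer(1))]
  da <- snap(runif(n, region$eta_da_range[1], region$eta_da_range[2]),
             spec$eta_da_levels)
  r <- snap(runif(n, region$ratio_range[1], region$ratio_range[2]),
            spec$ratio_levels)
  tibble(eta_da = da, ratio = r, eta_ach = r * da)
}
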