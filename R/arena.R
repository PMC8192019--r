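#' Arena geometry for the open-field navigation task
#'
#' The simulated environment is a circular open field containing two food
#' wells placed point-symmetrically in opposite inner quadrants, only one of
#' which is baited at any stage of the task.  The agent starts each trial on
#' the wall, to the left or right of the baited quadrants.
#'
#' The wall radius defaults to 2 a.u.: both start positions lie at norm
#' exactly 2 and all task geometry (wells, place-field lattice) fits inside.
#'
#' @param radius Arena (wall) radius in arbitrary units.
#' @param well_centers Two-row matrix of well centres; row 1 is the well
#'   baited during initial learning, row 2 the well baited during reversal.
#' @param well_radius Detection radius of each well.
#' @param start_positions Two-row matrix of start positions (left, right).
#'
#' @return An object of class `arena_spec`.
#' @examples
#' arena <- default_arena()
#' arena$well_centers
#' @export
arena_spec <- function(radius = 2,
                       well_centers = rbind(c(-0.43, 0.43), c(0.43, -0.43)),
                       well_radius = 0.3,
                       start_positions = rbind(left = c(-1.6, -1.2),
                                               right = c(1.6, 1.2))) {
  well_centers <- as.matrix(well_centers)
  start_positions <- as.matrix(start_positions)
  stopifnot(radius > 0, well_radius > 0,
            nrow(well_centers) == 2, ncol(well_centers) == 2,
            nrow(start_positions) == 2, ncol(start_positions) == 2)
  if (any(sqrt(rowSums(well_centers^2)) > radius) ||
      any(sqrt(rowSums(start_positions^2)) > radius + 1e-9)) {
    abort("well centres and start positions must lie within the arena",
          class = "snplastr_invalid_geometry")
  }
  if (max(abs(well_centers[1, ] + well_centers[2, ])) > 1e-9) {
    abort("well centres must be point-symmetric about the origin",
          class = "snplastr_invalid_geometry")
  }
  structure(
    list(radius = radius, well_centers = well_centers,
         well_radius = well_radius, start_positions = start_positions),
    class = "arena_spec"
  )
}

#' @rdname arena_spec
#' @export
default_arena <- function() arena_spec()

#' Two-stage trial protocol
#'
#' Defines the session structure: 8 days of initial place learning followed
#' by 12 days of reversal learning, 10 trials per day.  A trial lasts at most
#' `t_max` = 15 s; finding the reward appends a 300 ms consummatory pause
#' during which place-cell activity is silenced.  Neural dynamics are
#' integrated at `dt` = 1 ms.
#'
#' @param days_initial,days_reversal Days per stage.
#' @param trials_per_day Trials per day (must be even: balanced start sides).
#' @param t_max Maximum trial duration, seconds.
#' @param consummatory Consummatory pause after reward, milliseconds.
#' @param dt Integration time step, milliseconds.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(days_initial = 8, days_reversal = 12,
                          trials_per_day = 10, t_max = 15,
                          consummatory = 300, dt = 1) {
  stopifnot(days_initial >= 1, days_reversal >= 0, trials_per_day >= 1,
            t_max > 0, consummatory >= 0, dt > 0)
  if (trials_per_day %% 2 != 0) {
    abort("trials_per_day must be even (balanced left/right starts)",
          class = "snplastr_invalid_protocol")
  }
  structure(
    list(days_initial = days_initial, days_reversal = days_reversal,
         trials_per_day = trials_per_day, t_max = t_max,
         consummatory = consummatory, dt = dt,
         baited_well_by_stage = c(initial = 1L, reversal = 2L)),
    class = "protocol_spec"
  )
}

#' Random balanced start-side schedule for one day
#'
#' Each day has exactly half its trials starting from the left and half from
#' the right, in random order.  By default the order is constrained so that
#' no more than three consecutive trials start from the same side, mirroring
#' the pseudo-random mouse protocol; set `balance = FALSE` for a pure random
#' permutation.
#'
#' @param protocol A [protocol_spec()].
#' @param balance Enforce the maximum run length of 3.
#' @return Character vector of `"left"` / `"right"`, length `trials_per_day`.
#' @export
start_schedule <- function(protocol = protocol_spec(), balance = TRUE) {
  n <- protocol$trials_per_day
  if (n %% 2 != 0) {
    abort("trials_per_day must be even", class = "snplastr_invalid_protocol")
  }
  repeat {
    sides <- sample(rep(c("left", "right"), n / 2))
    if (!balance || max(rle(sides)$lengths) <= 3) return(sides)
  }
}

#' Classify the agent's position against the two wells
#'
#' Returns `"reward"` if the position is within the detection radius of the
#' baited well, `"wrong_well"` if within the other well (which terminates the
#' trial unrewarded), and `"none"` otherwise.  If both wells contained the
#' point, reward takes precedence.
#'
#' @param x Position, length-2 numeric.
#' @param arena An [arena_spec()].
#' @param baited Index (1 or 2) of the currently baited well.
#' @return One of `"none"`, `"reward"`, `"wrong_well"`.
#' @export
classify_position <- function(x, arena = default_arena(), baited = 1L) {
  stopifnot(length(x) == 2, baited %in% c(1L, 2L))
  d <- sqrt(rowSums((arena$well_centers - rep(x, each = 2))^2))
  if (d[baited] <= arena$well_radius) return("reward")
  if (d[3L - baited] <= arena$well_radius) return("wrong_well")
  "none"
}
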