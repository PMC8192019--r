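#' Population-vector action readout
#'
#' The movement taken at a time step is the average of the preferred
#' directions weighted by the estimated firing rates:
#' `a(t) = (1/N) * sum_j rho_j * a_j`, giving a continuous direction and
#' speed.
#'
#' @param rho Nonnegative rate estimates, spikes/ms (length N).
#' @param directions N x 2 matrix of preferred directions.
#' @return Length-2 displacement vector (a.u. per step).
#' @export
select_action <- function(rho, directions) {
  stopifnot(length(rho) == nrow(directions), all(rho >= 0))
  colSums(rho * directions) / nrow(directions)
}

#' Advance the agent's position with wall reflection
#'
#' The position moves by `a` unless that would exit the circular wall, in
#' which case the radial component of `a` is flipped:
#' `dx = a - 2 (a . x_hat) x_hat`.  Reflection preserves the step length; a
#' post-reflection position still outside the wall (floating-point overshoot,
#' or a tangential step taken exactly on the wall) is projected back onto the
#' boundary.
#'
#' @param x Current position (inside the arena).
#' @param a Displacement for this step.
#' @param arena An [arena_spec()].
#' @return New position, length-2 numeric with `norm <= radius`.
#' @export
update_position <- function(x, a, arena = default_arena()) {
  r <- arena$radius
  cand <- x + a
  if (sqrt(sum(cand^2)) <= r) return(cand)
  nx <- sqrt(sum(x^2))
  if (nx < .Machine$double.eps) {
    # unreachable with positive radius and sane step sizes; guard anyway
    new <- x - a
  } else {
    xh <- x / nx
    new <- x + a - 2 * sum(a * xh) * xh
  }
  nn <- sqrt(sum(new^2))
  if (nn > r) new <- new * (r / nn)
  new
}

#' Boundary mask on the feedforward synapses
#'
#' To avoid large boundary effects, synapses from place cells near the wall
#' onto action neurons whose preferred direction points out of the arena at
#' that cell are held at exactly zero and excluded from plasticity and from
#' the weight bounds.  A "boundary" cell has its centre within one lattice
#' spacing of the wall (`||x_i|| >= radius - sigma`); an outward direction
#' has positive radial component (`a_j . x_i > 0`, strict, so tangential
#' directions stay unmasked).
#'
#' @param grid A [place_cell_grid()].
#' @param directions N x 2 matrix of preferred directions.
#' @param arena An [arena_spec()].
#' @return n_place x N logical matrix; `TRUE` marks a masked synapse.
#' @export
boundary_mask <- function(grid = place_cell_grid(),
                          directions = preferred_directions(),
                          arena = default_arena()) {
  norms <- sqrt(rowSums(grid$centers^2))
  boundary <- norms >= arena$radius - grid$sigma
  outward <- grid$centers %*% t(directions) > 0
  boundary & outward
}
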