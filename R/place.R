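#' Place-cell population covering the arena
#'
#' 121 place cells on an 11 x 11 square lattice centred on the origin with
#' spacing `sigma` = 0.4 a.u. (spanning \[-2, 2\] on each axis).  Each cell
#' fires as an inhomogeneous Poisson process whose rate is a Gaussian
#' function of the agent's distance from the field centre, peaking at
#' 400 Hz when the agent sits exactly on the centre.
#'
#' @param spacing Lattice spacing and Gaussian width sigma (a.u.).
#' @param n_side Cells per lattice side (odd, so the origin is a centre).
#' @param peak_rate Peak firing rate, Hz.
#' @return An object of class `place_grid` with fields `centers`
#'   (n x 2 matrix), `sigma` and `peak_rate`.
#' @examples
#' grid <- place_cell_grid()
#' nrow(grid$centers)  # 121
#' @export
place_cell_grid <- function(spacing = 0.4, n_side = 11, peak_rate = 400) {
  stopifnot(spacing > 0, n_side >= 1, peak_rate > 0)
  half <- (n_side - 1) / 2
  ax <- seq(-half, half) * spacing
  centers <- as.matrix(expand.grid(x = ax, y = ax))
  dimnames(centers) <- NULL
  structure(
    list(centers = centers, sigma = spacing, peak_rate = peak_rate),
    class = "place_grid"
  )
}

#' Place-cell firing rates at a position
#'
#' Rate of cell i is `peak_rate * exp(-||x - x_i||^2 / sigma^2)`.
#'
#' @param x Position, length-2 numeric.
#' @param grid A [place_cell_grid()].
#' @return Numeric vector of rates in Hz, one per cell.
#' @export
place_rates <- function(x, grid = place_cell_grid()) {
  stopifnot(length(x) == 2)
  d2 <- (grid$centers[, 1] - x[1])^2 + (grid$centers[, 2] - x[2])^2
  grid$peak_rate * exp(-d2 / grid$sigma^2)
}

#' Sample one time step of place-cell spikes
#'
#' Bernoulli discretisation of the inhomogeneous Poisson process: each cell
#' spikes independently with probability `rate * dt`.  Requires
#' `max(rate) * dt <= 1` (0.4 at the 400 Hz peak with dt = 1 ms).
#'
#' @param rates Rates in Hz.
#' @param dt Time step in milliseconds.
#' @return Logical vector of spike events.
#' @export
sample_place_spikes <- function(rates, dt = 1) {
  p <- rates * dt / 1000
  if (any(p > 1)) {
    abort("rate * dt exceeds 1; decrease the time step",
          class = "snplastr_invalid_timestep")
  }
  runif(length(p)) < p
}
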