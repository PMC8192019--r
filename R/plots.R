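#' Learning-curve plot for one simulated session
#'
#' Daily percentage of rewarded trials across both stages, with the stage
#' switch marked.
#'
#' @param object A `snplast_session`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snplast_session <- function(object, ...) {
  d <- object$daily
  d$day_overall <- seq_len(nrow(d))
  switch_at <- sum(d$stage == "initial") + 0.5
  ggplot2::ggplot(d, ggplot2::aes(.data$day_overall, .data$pct_correct,
                                  colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = switch_at, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = 80, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "% correct trials", colour = "stage",
                  title = sprintf("eta_ACh = %g, eta_DA = %g",
                                  object$params["eta_ach"],
                                  object$params["eta_da"])) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Policy preference map plot
#'
#' Vector field of the agent's policy (weight-averaged preferred direction at
#' each place-field centre), with the wells marked; the baited well is
#' filled.
#'
#' @param weights Feedforward weight matrix, or a `snplast_session` (its
#'   final weights are used).
#' @param network A [build_network()].
#' @param baited Which well is currently baited (1 or 2).
#' @param arrow_scale Multiplier applied to the vectors for display.
#' @return A ggplot.
#' @export
plot_policy_map <- function(weights, network = build_network(), baited = 1L,
                            arrow_scale = 20) {
  if (inherits(weights, "snplast_session")) {
    network <- weights$network
    weights <- weights$final_weights
  }
  pm <- policy_map(weights, network$grid, network$directions)
  wells <- as.data.frame(network$arena$well_centers)
  names(wells) <- c("x", "y")
  wells$baited <- seq_len(2) == baited
  circ <- tibble(
    x = network$arena$radius * cos(seq(0, 2 * pi, length.out = 200)),
    y = network$arena$radius * sin(seq(0, 2 * pi, length.out = 200))
  )
  ggplot2::ggplot(pm, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = circ, colour = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + arrow_scale * .data$vx,
                   yend = .data$y + arrow_scale * .data$vy),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")),
      colour = "steelblue"
    ) +
    ggplot2::geom_point(data = wells,
                        ggplot2::aes(shape = .data$baited), size = 6,
                        colour = "black") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Model fit overlaid on a subject's learning curve
#'
#' @param object A `snplast_fit`.
#' @param days_initial Days in the initial stage (to mark the stage switch).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snplast_fit <- function(object, days_initial = 8, ...) {
  d <- tibble(
    day = seq_along(object$subject_curve),
    subject = object$subject_curve,
    fitted = object$fitted_curve
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$day)) +
    ggplot2::geom_vline(xintercept = days_initial + 0.5, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$subject)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "day", y = "% correct trials") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Group-mean learning curves from trial records
#'
#' @param records Trial records for a cohort (shared schema).
#' @return A ggplot of per-group mean daily success across both stages.
#' @export
plot_learning_curves <- function(records) {
  validate_trial_records(records)
  d <- records |>
    dplyr::group_by(.data$group, .data$stage, .data$day) |>
    dplyr::summarise(pct = 100 * mean(.data$outcome), .groups = "drop") |>
    dplyr::arrange(.data$stage, .data$day)
  days_initial <- max(d$day[d$stage == 0])
  d$day_overall <- d$day + ifelse(d$stage == 1, days_initial, 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$day_overall, .data$pct,
                                  colour = .data$group)) +
    ggplot2::geom_vline(xintercept = days_initial + 0.5, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "% correct trials") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
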