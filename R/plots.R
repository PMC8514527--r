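#' Observed vs. fitted mortality responses
#'
#' Scatter of fitted against observed percent mortality-rate changes with
#' the one-to-one line: points on the diagonal are perfectly reproduced
#' projections.
#'
#' @param object A `damage_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot damage_fit
#' @export
autoplot.damage_fit <- function(object, ...) {
  df <- tibble::tibble(observed = object$y, fitted = object$fitted)
  lab <- if (is.null(object$spec)) "damage model"
         else sprintf("%s model %d", object$spec$outcome, object$spec$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "observed change in mortality rate (%)",
      y = "fitted change in mortality rate (%)",
      title = sprintf("Observed vs. fitted (%s)", lab)
    )
}

#' Global mortality response vs. global-mean warming
#'
#' Heat (red), cold (blue) and net (black) components of the aggregated
#' mortality-rate change along the warming grid, with the net-effect
#' confidence band.
#'
#' @param object A `mortality_curve` from [warming_response_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mortality_curve
#' @export
autoplot.mortality_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("global_dT", "y_hot", "y_cold", "y_net")],
    cols = c("y_hot", "y_cold", "y_net"),
    names_to = "component", values_to = "value")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$global_dT)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(y = .data$value,
                                    colour = .data$component)) +
    ggplot2::scale_colour_manual(
      values = c(y_hot = "firebrick", y_cold = "steelblue", y_net = "black"),
      labels = c(y_hot = "heat", y_cold = "cold", y_net = "net")) +
    ggplot2::labs(
      x = "increase in global mean temperature (°C vs. 2001–2020)",
      y = "change in global mortality rate (%)",
      colour = NULL
    )
}

#' Global mortality-rate change by scenario
#'
#' Bar chart of the net global change per scenario and period with 95%
#' error bars, faceted by adaptation setting.
#'
#' @param object A `global_summary` from [global_rate_change()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot global_summary
#' @export
autoplot.global_summary <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    adaptation = ifelse(.data$adaptation, "with income-based adaptation",
                        "without adaptation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario,
                                   y = .data$y_net_global,
                                   fill = .data$period)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::facet_wrap(~adaptation) +
    ggplot2::labs(x = NULL, y = "change in global mortality rate (%)",
                  fill = "period")
}
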