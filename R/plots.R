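#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-couple safer-bet probabilities with group bands
#'
#' Scatter of the per-couple posterior means with +/- 1 posterior-sd error
#' bars, coloured by group, with horizontal bands at the aggregated
#' setting-level estimates (`p_s` +/- 1 `sd_s`), faceted by setting.
#'
#' @param object a `couple_estimates` tibble from [estimate_couples()].
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot couple_estimates
#' @export
autoplot.couple_estimates <- function(object, ...) {
  agg <- aggregate_settings(object)
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$couple_index, .data$mean, colour = .data$group)
  ) +
    ggplot2::geom_rect(
      data = agg,
      ggplot2::aes(
        xmin = -Inf, xmax = Inf,
        ymin = .data$p_s - .data$sd_s, ymax = .data$p_s + .data$sd_s,
        fill = .data$group
      ),
      alpha = 0.2, inherit.aes = FALSE
    ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$mean - .data$sd,
        ymax = .data$mean + .data$sd
      ),
      size = 0.3
    ) +
    ggplot2::facet_wrap(~setting, scales = "free_x") +
    ggplot2::labs(
      x = "bet couple", y = "probability of taking the safer bet",
      colour = "group", fill = "group"
    ) +
    ggplot2::ylim(0, 1)
}

#' Box plot of cumulative response times by group
#'
#' @param responses a response tibble.
#' @return A ggplot object.
#' @export
plot_response_times <- function(responses) {
  totals <- summarize_times(responses)$totals
  ggplot2::ggplot(totals, ggplot2::aes(.data$group, .data$total_s)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "cumulative response time (s)")
}
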