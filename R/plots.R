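#' Plot a projection ledger
#'
#' Alive population, cumulative deaths and prevalent complication pools over
#' the projection years.
#'
#' @param object An `scd_ledger` from [run_world()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scd_ledger <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(cumulative_deaths = cumsum(deaths)) %>%
    select(year, alive = alive_end, cumulative_deaths,
           ph_prevalent = "ph_prevalent", ckd_prevalent = "ckd_prevalent") %>%
    tidyr::pivot_longer(-year, names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(year, value, colour = metric)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = NULL, y = "persons",
      title = sprintf("Projection, world %s treatment", attr(object, "world")),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-world comparison
#'
#' Side-by-side headline metrics for the worlds with and without treatment
#' availability.
#'
#' @param object An `scd_comparison` from [compare_worlds()].
#' @param metrics Metrics to display (default: the count metrics).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scd_comparison <- function(object,
                                    metrics = c("deaths", "strokes",
                                                "ph_incident", "ckd_incident"),
                                    ...) {
  df <- object$comparison %>%
    filter(metric %in% metrics) %>%
    tidyr::pivot_longer(c("without", "with"),
                        names_to = "world", values_to = "value") %>%
    mutate(world = factor(world, levels = c("without", "with")))
  ggplot2::ggplot(df, ggplot2::aes(metric, value, fill = world)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "cumulative count", fill = "world") +
    ggplot2::theme_minimal()
}

#' Tornado plot
#'
#' Horizontal bars spanning the metric impact at the low and high bound of
#' each parameter, ranked by spread; the vertical line marks the base-case
#' impact.
#'
#' @param object An `scd_tornado` from [tornado()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scd_tornado <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(param_id = factor(param_id, levels = rev(param_id)))
  base <- df$impact_base[1]
  ggplot2::ggplot(df, ggplot2::aes(y = param_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = impact_low, xend = impact_high, yend = param_id),
      linewidth = 5, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(
      x = sprintf("%% impact on %s", attr(object, "metric")),
      y = NULL,
      title = "One-way deterministic sensitivity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the uptake schedule
#'
#' Treated share (relative to the pre-entrant population) and engine coverage
#' over the projection years.
#'
#' @param params An [scd_parameters] object.
#' @return A ggplot object.
#' @export
plot_uptake <- function(params = base_case()) {
  df <- build_schedule(params) %>%
    tidyr::pivot_longer(c("share", "coverage"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(year, value, linetype = metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "treated share", linetype = NULL,
                  title = "Treatment adoption and diffusion") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
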