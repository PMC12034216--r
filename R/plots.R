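#' Plot per-group SOC stocks by depth layer
#'
#' Point-and-interval plot of mean stocks with 95% CIs per rotation
#' group, faceted by depth layer.
#'
#' @param summaries Output of [group_summaries()].
#' @return A ggplot object.
#' @export
plot_group_summaries <- function(summaries) {
  ggplot2::ggplot(
    summaries,
    ggplot2::aes(x = .data$rotation_group, y = .data$mean)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$layer), scales = "free_y") +
    ggplot2::labs(
      x = "years of corn in the 3-year rotation",
      y = "SOC stock (Mg C/ha)",
      title = "SOC stocks by rotation group and depth layer (95% CI)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot rotation-pattern area proportions per region
#'
#' @param proportions Output of [rotation_proportions()].
#' @param denominator `"all"` (share of all sampled land) or
#'   `"corn_soy"` (share of corn-soy land only).
#' @return A ggplot object.
#' @export
plot_rotation_proportions <- function(proportions,
                                      denominator = c("all", "corn_soy")) {
  denominator <- match.arg(denominator)
  df <- proportions
  if (denominator == "corn_soy") {
    df <- df[df$pattern != "other", ]
    df$proportion <- df$proportion_corn_soy
  }
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$pattern, y = .data$proportion)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$region)) +
    ggplot2::labs(
      x = "rotation pattern (years of corn in 3)",
      y = paste0(
        "share of ",
        if (denominator == "all") "sampled land" else "corn-soy land"
      ),
      title = "Rotation-pattern area shares by region"
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean corn/soybean planting frequency per region
#'
#' @param frequency Output of [planting_frequency()].
#' @return A ggplot object.
#' @export
plot_planting_frequency <- function(frequency) {
  ggplot2::ggplot(
    frequency,
    ggplot2::aes(x = .data$region, y = .data$mean_years, fill = .data$crop)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "mean years planted",
      title = "Average corn and soybean planting frequency"
    ) +
    ggplot2::theme_minimal()
}

#' Plot scenario SOC gains
#'
#' Bar chart of per-state SOC gains (million Mg C) for each conversion
#' scenario.
#'
#' @param results Output of [run_scenarios()].
#' @return A ggplot object.
#' @export
plot_scenarios <- function(results) {
  df <- results[!results$is_total, ]
  df$scenario <- paste(df$from_group, "→", df$to_group)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$scenario, y = .data$delta_soc / 1e6,
                 fill = .data$state)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "conversion", y = "SOC gain (million Mg C)",
      title = "Aggregate SOC gains by conversion scenario"
    ) +
    ggplot2::theme_minimal()
}
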