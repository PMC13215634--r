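# Diagnostic figures: per-participant daily wear trajectories from both
# measurement methods, and per-participant equality-line scatter for the
# aggregated outcomes.

#' Per-participant wear-time trajectories
#'
#' Daily wear minutes across the intervention period, one facet per
#' participant, sensor and self-report overlaid. Missing self-report days
#' are simply absent.
#'
#' @param sensor_daily,selfreport_daily Calendar-complete daily series
#'   (`participant_id`, `date`, `minutes`).
#' @return A ggplot object.
#' @export
plot_wear_trajectories <- function(sensor_daily, selfreport_daily) {
  s <- sensor_daily
  s$method <- "sensor"
  r <- selfreport_daily[!is.na(selfreport_daily$minutes), ]
  r$method <- "self-report"
  df <- dplyr::bind_rows(s, r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$minutes,
                                   colour = .data$method)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = "day", y = "daily wear (min)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Equality-line scatter of sensor versus self-report
#'
#' One point per participant for an aggregated outcome (`avg_daily`,
#' `total`, or `days_worn`), with the line of equality marking perfect
#' agreement.
#'
#' @param sensor_daily,selfreport_daily Calendar-complete daily series.
#' @param level One of `"avg_daily"`, `"total"`, `"days_worn"`.
#' @return A ggplot object.
#' @export
plot_equality <- function(sensor_daily, selfreport_daily,
                          level = "avg_daily") {
  level <- match.arg(level, c("avg_daily", "total", "days_worn"))
  panel <- align_panel(sensor_daily, selfreport_daily, level)
  unit <- switch(level, avg_daily = "min/day", total = "min",
                 days_worn = "days")
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$sensor,
                                      y = .data$selfreport)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "darkgreen") +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("sensor (", unit, ")"),
                  y = paste0("self-report (", unit, ")"),
                  title = paste("Agreement:", level)) +
    ggplot2::theme_minimal()
}
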