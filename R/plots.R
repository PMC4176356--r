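# ggplot2 views of the result types.

#' Plot a fraction-on phase diagram
#'
#' Raster of the interpolated fraction-on surface over (dLk, epsilon)
#' with the isoprobability lines overlaid.
#'
#' @param object a `phase_diagram`
#' @param ... unused
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$dLk, y = .data$epsilon)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fraction_on)) +
    ggplot2::geom_path(data = object$isolines, colour = "white",
                       ggplot2::aes(group = .data$line_id)) +
    ggplot2::scale_fill_viridis_c(name = "fraction on") +
    ggplot2::labs(x = expression(Delta * Lk), y = expression(epsilon ~ (k[B] * T)))
}

#' Plot a telegraph signal
#' @param object a `telegraph_signal`
#' @param ... unused
#' @export
autoplot.telegraph_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = as.integer(.data$on))) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = c(0, 1), labels = c("off", "on")) +
    ggplot2::labs(x = "time (reduced units)", y = NULL,
                  title = attr(object, "pair"))
}

#' Plot trajectory observables against time
#' @param object a `bd_trajectory`
#' @param ... unused
#' @export
autoplot.bd_trajectory <- function(object, ...) {
  obs <- tidy(object)
  long <- tidyr::pivot_longer(obs, -"time", names_to = "observable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (reduced units)", y = NULL)
}

#' Dwell-time profiles against supercoiling
#'
#' Mean on/off dwell times (or any dwell statistics table with columns
#' `dLk`, `statistic`, `value` and optional CI columns) as profiles over
#' the linking-number deficit.
#'
#' @param tbl tidy dwell-statistics table
#' @export
plot_dwell_profile <- function(tbl) {
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = abs(.data$dLk), y = .data$value,
                                         colour = .data$statistic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression("|" * Delta * Lk * "|"),
                  y = "dwell time (reduced units)")
  if (all(c("ci_lo", "ci_hi") %in% names(tbl)))
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                                 ymax = .data$ci_hi),
                                    width = 0.2)
  p
}
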