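# ggplot2 views of traces, dwell-time fits and mode compositions.

#' Plot fluorescence traces with detected events
#'
#' @param traces Trace tibble.
#' @param events Optional event table; detected onsets are marked.
#' @param boutons Optional character vector restricting the boutons shown.
#' @return A ggplot object (one facet per bouton).
#' @export
plot_trace <- function(traces, events = NULL, boutons = NULL) {
  check_trace_df(traces)
  if (!is.null(boutons)) {
    traces <- filter(traces, .data$bouton_id %in% boutons)
    if (!is.null(events)) events <- filter(events, .data$bouton_id %in% boutons)
  }
  p <- ggplot2::ggplot(traces, ggplot2::aes(x = .data$time_s, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$bouton_id), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev <- filter(events, .data$detected)
    if (nrow(ev) > 0) {
      p <- p + ggplot2::geom_vline(
        data = ev,
        ggplot2::aes(xintercept = .data$onset_time_s),
        colour = "red", linetype = "dashed", linewidth = 0.3
      )
    }
  }
  p
}

#' @method autoplot dwell_fit
#' @export
autoplot.dwell_fit <- function(object, ...) {
  h <- object$histogram
  tt <- seq(min(h$mid_s), max(h$mid_s), length.out = 400)
  curve <- if (object$model == "single") {
    object$A1 * exp(-tt / object$tau1_s)
  } else {
    object$A1 * exp(-tt / object$tau1_s) + object$A2 * exp(-tt / object$tau2_s)
  }
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid_s, y = .data$density)) +
    ggplot2::geom_col(ggplot2::aes(width = .data$width_s),
                      fill = "grey70", colour = "grey40") +
    ggplot2::geom_line(
      data = tibble(mid_s = tt, density = curve),
      colour = "black", linewidth = 0.7
    ) +
    ggplot2::labs(
      x = "dwell time (s)", y = "probability density",
      title = sprintf("%s-exponential fit (R2 = %.3f)", object$model,
                      object$r_square)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot train_fit
#' @export
autoplot.train_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(tidyr::pivot_longer(g[, 1:3], dplyr::everything()),
                  ggplot2::aes(x = .data$name, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}

#' Mode-composition bar chart
#'
#' @param events Event table (or the tibble from [mode_proportions()]).
#' @return A ggplot object.
#' @export
plot_mode_proportions <- function(events) {
  tb <- if (all(c("mode", "percent") %in% names(events))) events else {
    mode_proportions(events)
  }
  tb$mode <- factor(tb$mode, levels = c("ultrafast", "fast", "ultraslow"))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$mode, y = .data$percent,
                                   fill = .data$mode)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(
      ultrafast = "#4daf4a", fast = "#377eb8", ultraslow = "#ffd92f"
    )) +
    ggplot2::labs(x = NULL, y = "% of events") +
    ggplot2::theme_minimal()
}
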