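#' Plot a preprocessed trial
#'
#' Velocity view of one trial: filtered velocity, moving-averaged velocity,
#' target-reversal time zero, and (when supplied) the detected onset and
#' reversal.
#'
#' @param trial Preprocessed single-trial tibble.
#' @param events Optional one-row event tibble with `onset_ms`,
#'   `reversal_ms`, `threshold`.
#' @return A ggplot object.
#' @export
plot_trial_velocity <- function(trial, events = NULL) {
  p <- ggplot2::ggplot(trial, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$vel_filt),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$vel_smooth),
                       colour = "firebrick", linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "time from target reversal (ms)",
                  y = "eye velocity (deg/s)")
  if (!is.null(events) && nrow(events) == 1) {
    if ("threshold" %in% names(events)) {
      p <- p + ggplot2::geom_hline(yintercept = events$threshold,
                                   linetype = 3, colour = "grey40")
    }
    p <- p +
      ggplot2::geom_vline(xintercept = c(events$onset_ms,
                                         events$reversal_ms),
                          colour = "steelblue", linetype = 4)
  }
  p
}

#' Plot per-velocity event summaries
#'
#' Mean of an event measure per observer and target velocity with the
#' grand mean overlaid, one panel layout per measure.
#'
#' @param events Trial-events tibble (included trials are used).
#' @param measure One of `"onset_ms"`, `"reversal_ms"`, `"mean_decel"`.
#' @return A ggplot object.
#' @export
plot_event_summary <- function(events,
                               measure = c("reversal_ms", "onset_ms",
                                           "mean_decel")) {
  measure <- match.arg(measure)
  d <- events |>
    filter(.data$included) |>
    group_by(.data$observer, .data$leftward_velocity) |>
    summarise(m = mean(.data[[measure]]), .groups = "drop")
  g <- d |>
    group_by(.data$leftward_velocity) |>
    summarise(m = mean(.data$m), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$leftward_velocity,
                                  y = .data$m)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$observer),
                       colour = "grey70") +
    ggplot2::geom_line(data = g, linewidth = 1) +
    ggplot2::geom_point(data = g, size = 2) +
    ggplot2::labs(x = "target velocity (deg/s)", y = measure)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pursuit_histogram <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$bin_left + object$binwidth / 2,
                               y = .data$count, colour = .data$group)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::labs(x = "normalized timing of eye reversal", y = "count",
                  colour = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pursuit_lme <- function(object, ...) {
  d <- filter(object$fixed, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 2 * .data$se,
                   xmax = .data$estimate + 2 * .data$se)) +
    ggplot2::labs(x = "estimate (ms per unit)", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pursuit_lme_grid <- function(object, ...) {
  d <- mutate(glance(object),
              family = dplyr::case_when(
                .data$kb == 0 ~ "stimulus only",
                .data$ks == 0 ~ "behavior only",
                TRUE ~ "both histories"
              ),
              lag = pmax(.data$ks, .data$kb))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$aic,
                                  colour = .data$family)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$selected), size = 2.5) +
    ggplot2::labs(x = "history depth (lags)", y = "AIC", colour = NULL,
                  shape = "selected")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
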