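#' Plot simulated or measured BRET kinetic traces
#'
#' One panel per condition, one line per well, stimulation time marked.
#'
#' @param traces A trace tibble.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces) {
  traces <- validate_traces(traces)
  ggplot2::ggplot(traces,
                  ggplot2::aes(x = .data$time_s, y = .data$ratio,
                               group = interaction(.data$experiment_id,
                                                   .data$well_id),
                               colour = .data$experiment_id)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$stim_time_s),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "Time (s)", y = "BRET ratio (530/470)",
                  colour = "Experiment") +
    ggplot2::theme_minimal()
}

#' Plot the normalized Renyi entropy spectrum by condition
#'
#' Mean normalized entropy (wells averaged within experiment, then across
#' experiments) against the order, with SEM ribbons; the infinite order is
#' drawn as a detached point beyond the finite grid.
#'
#' @param metrics Metric tibble from [analyze_traces()].
#' @param tau Coarse-graining scale to plot (default 1).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(metrics, tau = 1L) {
  dat <- metrics |>
    dplyr::filter(.data$tau == !!tau) |>
    dplyr::group_by(.data$experiment_id, .data$condition, .data$alpha) |>
    dplyr::summarise(H_norm = mean(.data$H_norm), .groups = "drop") |>
    dplyr::group_by(.data$condition, .data$alpha) |>
    dplyr::summarise(
      mean = mean(.data$H_norm),
      sem = if (dplyr::n() > 1) sd(.data$H_norm) / sqrt(dplyr::n())
            else 0,
      .groups = "drop")
  finite_max <- max(dat$alpha[is.finite(dat$alpha)])
  inf_pos <- finite_max + 2
  dat <- dplyr::mutate(
    dat, alpha_pos = ifelse(is.finite(.data$alpha), .data$alpha, inf_pos))
  breaks <- c(pretty(dat$alpha_pos[is.finite(dat$alpha)]), inf_pos)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$alpha_pos, y = .data$mean,
                                    colour = .data$condition,
                                    fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, is.finite(.data$alpha))) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, !is.finite(.data$alpha)),
                        shape = 18, size = 3) +
    ggplot2::scale_x_continuous(breaks = breaks,
                                labels = c(utils::head(breaks, -1), "Inf")) +
    ggplot2::labs(x = "Renyi order", y = "Normalized entropy (H / H0)",
                  colour = "Condition", fill = "Condition") +
    ggplot2::theme_minimal()
}

#' Bar plot of one metric by condition (mean +/- SEM)
#'
#' @param metrics Metric tibble from [analyze_traces()].
#' @param metric Metric name: `"sampen"`, `"H_norm"` or `"H_raw"`.
#' @param alpha Order for the Renyi metrics.
#' @param tau Coarse-graining scale (default 1).
#' @return A ggplot object.
#' @export
plot_metric_bars <- function(metrics, metric = "sampen", alpha = NA_real_,
                             tau = 1L) {
  s <- suppressWarnings(summarize_metrics(
    metrics, tibble(metric = metric, alpha = alpha), tau = tau))
  lab <- if (metric == "sampen") "Sample Entropy" else
    sprintf("%s (alpha = %s)", metric, format(alpha))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$mean,
                                  fill = .data$condition)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}
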