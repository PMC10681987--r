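#' Plot lateralization-index trajectories over exposure time
#'
#' Group-mean baseline-corrected LI per time bin and condition, with
#' individual sessions as points. Positive LI = right-biased, negative =
#' left-biased.
#'
#' @param li tibble from the lateralization stage (columns `bin_label`,
#'   `li_corrected`, `condition`).
#' @return a ggplot object.
#' @export
plot_li_timecourse <- function(li) {
  stopifnot(all(c("bin_label", "li_corrected", "condition") %in% names(li)))
  means <- li |>
    dplyr::group_by(.data$condition, .data$bin_label) |>
    dplyr::summarise(li = mean(.data$li_corrected), .groups = "drop")
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$bin_label, y = .data$li,
                               colour = .data$condition,
                               group = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(data = li,
                        ggplot2::aes(y = .data$li_corrected), alpha = 0.4,
                        position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point(size = 3, shape = 15) +
    ggplot2::labs(x = "Exposure time (3-day bins)",
                  y = "Baseline-corrected LI", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot adaptation of per-trial response magnitudes
#'
#' ARM against presentation index, one line per (channel, stimulus), with
#' the trials 6-25 regression window shaded.
#'
#' @param responses tibble from [compute_arm()].
#' @param trials regression window to highlight (default `6:25`).
#' @return a ggplot object.
#' @export
plot_adaptation <- function(responses, trials = 6:25) {
  ggplot2::ggplot(responses,
                  ggplot2::aes(x = .data$presentation, y = .data$arm,
                               group = interaction(.data$channel,
                                                   .data$stimulus))) +
    ggplot2::annotate("rect", xmin = min(trials), xmax = max(trials),
                      ymin = -Inf, ymax = Inf, alpha = 0.08,
                      fill = "steelblue") +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = mean,
                          geom = "line", colour = "firebrick",
                          linewidth = 1) +
    ggplot2::labs(x = "Presentation", y = "ARM (V)") +
    ggplot2::theme_minimal()
}

#' Plot Go/NoGo block performance
#'
#' Proportion correct per 50-trial block with the criterion threshold line.
#'
#' @param blocks tibble from [score_blocks()].
#' @param threshold criterion level to mark (default 0.8).
#' @return a ggplot object.
#' @export
plot_block_performance <- function(blocks, threshold = 0.8) {
  ggplot2::ggplot(dplyr::filter(blocks, .data$complete),
                  ggplot2::aes(x = .data$block, y = .data$p_correct,
                               colour = .data$subject)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "50-trial block", y = "Proportion correct",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.lat_pipeline <- function(object, ...) {
  if (is.null(object$li))
    stop("pipeline was run without the lateralization stage", call. = FALSE)
  plot_li_timecourse(object$li)
}

#' @export
ggplot2::autoplot
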