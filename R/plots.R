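#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter of Pareto records in TAR/TRR space
#'
#' One point per Pareto record, colored by channel count; the visual analog
#' of the optimization-front scatter used to judge how performance trades
#' off against montage size.
#'
#' @param object A `channel_selection_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.channel_selection_result <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$trr, y = .data$tar,
                               colour = factor(.data$n_channels))) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "True rejection rate", y = "True acceptance rate",
                  colour = "channels",
                  title = "Pareto records across optimization runs") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Channel occurrence map
#'
#' Tile map of how often each channel enters Pareto records, stratified by
#' record size.
#'
#' @param records Records tibble or `channel_selection_result`.
#' @return A ggplot.
#' @export
plot_channel_occurrence <- function(records) {
  occ <- channel_occurrence_map(records)
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$channel,
                                    y = factor(.data$n_channels),
                                    fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "channel", y = "channels in record", fill = "count",
                  title = "Channel occurrence across Pareto records") +
    ggplot2::theme_minimal()
}

#' Objective-space view of one evolution
#'
#' All evaluated candidates of a single NSGA-III run in (1-TAR, 1-TRR)
#' space, shaded by generation.
#'
#' @param object An `nsga3_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nsga3_result <- function(object, ...) {
  log <- object$log
  df <- tibble::tibble(
    generation = log$generation,
    f2 = vapply(log$objectives, `[`, numeric(1), 2L),
    f3 = vapply(log$objectives, `[`, numeric(1), 3L)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f3, y = .data$f2,
                                   colour = .data$generation)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "objective 3", y = "objective 2",
                  title = "Evaluated candidates by generation") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
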