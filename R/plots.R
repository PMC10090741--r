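#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-year multiverse envelopes
#'
#' One panel per country: the full min–max band across baseline windows
#' (salmon), the interquartile band (purple) and the median line —
#' the year-by-year picture of how sensitive relative excess is to the
#' baseline choice.
#'
#' @param object An `mv_envelope` from [yearly_envelope()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mv_envelope
#' @export
autoplot.mv_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "salmon", alpha = 0.6) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         fill = "mediumpurple", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~country) +
    ggplot2::labs(x = "Projected year",
                  y = "Relative excess deaths p% (of expected)")
}

#' Plot the distribution of p-scores per country
#'
#' Boxplot of per-window P-scores by country, countries ordered by
#' median excess.
#'
#' @param object An `mv_grid` from [run_multiverse()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mv_grid
#' @export
autoplot.mv_grid <- function(object, ...) {
  dat <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$country, .data$p_pct, FUN = median),
    y = .data$p_pct
  )) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative excess deaths p% (of expected)")
}

#' Heat map of country ranks across the baseline multiverse
#'
#' Countries (ordered from consistently-worst down) against rank, tile
#' shade giving how many baseline windows produced that rank. A dark
#' diagonal means the ranking is stable against the baseline choice.
#'
#' @param object An `mv_rank` from [rank_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mv_rank
#' @export
autoplot.mv_rank <- function(object, ...) {
  hist <- object$histogram |>
    dplyr::mutate(country = factor(.data$country,
                                   levels = rev(object$summary$country)))
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$rank, y = .data$country,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "windows") +
    ggplot2::labs(x = "Rank (1 = highest excess)", y = NULL)
}
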