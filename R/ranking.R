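#' Rank countries by relative excess within one baseline window
#'
#' Rank 1 goes to the country with the highest P-score (the worst excess
#' mortality). Ties are broken deterministically by country code and
#' flagged.
#'
#' @param estimates A data frame with one row per country: columns
#'   `country` and `p_pct`.
#' @return A tibble `country`, `p_pct`, `rank`, `tied`.
#' @examples
#' rank_countries(tibble::tibble(country = c("A", "B", "C"),
#'                               p_pct = c(5, 2, 8)))
#' @export
rank_countries <- function(estimates) {
  if (anyDuplicated(estimates$country)) {
    abort("duplicate country in one window's estimates")
  }
  estimates |>
    dplyr::mutate(
      tied = duplicated(.data$p_pct) | duplicated(.data$p_pct, fromLast = TRUE)
    ) |>
    dplyr::arrange(dplyr::desc(.data$p_pct), .data$country) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("country", "p_pct", "rank", "tied")
}

#' Distribution of country ranks across the baseline multiverse
#'
#' Ranks every country within every baseline window and aggregates: the
#' per-country average rank and rank standard deviation, and the
#' rank-occurrence histogram (how often each country landed at each
#' rank). Countries are ordered from consistently-worst (average rank
#' near 1) downwards, the order a rank-stability heat map uses.
#'
#' @param grid An `mv_grid` from [run_multiverse()] covering a complete
#'   country-by-window grid for one projected period.
#' @return An object of class `mv_rank`: a list with `summary` (tibble
#'   `country`, `avg_rank`, `rank_sd`, ordered), `histogram` (tibble
#'   `country`, `rank`, `n`), `ranks` (the full per-window assignment)
#'   and `n_windows`.
#' @export
rank_distribution <- function(grid) {
  countries <- sort(unique(grid$country))
  windows <- dplyr::distinct(grid, .data$window_start, .data$window_end)
  full <- tidyr::expand_grid(country = countries, windows)
  missing <- dplyr::anti_join(
    full, grid, by = c("country", "window_start", "window_end")
  )
  if (nrow(missing) > 0) {
    abort(paste0(
      "incomplete country x window grid; missing e.g. ",
      paste(head(paste0(missing$country, "@", missing$window_start, "-",
                        missing$window_end), 5), collapse = ", ")
    ))
  }
  ranks <- grid |>
    dplyr::group_by(.data$window_start, .data$window_end) |>
    dplyr::group_modify(~ rank_countries(.x)) |>
    dplyr::ungroup()
  summary <- ranks |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(avg_rank = mean(.data$rank),
                     rank_sd = stats::sd(.data$rank),
                     any_tie = any(.data$tied),
                     .groups = "drop") |>
    dplyr::arrange(.data$avg_rank, .data$country)
  histogram <- ranks |>
    dplyr::count(.data$country, .data$rank) |>
    dplyr::arrange(.data$country, .data$rank)
  structure(
    list(summary = summary, histogram = histogram, ranks = ranks,
         n_windows = nrow(windows)),
    class = "mv_rank"
  )
}

#' @export
print.mv_rank <- function(x, ...) {
  cat("Rank distribution over", x$n_windows, "baseline windows,",
      nrow(x$summary), "countries\n")
  print(x$summary, ...)
  invisible(x)
}
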