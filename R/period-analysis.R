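#' Worst k-year periods by multiverse-average excess
#'
#' Scores every consecutive k-year span of the candidate years by its
#' multiverse-average P-score and sorts from worst (highest excess)
#' down. By default the baselines for a scanned span exclude the span's
#' own years, the same rule that keeps pandemic years out of their own
#' baseline; `baseline_policy = "all_windows"` scores every span against
#' the full window set instead.
#'
#' @param demography Annual demography panel.
#' @param k Span length in years, 1–4.
#' @param candidate_years Years over which spans are scanned; default
#'   the full coverage of `demography`.
#' @param baseline_range Candidate baseline years, default `c(2009, 2019)`.
#' @param baseline_policy `"exclude_scanned"` (default) or `"all_windows"`.
#' @return A tibble `country`, `period_start`, `period_end`, `p_pct`,
#'   `worst_rank`, `tied`, sorted worst-first within country. Exact score
#'   ties fall back to chronological order and are flagged.
#' @export
worst_periods <- function(demography, k, candidate_years = NULL,
                          baseline_range = c(2009, 2019),
                          baseline_policy = c("exclude_scanned", "all_windows")) {
  baseline_policy <- match.arg(baseline_policy)
  check_demography(demography)
  if (!k %in% 1:4) abort("span length k must be 1, 2, 3 or 4")
  candidate_years <- candidate_years %||%
    seq.int(min(demography$year), max(demography$year))
  starts <- candidate_years[candidate_years + k - 1 <= max(candidate_years)]
  if (length(starts) == 0) abort("no candidate k-year span fits the years given")
  scores <- purrr::map(starts, function(a) {
    span <- seq.int(a, a + k - 1)
    windows <- enumerate_windows(
      baseline_range[1], baseline_range[2],
      exclude = if (baseline_policy == "exclude_scanned") span else NULL
    )
    run_multiverse(demography, c(a, a + k - 1), windows = windows,
                   allow_overlap = baseline_policy == "all_windows") |>
      summarize_multiverse() |>
      dplyr::transmute(.data$country, period_start = a, period_end = a + k - 1,
                       p_pct = .data$mean)
  }) |>
    purrr::list_rbind()
  # ties compared at 1e-9 (percent) so equal-by-construction spans sort
  # chronologically rather than by floating noise
  scores |>
    dplyr::group_by(.data$country) |>
    dplyr::mutate(
      p_key = round(.data$p_pct, 9),
      tied = duplicated(.data$p_key) | duplicated(.data$p_key, fromLast = TRUE)
    ) |>
    dplyr::arrange(dplyr::desc(.data$p_key), .data$period_start,
                   .by_group = TRUE) |>
    dplyr::mutate(worst_rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-"p_key")
}

#' Attenuation of pandemic excess under longer projected periods
#'
#' For each country: single-year P-scores for 2020 and 2021, multi-year
#' P-scores for 2020–2021, 2019–2021 and 2018–2021 (all multiverse
#' averages; baselines exclude any projected year), and the drops
#' `max(p2020, p2021) - p_kyr` for k = 2, 3, 4. Large drops indicate
#' mortality displacement: the pandemic peak dissolves once the period
#' absorbs the adjacent deficit years.
#'
#' @param demography Annual demography panel covering 2018–2021 and the
#'   baseline range.
#' @param baseline_range Candidate baseline years, default `c(2009, 2019)`.
#' @param pandemic_years The two single peak-candidate years, default
#'   `c(2020, 2021)`; the 2-, 3- and 4-year periods end at the later one.
#' @return A tibble per country: `p2020`, `p2021`, `p_2yr`, `p_3yr`,
#'   `p_4yr`, `drop_2`, `drop_3`, `drop_4` (percent / percentage points).
#' @export
attenuation_table <- function(demography, baseline_range = c(2009, 2019),
                              pandemic_years = c(2020, 2021)) {
  check_demography(demography)
  y2 <- max(pandemic_years)
  periods <- list(
    p2020 = c(pandemic_years[1], pandemic_years[1]),
    p2021 = c(y2, y2),
    p_2yr = c(y2 - 1, y2),
    p_3yr = c(y2 - 2, y2),
    p_4yr = c(y2 - 3, y2)
  )
  cols <- purrr::imap(periods, function(per, nm) {
    run_multiverse(demography, per, baseline_range = baseline_range) |>
      summarize_multiverse() |>
      dplyr::select("country", !!nm := "mean")
  })
  tab <- purrr::reduce(cols, dplyr::inner_join, by = "country")
  peak <- pmax(tab$p2020, tab$p2021)
  tab |>
    dplyr::mutate(
      drop_2 = peak - .data$p_2yr,
      drop_3 = peak - .data$p_3yr,
      drop_4 = peak - .data$p_4yr
    )
}

#' Cross-country mean and spread of projected-period excess
#'
#' Per period column of an attenuation table, the mean and sample
#' standard deviation over countries — the statistics showing that both
#' the level and the dispersion of excess shrink as the projected period
#' lengthens.
#'
#' @param table An attenuation table (or any per-country tibble).
#' @param columns Numeric columns to summarize.
#' @return A tibble `column`, `mean`, `sd`.
#' @export
cross_country_dispersion <- function(table,
                                     columns = c("p2020", "p2021", "p_2yr",
                                                 "p_3yr", "p_4yr")) {
  columns <- intersect(columns, names(table))
  if (nrow(table) < 2) abort("need at least two countries")
  purrr::map(columns, function(cl) {
    tibble::tibble(column = cl, mean = mean(table[[cl]]),
                   sd = stats::sd(table[[cl]]))
  }) |>
    purrr::list_rbind()
}

#' Aggregate several countries into one composite demography
#'
#' Band-wise sums of deaths and populations across countries with
#' identical year and band coverage; rates are recomputed from the sums.
#' Useful for composites such as an all-Europe pseudo-country whose
#' population rivals the largest member state.
#'
#' @param demography Annual demography panel holding the countries.
#' @param countries Countries to aggregate; default all present.
#' @param label Country code given to the composite.
#' @return An annual demography tibble for the single composite country.
#' @export
aggregate_countries <- function(demography, countries = NULL,
                                label = "COMPOSITE") {
  check_demography(demography)
  countries <- countries %||% unique(demography$country)
  demography <- dplyr::filter(demography, .data$country %in% countries)
  coverage <- demography |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(key = paste(sort(paste0(.data$year, ":", .data$band)),
                                 collapse = ";"), .groups = "drop")
  if (dplyr::n_distinct(coverage$key) != 1) {
    abort("countries differ in year/band coverage; cannot aggregate")
  }
  demography |>
    dplyr::group_by(.data$year, .data$band) |>
    dplyr::summarise(deaths = sum(.data$deaths),
                     population = sum(.data$population), .groups = "drop") |>
    dplyr::mutate(country = label, rate = .data$deaths / .data$population) |>
    dplyr::select("country", "year", "band", "deaths", "population", "rate") |>
    dplyr::arrange(.data$year, match(.data$band, band_labels()))
}
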