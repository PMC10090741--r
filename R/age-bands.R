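#' The five standard STMF age bands
#'
#' Weekly short-term mortality fluctuation files stratify deaths into five
#' age bands: 0-14, 15-64, 65-74, 75-84 and 85+. All analysis in mvexcess
#' runs on these bands; annual 1-year-age archive data is collapsed onto
#' them with [collapse_age_bands()].
#'
#' @return A tibble with columns `band` (label), `lower` and `upper`
#'   (inclusive age limits in years; `upper` is `Inf` for the open-ended
#'   85+ band). Bands are disjoint and exhaustive over ages 0 and above.
#' @examples
#' age_bands()
#' @export
age_bands <- function() {
  tibble::tibble(
    band  = c("0-14", "15-64", "65-74", "75-84", "85+"),
    lower = c(0L, 15L, 65L, 75L, 85L),
    upper = c(14, 64, 74, 84, Inf)
  )
}

band_labels <- function() age_bands()$band

#' Map single-year ages to the five standard age bands
#'
#' @param age Integer vector of ages in years (open-ended top ages such as
#'   110+ should already be coded as their lower limit, e.g. 110).
#' @return Character vector of band labels, same length as `age`.
#' @examples
#' band_of_age(c(0, 14, 15, 64, 65, 74, 75, 84, 85, 110))
#' @export
band_of_age <- function(age) {
  if (any(age < 0, na.rm = TRUE)) abort("ages must be non-negative")
  bands <- age_bands()
  idx <- findInterval(age, bands$lower)
  bands$band[idx]
}

#' Collapse a 1-year-age annual panel onto the five standard age bands
#'
#' Sums deaths and population of the constituent single-year ages of each
#' band and recomputes the band mortality rate as summed deaths over
#' summed population. The operation is linear: collapsing the sum of two
#' panels equals the sum of the collapsed panels.
#'
#' @param panel A data frame with columns `year`, `age`, `deaths`,
#'   `population`, and optionally `country`.
#' @return A tibble with one row per (country,) year and band: columns
#'   `year`, `band`, `deaths`, `population`, `rate`.
#' @examples
#' panel <- tidyr::expand_grid(year = 2015, age = 0:110)
#' panel$deaths <- 1; panel$population <- 100
#' collapse_age_bands(panel)
#' @export
collapse_age_bands <- function(panel) {
  need <- c("year", "age", "deaths", "population")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  keys <- intersect("country", names(panel))
  panel |>
    dplyr::mutate(band = band_of_age(.data$age)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year", "band")))) |>
    dplyr::summarise(
      deaths = sum(.data$deaths),
      population = sum(.data$population),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      band = factor(.data$band, levels = band_labels()),
      rate = .data$deaths / .data$population
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "year", "band")))) |>
    dplyr::mutate(band = as.character(.data$band))
}

# Validate an annual demography panel: country, year, band, deaths,
# population, rate. Used at the head of every analysis verb.
check_demography <- function(demography, require_population = TRUE,
                             arg = "demography") {
  need <- c("country", "year", "band", "deaths")
  if (require_population) need <- c(need, "population")
  missing_cols <- setdiff(need, names(demography))
  if (length(missing_cols) > 0) {
    abort(paste0(arg, " lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad_band <- setdiff(unique(demography$band), band_labels())
  if (length(bad_band) > 0) {
    abort(paste0("unknown age band(s): ", paste(bad_band, collapse = ", ")))
  }
  if (require_population && any(demography$population <= 0)) {
    abort("population must be positive for every populated cell")
  }
  if (any(demography$deaths < 0)) abort("deaths must be non-negative")
  invisible(demography)
}

# Years covered by every band of a country; errors if a requested year is
# absent. Returns demography restricted to `years`.
demography_years <- function(demography, years, what = "demography") {
  have <- demography |>
    dplyr::distinct(.data$country, .data$year)
  missing <- have |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(miss = list(setdiff(years, .data$year)), .groups = "drop") |>
    tidyr::unnest("miss")
  if (nrow(missing) > 0) {
    abort(paste0(
      what, " lacks year(s) ",
      paste(unique(missing$miss), collapse = ", "),
      " for country ", paste(unique(missing$country), collapse = ", ")
    ))
  }
  dplyr::filter(demography, .data$year %in% years)
}
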