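#' Specify a synthetic national demography scenario
#'
#' Defines a country-scale annual demography with five age bands, a
#' declining mortality trend, optional log-rate noise, and optional
#' pandemic-year shocks. Defaults sketch a mid-size high-income country
#' of about 10 million people over 2009–2021: band mortality declining
#' 1.5% per year, mild population ageing, 2% log-rate noise, and
#' multiplicative pandemic shocks of +10% in 2020 and +5% in 2021.
#'
#' @param country Country code for the synthetic country.
#' @param years Calendar years covered (contiguous).
#' @param base_population Population per band in the first year
#'   (vector of 5, bands in [age_bands()] order).
#' @param pop_growth Annual multiplicative population growth per band;
#'   the default grows the older bands faster (ageing).
#' @param base_rate Band mortality rate (deaths per person-year) in the
#'   first year.
#' @param rate_decline Annual multiplicative rate trend per band, in
#'   (0, 1] for improving mortality; default 0.985 everywhere.
#' @param sigma Standard deviation of i.i.d. Gaussian noise on log
#'   rates; 0 disables noise.
#' @param shocks Named list mapping a year (as character) to a
#'   multiplicative rate factor, scalar or per-band vector of 5, e.g.
#'   `list("2020" = 1.12)`.
#' @param deterministic If `TRUE`, deaths are exactly `rate * population`
#'   (possibly fractional); otherwise Poisson counts with that mean.
#' @param seed Integer seed fixing the whole realization.
#' @return A `scenario_spec` object for [simulate_country()].
#' @export
scenario_spec <- function(country = "SYN",
                          years = 2009:2021,
                          base_population = c(1.6e6, 6.6e6, 1.0e6, 0.55e6, 0.2e6),
                          pop_growth = c(0.999, 1.000, 1.008, 1.010, 1.015),
                          base_rate = c(0.0003, 0.0030, 0.0180, 0.0500, 0.1500),
                          rate_decline = rep(0.985, 5),
                          sigma = 0.02,
                          shocks = list("2020" = 1.10, "2021" = 1.05),
                          deterministic = FALSE,
                          seed = 1L) {
  rep5 <- function(x) if (length(x) == 1) rep(x, 5) else x
  base_population <- rep5(base_population); pop_growth <- rep5(pop_growth)
  base_rate <- rep5(base_rate); rate_decline <- rep5(rate_decline)
  lens <- lengths(list(base_population, pop_growth, base_rate, rate_decline))
  if (any(lens != 5)) abort("band parameters must have length 1 or 5")
  if (any(base_population <= 0) || any(base_rate <= 0) ||
      any(pop_growth <= 0) || any(rate_decline <= 0) ||
      any(rate_decline > 1)) {
    abort("populations, rates and growth factors must be positive; rate_decline in (0, 1]")
  }
  if (sigma < 0) abort("sigma must be non-negative")
  if (any(diff(years) != 1)) abort("years must be contiguous")
  shocks <- lapply(shocks %||% list(), rep5)
  if (any(unlist(shocks) < 0)) abort("shock factors must be non-negative")
  structure(
    list(country = country, years = as.integer(years),
         base_population = base_population, pop_growth = pop_growth,
         base_rate = base_rate, rate_decline = rate_decline,
         sigma = sigma, shocks = shocks,
         deterministic = isTRUE(deterministic), seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate an annual demography panel from a scenario
#'
#' Populations follow the deterministic growth schedule
#' `N[b, t] = N0[b] * g[b]^t`; rates follow
#' `m[b, t] = m0[b] * d[b]^t * shock[b, year] * exp(eps)` with
#' `eps ~ N(0, sigma^2)`; deaths are Poisson with mean `m * N`, or
#' exactly `m * N` in deterministic mode. The same seed always yields
#' the same panel.
#'
#' @param spec A [scenario_spec()].
#' @return An annual demography tibble (`country`, `year`, `band`,
#'   `deaths`, `population`, `rate`) with the realized rates; the
#'   scenario is attached as attribute `"scenario"`.
#' @examples
#' demo <- simulate_country(scenario_spec(sigma = 0, deterministic = TRUE,
#'                                        shocks = NULL))
#' head(demo)
#' @export
simulate_country <- function(spec) {
  if (!inherits(spec, "scenario_spec")) abort("spec must be a scenario_spec")
  bands <- band_labels()
  with_preserved_seed(spec$seed, {
    panel <- tidyr::expand_grid(year = spec$years, band_i = 1:5) |>
      dplyr::mutate(
        t = .data$year - spec$years[1],
        band = bands[.data$band_i],
        population = spec$base_population[.data$band_i] *
          spec$pop_growth[.data$band_i]^.data$t,
        shock = purrr::map2_dbl(.data$year, .data$band_i, function(y, b) {
          s <- spec$shocks[[as.character(y)]]
          if (is.null(s)) 1 else s[b]
        }),
        rate = spec$base_rate[.data$band_i] *
          spec$rate_decline[.data$band_i]^.data$t * .data$shock *
          exp(if (spec$sigma > 0) rnorm(dplyr::n(), 0, spec$sigma) else 0),
        deaths = if (spec$deterministic) .data$rate * .data$population
                 else rpois(dplyr::n(), .data$rate * .data$population)
      )
  })
  out <- panel |>
    dplyr::transmute(country = spec$country, .data$year, .data$band,
                     deaths = as.numeric(.data$deaths), .data$population,
                     rate = .data$deaths / .data$population)
  attr(out, "scenario") <- spec
  out
}

#' Number of ISO weeks in a calendar year
#'
#' 52 for most years, 53 when the year starts on a Thursday (or on a
#' Wednesday in a leap year) — the rule that decides how many weekly
#' rows a year occupies in an STMF file.
#'
#' @param year Integer vector of calendar years.
#' @return Integer vector of 52s and 53s.
#' @export
iso_weeks_in_year <- function(year) {
  wd <- function(y) as.POSIXlt(sprintf("%d-01-01", y), tz = "UTC")$wday
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(wd(year) == 4 | (leap & wd(year) == 3), 53L, 52L)
}

# Split one annual death count into nweeks weekly values that sum back
# exactly; random proportions, last week takes the remainder.
split_weeks <- function(total, nweeks) {
  w <- runif(nweeks, 0.5, 1.5)
  weekly <- total * w / sum(w)
  weekly[nweeks] <- total - sum(weekly[-nweeks])
  weekly
}

#' Write a demography panel as STMF and archive fixture files
#'
#' Emits the exact dialects [read_stmf()] and [read_annual_archive()]
#' parse: a combined weekly `stmf.csv` (annual band deaths split over 52
#' or 53 ISO weeks with conserved totals) and, per country, annual
#' `<country>_deaths.txt` / `<country>_population.txt` tables with the
#' five band values spread uniformly over their constituent single-year
#' ages (0–110+). Round-tripping the files through the readers and
#' [collapse_age_bands()] / [annualize_stmf()] reproduces the panel.
#'
#' @param demography Annual demography panel to serialize.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the weekly split.
#' @param stmf_years Years to include in the weekly file; default all.
#' @param forecast_years Years whose weekly rows get `Forecast = 1`
#'   (for exercising strict-mode filtering); default none.
#' @return Invisibly, a named list of file paths (`stmf`, and per
#'   country `deaths`/`population`).
#' @export
write_fixtures <- function(demography, dir, seed = 1L, stmf_years = NULL,
                           forecast_years = integer()) {
  check_demography(demography)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stmf_years <- stmf_years %||% sort(unique(demography$year))
  band_cols <- c("D0_14", "D15_64", "D65_74", "D75_84", "D85p")
  weekly <- with_preserved_seed(seed, {
    demography |>
      dplyr::filter(.data$year %in% stmf_years) |>
      dplyr::group_by(.data$country, .data$year, .data$band) |>
      dplyr::reframe({
        nw <- iso_weeks_in_year(.data$year[1])
        wk_deaths <- split_weeks(.data$deaths, nw)
        tibble::tibble(week = seq_len(nw), deaths = wk_deaths)
      }) |>
      dplyr::ungroup()
  })
  wide <- weekly |>
    dplyr::mutate(band = band_cols[match(.data$band, band_labels())]) |>
    tidyr::pivot_wider(names_from = "band", values_from = "deaths") |>
    dplyr::arrange(.data$country, .data$year, .data$week) |>
    dplyr::mutate(
      Sex = "b",
      DTotal = rowSums(dplyr::pick(dplyr::all_of(band_cols))),
      Split = 0, SplitSex = 0,
      Forecast = as.integer(.data$year %in% forecast_years)
    ) |>
    dplyr::select(CountryCode = "country", Year = "year", Week = "week",
                  "Sex", dplyr::all_of(band_cols), "DTotal",
                  "Split", "SplitSex", "Forecast")
  stmf_path <- file.path(dir, "stmf.csv")
  readr::write_csv(wide, stmf_path, progress = FALSE)
  paths <- list(stmf = stmf_path)
  ages_of <- function(b) {
    bb <- age_bands()[age_bands()$band == b, ]
    seq.int(bb$lower, min(bb$upper, 110))
  }
  for (cc in unique(demography$country)) {
    one <- dplyr::filter(demography, .data$country == cc)
    per_age <- one |>
      dplyr::group_by(.data$year, .data$band) |>
      dplyr::reframe({
        ages <- ages_of(.data$band[1])
        k <- length(ages)
        d <- rep(.data$deaths / k, k); d[k] <- .data$deaths[1] - sum(d[-k])
        p <- rep(.data$population / k, k)
        p[k] <- .data$population[1] - sum(p[-k])
        tibble::tibble(age = ages, deaths = d, population = p)
      }) |>
      dplyr::arrange(.data$year, .data$age)
    write_hmd <- function(df, value, path, title) {
      lines <- c(title, "",
                 sprintf("%6s %6s %18s %18s %18s",
                         "Year", "Age", "Female", "Male", "Total"),
                 sprintf("%6d %6s %18.8f %18.8f %18.8f",
                         df$year,
                         ifelse(df$age == 110, "110+", as.character(df$age)),
                         df[[value]] / 2, df[[value]] / 2, df[[value]]))
      readr::write_lines(lines, path)
      path
    }
    paths[[paste0(cc, "_deaths")]] <- write_hmd(
      per_age, "deaths", file.path(dir, paste0(cc, "_deaths.txt")),
      paste0(cc, ", Deaths (period 1x1), synthetic fixture"))
    paths[[paste0(cc, "_population")]] <- write_hmd(
      per_age, "population", file.path(dir, paste0(cc, "_population.txt")),
      paste0(cc, ", Population (1-year ages), synthetic fixture"))
  }
  invisible(paths)
}
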