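#' Enumerate all consecutive-year baseline windows
#'
#' Every span of consecutive calendar years `[a, b]` with
#' `first <= a <= b <= last` is a candidate reference baseline. For a
#' candidate range of n years there are n(n+1)/2 such windows — 66 for
#' the default 2009–2019 range.
#'
#' @param first,last First and last candidate baseline year (inclusive).
#' @param exclude Optional years (integer vector) that may not appear in
#'   a baseline; windows intersecting them are omitted. Used to keep the
#'   projected period (and the pandemic years when they are projected)
#'   out of its own baseline.
#' @return A tibble of windows (`window_start`, `window_end`), ordered by
#'   start then end year.
#' @examples
#' nrow(enumerate_windows(2009, 2019))            # 66
#' nrow(enumerate_windows(2009, 2019, 2019:2021)) # 55
#' @export
enumerate_windows <- function(first, last, exclude = NULL) {
  if (length(first) != 1 || length(last) != 1 || first > last) {
    abort("need first <= last candidate baseline years")
  }
  w <- tidyr::expand_grid(window_start = seq.int(first, last),
                          window_end   = seq.int(first, last)) |>
    dplyr::filter(.data$window_end >= .data$window_start)
  if (!is.null(exclude)) {
    exclude <- as.integer(exclude)
    w <- dplyr::filter(
      w, .data$window_end < min(exclude) | .data$window_start > max(exclude) |
        purrr::map2_lgl(.data$window_start, .data$window_end,
                        ~ !any(seq.int(.x, .y) %in% exclude))
    )
  }
  dplyr::arrange(w, .data$window_start, .data$window_end)
}

#' Average age-band mortality rates over a baseline window
#'
#' The counterfactual mortality of each band is the unweighted arithmetic
#' mean of its annual rates over the window years (a mean of rates, not
#' pooled deaths over pooled population).
#'
#' @param demography Annual demography panel (`country`, `year`, `band`,
#'   `deaths`, `population`, `rate`).
#' @param window The baseline window, as `c(start, end)` or a one-row
#'   tibble with `window_start`/`window_end`.
#' @return A tibble `country`, `band`, `rate` of averaged baseline rates.
#' @export
baseline_rates <- function(demography, window) {
  check_demography(demography)
  window <- window_years(window)
  demography <- demography_years(demography, window, "baseline window")
  if (!"rate" %in% names(demography)) {
    demography$rate <- demography$deaths / demography$population
  }
  demography |>
    dplyr::group_by(.data$country, .data$band) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
}

window_years <- function(window) {
  if (is.data.frame(window)) {
    stopifnot(nrow(window) == 1)
    seq.int(window$window_start, window$window_end)
  } else {
    seq.int(min(window), max(window))
  }
}

#' Expected deaths for a projected period under baseline rates
#'
#' Applies the averaged band rates to the projected period's band
#' populations: `E = sum over period years and bands of rate * population`.
#'
#' @param rates Baseline band rates from [baseline_rates()] (`country`,
#'   `band`, `rate`).
#' @param demography Annual demography panel supplying period populations.
#' @param period Projected period, `c(start, end)` (or a single year).
#' @return A tibble `country`, `expected`.
#' @export
expected_deaths <- function(rates, demography, period) {
  check_demography(demography)
  years <- seq.int(min(period), max(period))
  demography <- demography_years(demography, years, "projected period")
  dplyr::inner_join(demography, rates, by = c("country", "band"),
                    suffix = c("", ".baseline")) |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(expected = sum(.data$rate.baseline * .data$population),
                     .groups = "drop")
}

#' Relative excess deaths (P-score)
#'
#' The comparison unit throughout: observed deaths `D` minus expected
#' deaths `E`, as a percentage of expected, `100 * (D - E) / E`.
#'
#' @param observed,expected Numeric vectors of observed and expected
#'   death counts; `expected` must be positive.
#' @return Numeric vector of P-scores in percent.
#' @examples
#' relative_excess(110, 100) # 10
#' @export
relative_excess <- function(observed, expected) {
  if (any(expected <= 0)) abort("expected deaths must be positive")
  100 * (observed - expected) / expected
}

#' Run the multiverse of baseline windows for one projected period
#'
#' Computes one excess-death estimate per country and baseline window:
#' observed period deaths `D`, expected deaths `E` under the window's
#' averaged band rates, and the P-score `p_pct`. This is the engine every
#' summary, ranking and attenuation analysis consumes.
#'
#' @param demography Annual demography panel.
#' @param period Projected period, `c(start, end)` or a single year
#'   (lengths 1–4 are the intended use).
#' @param windows Baseline windows tibble from [enumerate_windows()];
#'   default enumerates `baseline_range` excluding the period years, so
#'   pandemic or projected years never sit in their own baseline.
#' @param baseline_range Candidate baseline years, default `c(2009, 2019)`.
#' @param allow_overlap Permit windows that intersect the projected
#'   period (used by [yearly_envelope()]'s `all_66` policy for historical
#'   years). By default an intersecting window is an error, not a silent
#'   exclusion.
#' @return A tibble of class `mv_grid`: `country`, `period_start`,
#'   `period_end`, `window_start`, `window_end`, `D`, `E`, `p_pct`.
#' @examples
#' demo <- simulate_country(scenario_spec(sigma = 0, deterministic = TRUE))
#' grid <- run_multiverse(demo, c(2020, 2021))
#' summarize_multiverse(grid)
#' @export
run_multiverse <- function(demography, period, windows = NULL,
                           baseline_range = c(2009, 2019),
                           allow_overlap = FALSE) {
  check_demography(demography)
  period <- c(min(period), max(period))
  period_years <- seq.int(period[1], period[2])
  if (length(period_years) > 4) {
    abort("projected periods longer than 4 years are not supported")
  }
  if (is.null(windows)) {
    windows <- enumerate_windows(baseline_range[1], baseline_range[2],
                                 exclude = period_years)
  }
  if (nrow(windows) == 0) abort("no admissible baseline windows")
  if (!allow_overlap) {
    bad <- dplyr::filter(windows, .data$window_end >= period[1] &
                           .data$window_start <= period[2])
    if (nrow(bad) > 0) {
      abort(paste0("baseline window(s) intersect the projected period: ",
                   paste(paste0(bad$window_start, "-", bad$window_end),
                         collapse = ", ")))
    }
  }
  observed <- demography_years(demography, period_years, "projected period") |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(D = sum(.data$deaths), .groups = "drop")
  base_years <- seq.int(min(windows$window_start), max(windows$window_end))
  if (!"rate" %in% names(demography)) {
    demography$rate <- demography$deaths / demography$population
  }
  # Per country: window-mean band rates via cumulative sums over years,
  # then E = sum_b mbar_b * (band population summed over period years).
  grid <- purrr::map(sort(unique(demography$country)), function(cc) {
    one <- dplyr::filter(demography, .data$country == cc)
    one_b <- demography_years(one, base_years, "baseline window")
    bands <- intersect(band_labels(), unique(one$band))
    rate_mat <- matrix(NA_real_, nrow = length(base_years),
                       ncol = length(bands),
                       dimnames = list(base_years, bands))
    rate_mat[cbind(match(one_b$year, base_years),
                   match(one_b$band, bands))] <- one_b$rate
    if (anyNA(rate_mat)) abort(paste0("missing band rates for ", cc))
    cs <- rbind(0, apply(rate_mat, 2, cumsum))
    a <- match(windows$window_start, base_years)
    b <- match(windows$window_end, base_years)
    mbar <- (cs[b + 1L, , drop = FALSE] - cs[a, , drop = FALSE]) /
      (windows$window_end - windows$window_start + 1)
    one_p <- dplyr::filter(one, .data$year %in% period_years)
    pop <- tapply(one_p$population, factor(one_p$band, bands), sum)
    tibble::tibble(country = cc,
                   window_start = windows$window_start,
                   window_end = windows$window_end,
                   E = as.numeric(mbar %*% pop))
  }) |>
    purrr::list_rbind() |>
    dplyr::inner_join(observed, by = "country") |>
    dplyr::mutate(
      period_start = period[1], period_end = period[2],
      p_pct = relative_excess(.data$D, .data$E)
    ) |>
    dplyr::select("country", "period_start", "period_end",
                  "window_start", "window_end", "D", "E", "p_pct") |>
    dplyr::arrange(.data$country, .data$window_start, .data$window_end)
  class(grid) <- c("mv_grid", class(grid))
  grid
}

#' Summarize the multiverse distribution of P-scores
#'
#' Per country and projected period: number of windows, mean, sample
#' standard deviation (n−1 denominator), minimum, maximum, range, median
#' and quartiles of the per-window P-scores.
#'
#' @param grid An `mv_grid` from [run_multiverse()] (any tibble with
#'   `country`, `period_start`, `period_end`, `p_pct` works).
#' @param quartile_type Quantile algorithm passed to [stats::quantile()];
#'   default 7 (linear interpolation).
#' @return A tibble with one row per country and period; `sd` is `NA`
#'   (flagged by `sd_defined = FALSE`) when only one window is present.
#' @export
summarize_multiverse <- function(grid, quartile_type = 7) {
  if (nrow(grid) == 0) abort("no estimates to summarize")
  grid |>
    dplyr::group_by(.data$country, .data$period_start, .data$period_end) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      mean = mean(.data$p_pct),
      sd = if (dplyr::n() > 1) stats::sd(.data$p_pct) else NA_real_,
      sd_defined = dplyr::n() > 1,
      min = min(.data$p_pct),
      max = max(.data$p_pct),
      range = max(.data$p_pct) - min(.data$p_pct),
      q1 = quantile(.data$p_pct, 0.25, type = quartile_type, names = FALSE),
      median = median(.data$p_pct),
      q3 = quantile(.data$p_pct, 0.75, type = quartile_type, names = FALSE),
      .groups = "drop"
    )
}

#' Per-year multiverse envelopes of relative excess
#'
#' For each single projected year, runs the multiverse and reports the
#' five envelope statistics (min, first quartile, median, third quartile,
#' max) of the per-window P-scores — the numbers behind a shaded
#' year-by-year excess plot.
#'
#' @param demography Annual demography panel.
#' @param years Projected years to evaluate.
#' @param window_policy `"all_66"` (default) uses every window of the
#'   candidate range for every year, so a historical year may sit inside
#'   its own baseline; `"exclude_overlap"` drops windows containing the
#'   projected year.
#' @param baseline_range Candidate baseline years, default `c(2009, 2019)`.
#' @param quartile_type Passed to [stats::quantile()].
#' @return A tibble of class `mv_envelope`: `country`, `year`,
#'   `n_windows`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
yearly_envelope <- function(demography, years,
                            window_policy = c("all_66", "exclude_overlap"),
                            baseline_range = c(2009, 2019),
                            quartile_type = 7) {
  window_policy <- match.arg(window_policy)
  out <- purrr::map(years, function(y) {
    windows <- enumerate_windows(
      baseline_range[1], baseline_range[2],
      exclude = if (window_policy == "exclude_overlap") y else NULL
    )
    run_multiverse(demography, c(y, y), windows = windows,
                   allow_overlap = window_policy == "all_66") |>
      summarize_multiverse(quartile_type = quartile_type) |>
      dplyr::transmute(.data$country, year = y, .data$n_windows,
                       .data$min, .data$q1, .data$median, .data$q3, .data$max)
  }) |>
    purrr::list_rbind()
  class(out) <- c("mv_envelope", class(out))
  out
}
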