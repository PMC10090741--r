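#' Down-weighting schemes for older reference years
#'
#' A plain multiverse average treats an 11-year-old baseline as seriously
#' as last year's. Three schemes discount older reference years relative
#' to an anchor year (the last pre-pandemic year, 2019 by default):
#'
#' * `dw1` — linear, 10% per year: `w(y) = max(0, 1 - 0.10 (anchor - y))`,
#'   so 2009 gets weight 0;
#' * `dw2` — linear, 5% per year: `w(y) = max(0, 1 - 0.05 (anchor - y))`,
#'   so 2009 gets weight 0.50;
#' * `dw3` — geometric halving: `w(y) = 0.5^(anchor - y)`;
#' * `equal` — constant 1 (reduces weighted averages to plain means).
#'
#' @param name Scheme name: `"dw1"`, `"dw2"`, `"dw3"` or `"equal"`.
#' @param anchor_year Year receiving weight 1; default 2019.
#' @return An object of class `weight_scheme`.
#' @examples
#' year_weight(2009, weight_scheme("dw1")) # 0
#' year_weight(2009, weight_scheme("dw3")) # 0.5^10
#' @export
weight_scheme <- function(name = c("dw1", "dw2", "dw3", "equal"),
                          anchor_year = 2019) {
  name <- match.arg(name)
  structure(list(name = name, anchor_year = anchor_year),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme ", x$name, ", anchor ", x$anchor_year, ">\n", sep = "")
  invisible(x)
}

as_weight_scheme <- function(scheme, anchor_year = 2019) {
  if (inherits(scheme, "weight_scheme")) scheme
  else weight_scheme(scheme, anchor_year)
}

#' Per-year weight under a down-weighting scheme
#'
#' @param year Calendar year(s), none after the scheme's anchor year.
#' @param scheme A [weight_scheme()] or its name.
#' @param anchor_year Anchor used when `scheme` is given by name.
#' @return Numeric weights in `[0, 1]`, non-increasing as years recede.
#' @export
year_weight <- function(year, scheme = "dw1", anchor_year = 2019) {
  scheme <- as_weight_scheme(scheme, anchor_year)
  if (any(year > scheme$anchor_year)) {
    abort("year after the scheme's anchor year has no defined weight")
  }
  back <- scheme$anchor_year - year
  switch(scheme$name,
    dw1   = pmax(0, 1 - 0.10 * back),
    dw2   = pmax(0, 1 - 0.05 * back),
    dw3   = 0.5^back,
    equal = rep(1, length(back))
  )
}

#' Per-window weight: the mean of its years' weights
#'
#' A baseline window is weighted by the arithmetic mean of the per-year
#' weights of the reference years it contains; e.g. under `dw1` the
#' 2018–2019 window gets (0.9 + 1.0)/2 = 0.95.
#'
#' @param windows Windows tibble (`window_start`, `window_end`) from
#'   [enumerate_windows()], or a single `c(start, end)` vector.
#' @param scheme A [weight_scheme()] or its name.
#' @param anchor_year Anchor used when `scheme` is given by name.
#' @return The windows tibble with a `weight` column appended (or a bare
#'   number for a single-window vector input).
#' @examples
#' window_weight(c(2018, 2019), "dw1") # 0.95
#' window_weight(c(2018, 2019), "dw3") # 0.75
#' @export
window_weight <- function(windows, scheme = "dw1", anchor_year = 2019) {
  scheme <- as_weight_scheme(scheme, anchor_year)
  if (!is.data.frame(windows)) {
    return(mean(year_weight(window_years(windows), scheme)))
  }
  windows |>
    dplyr::mutate(weight = purrr::map2_dbl(
      .data$window_start, .data$window_end,
      ~ mean(year_weight(seq.int(.x, .y), scheme))
    ))
}

#' Weighted average of multiverse estimates
#'
#' `sum(w * p) / sum(w)`; the normalization runs over the included
#' windows, so windows with weight 0 (e.g. the 2009-only baseline under
#' `dw1`) simply contribute nothing.
#'
#' @param p_pct P-scores, one per window.
#' @param weights Matching window weights; must not all be zero.
#' @return The weighted mean P-score (percent).
#' @export
weighted_average <- function(p_pct, weights) {
  if (length(p_pct) != length(weights)) {
    abort("need one weight per estimate")
  }
  if (all(weights == 0)) abort("all window weights are zero")
  sum(weights * p_pct) / sum(weights)
}

#' Down-weighted multiverse averages per country
#'
#' Convenience verb: applies one or more down-weighting schemes to a
#' multiverse grid and returns the weighted average P-score per country,
#' period and scheme — the `dw1`/`dw2`/`dw3` columns of a summary table.
#'
#' @param grid An `mv_grid` from [run_multiverse()].
#' @param schemes Character vector of scheme names.
#' @param anchor_year Anchor year for all schemes.
#' @return A tibble `country`, `period_start`, `period_end`, `scheme`,
#'   `p_pct` (pivot wider for a Table-style layout).
#' @export
weighted_multiverse <- function(grid, schemes = c("dw1", "dw2", "dw3"),
                                anchor_year = 2019) {
  purrr::map(schemes, function(s) {
    w <- window_weight(
      dplyr::distinct(grid, .data$window_start, .data$window_end), s,
      anchor_year
    )
    grid |>
      dplyr::inner_join(w, by = c("window_start", "window_end")) |>
      dplyr::group_by(.data$country, .data$period_start, .data$period_end) |>
      dplyr::summarise(p_pct = weighted_average(.data$p_pct, .data$weight),
                       .groups = "drop") |>
      dplyr::mutate(scheme = s)
  }) |>
    purrr::list_rbind() |>
    dplyr::select("country", "period_start", "period_end", "scheme", "p_pct")
}
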