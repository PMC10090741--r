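#' Packaged reference results for 33 high-income countries
#'
#' Published multiverse excess-mortality results for 33 high-income
#' countries (plus a Europe composite) over 2009–2021, shipped as plain
#' CSV for cross-checking:
#'
#' * `"summary"` — per-country multiverse summary for the projected
#'   period 2020+2021 across the 66 baseline windows of 2009–2019:
#'   average, SD, minimum, maximum and range of the P-score, plus the
#'   dw1/dw2/dw3 down-weighted averages (percent);
#' * `"projected_periods"` — per-country P-scores for projected periods
#'   2020, 2021, 2020–2021, 2019–2021 and 2018–2021 and the attenuation
#'   drops `max(p2020, p2021) - p_kyr` (percentage points).
#'
#' Values are as printed (one decimal), so statistics recomputed from
#' them can differ from unrounded originals in the last digit.
#'
#' @param which `"summary"` or `"projected_periods"`.
#' @return A tibble.
#' @export
reference_table <- function(which = c("summary", "projected_periods")) {
  which <- match.arg(which)
  file <- switch(which,
    summary = "reference_summary_2020_2021.csv",
    projected_periods = "reference_projected_periods.csv"
  )
  path <- system.file("extdata", file, package = "mvexcess", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
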