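#' Read a weekly short-term mortality fluctuations (STMF) file
#'
#' Parses the `stmf.csv` dialect distributed by the Human Mortality
#' Database: one row per country, year, ISO week and sex stratum, with
#' death counts in the five standard age bands
#' (columns `D0_14`, `D15_64`, `D65_74`, `D75_84`, `D85p`) and a rounded
#' total (`DTotal`). Counts may be fractional because the source splits
#' deaths of unknown age proportionally.
#'
#' @param path Path to a CSV file in the STMF dialect. A header row is
#'   required; rate columns and flag columns other than `Forecast` are
#'   ignored.
#' @param sex Sex stratum to keep: `"b"` (both, the default), `"f"` or
#'   `"m"` (aliases `"both"`, `"female"`, `"male"` accepted).
#' @param strict If `TRUE`, rows flagged `Forecast == 1` are dropped; by
#'   default all rows are retained.
#' @return A tibble of weekly death records in long form: `country`,
#'   `year`, `week`, `sex`, `band`, `deaths`. Rows whose band deaths
#'   disagree with the file's `DTotal` by more than 0.5 trigger a warning
#'   naming the rows (STMF totals are rounded, so 0.5 is the expected
#'   slack); they are reported, never silently dropped.
#' @seealso [annualize_stmf()] to sum weeks into annual band deaths.
#' @export
read_stmf <- function(path, sex = c("b", "f", "m", "both", "female", "male"),
                      strict = FALSE) {
  sex <- match.arg(sex)
  sex <- c(b = "b", f = "f", m = "m", both = "b", female = "f", male = "m")[[sex]]
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  band_cols <- c("D0_14", "D15_64", "D65_74", "D75_84", "D85p")
  need <- c("CountryCode", "Year", "Week", "Sex", band_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("STMF file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("Year", "Week", band_cols, intersect("DTotal", names(raw)))) {
    vals <- raw[[col]]
    if (!is.numeric(vals)) {
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & is.na(parsed))
      if (length(bad) > 0) {
        abort(paste0("unreadable numeric value in column ", col,
                     " at data row(s) ", paste(head(bad, 5), collapse = ", ")))
      }
      raw[[col]] <- parsed
    }
  }
  if (strict && "Forecast" %in% names(raw)) {
    raw <- dplyr::filter(raw, is.na(.data$Forecast) | .data$Forecast != 1)
  }
  raw <- dplyr::filter(raw, tolower(.data$Sex) == sex)
  if ("DTotal" %in% names(raw) && nrow(raw) > 0) {
    band_sum <- rowSums(raw[band_cols])
    off <- which(abs(band_sum - raw$DTotal) > 0.5)
    if (length(off) > 0) {
      warn(paste0("band deaths disagree with DTotal by more than 0.5 in ",
                  length(off), " row(s), e.g. row ",
                  paste(head(off, 5), collapse = ", ")))
    }
  }
  out <- raw |>
    dplyr::select(country = "CountryCode", year = "Year", week = "Week",
                  sex = "Sex", dplyr::all_of(band_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(band_cols),
                        names_to = "band", values_to = "deaths") |>
    dplyr::mutate(
      band = band_labels()[match(.data$band, c("D0_14", "D15_64", "D65_74",
                                               "D75_84", "D85p"))],
      sex = tolower(.data$sex)
    )
  if (any(out$deaths < 0, na.rm = TRUE)) abort("negative weekly death count")
  if (any(out$week < 1, na.rm = TRUE)) abort("week index below 1")
  out
}

#' Sum weekly STMF records into annual band death counts
#'
#' Annual deaths are the sum over the weeks the file assigns to each
#' calendar year; the file's own year label is trusted verbatim (no ISO
#' re-dating), so 53-week years contribute 53 weekly values.
#'
#' @param records Weekly records from [read_stmf()]; all rows must share
#'   one sex stratum.
#' @return A partial annual demography tibble (`country`, `year`, `band`,
#'   `deaths`) without populations.
#' @export
annualize_stmf <- function(records) {
  need <- c("country", "year", "week", "band", "deaths")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if ("sex" %in% names(records) && dplyr::n_distinct(records$sex) > 1) {
    abort("records mix sex strata; filter to one before annualizing")
  }
  dup <- records |>
    dplyr::count(.data$country, .data$year, .data$week, .data$band) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    keys <- dup |>
      dplyr::distinct(.data$country, .data$year, .data$week) |>
      dplyr::mutate(key = paste0(.data$country, ":", .data$year, ":W", .data$week))
    abort(paste0("duplicate (country, year, week) rows: ",
                 paste(head(keys$key, 10), collapse = ", ")))
  }
  records |>
    dplyr::group_by(.data$country, .data$year, .data$band) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
    dplyr::arrange(.data$country, .data$year,
                   match(.data$band, band_labels()))
}

# Parse one HMD archive table (Deaths_1x1 / Population dialect): optional
# preamble lines, then a header "Year Age Female Male Total", whitespace-
# or comma-delimited. Age "110+" is coded as 110. Population files may
# carry duplicate year rows labelled e.g. "1959-" and "1959+" around a
# territorial change; `boundary` picks which estimate survives.
read_hmd_table <- function(path, value_col = "Total",
                           boundary = c("plus", "minus")) {
  boundary <- match.arg(boundary)
  lines <- readr::read_lines(path)
  hdr <- grep("\\bYear\\b[ ,\t]+\\bAge\\b", lines)[1]
  if (is.na(hdr)) abort(paste0("no 'Year Age ...' header found in ", path))
  body <- lines[hdr:length(lines)]
  body <- body[nzchar(trimws(body))]
  delim <- if (grepl(",", body[1])) "," else NULL
  tab <- if (is.null(delim)) {
    readr::read_table(I(body), show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character()))
  } else {
    readr::read_csv(I(body), show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  if (!all(c("Year", "Age") %in% names(tab)) || !value_col %in% names(tab)) {
    abort(paste0(path, " lacks required column(s) among Year, Age, ", value_col))
  }
  tab <- tab |>
    dplyr::mutate(
      year_label = trimws(.data$Year),
      year = as.integer(sub("[+-]$", "", .data$year_label)),
      age = as.integer(sub("\\+$", "", trimws(.data$Age))),
      value = suppressWarnings(as.numeric(gsub("[ ,]", "", .data[[value_col]])))
    )
  if (any(is.na(tab$year)) || any(is.na(tab$age))) {
    abort(paste0("unparseable Year/Age entries in ", path))
  }
  bad <- which(is.na(tab$value) & !trimws(tab[[value_col]]) %in% c(".", "NA", ""))
  if (length(bad) > 0) {
    abort(paste0("unreadable numeric value in ", path, " at data row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  # resolve duplicated boundary years: keep the chosen estimate
  marker <- if (boundary == "plus") "\\+$" else "-$"
  tab <- tab |>
    dplyr::group_by(.data$year, .data$age) |>
    dplyr::filter(dplyr::n() == 1 | grepl(marker, .data$year_label)) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  if (any(tab$value < 0, na.rm = TRUE)) {
    abort(paste0("negative value in ", path))
  }
  dplyr::select(tab, "year", "age", "value")
}

#' Read annual HMD-archive deaths and population files (1-year ages)
#'
#' Reads a pair of per-country archive tables in the `Deaths_1x1` and
#' `Population` dialects (columns `Year`, `Age`, `Female`, `Male`,
#' `Total`; whitespace- or comma-delimited; age `110+` allowed) and joins
#' them into a single panel keyed by year and single-year age.
#'
#' @param deaths_path,population_path Paths to the archive tables.
#' @param sex Which value column to use; `"Total"` (default), `"Female"`
#'   or `"Male"`.
#' @param boundary Population files can list two estimates for a year at
#'   a territorial boundary (labels like `1959-`/`1959+`, i.e. the 1
#'   January estimates under the old and new definition). `"plus"` (the
#'   default) keeps the estimate labelled for 1 January of that year
#'   under the current definition; `"minus"` keeps the other.
#' @return A tibble `year`, `age`, `deaths`, `population`. Deaths
#'   reported for a (year, age) with no population are an error, as are
#'   negative values.
#' @seealso [collapse_age_bands()] to move to the five standard bands.
#' @export
read_annual_archive <- function(deaths_path, population_path,
                                sex = c("Total", "Female", "Male"),
                                boundary = c("plus", "minus")) {
  sex <- match.arg(sex)
  boundary <- match.arg(boundary)
  d <- read_hmd_table(deaths_path, value_col = sex) |>
    dplyr::rename(deaths = "value")
  p <- read_hmd_table(population_path, value_col = sex, boundary = boundary) |>
    dplyr::rename(population = "value")
  panel <- dplyr::full_join(d, p, by = c("year", "age")) |>
    dplyr::arrange(.data$year, .data$age)
  orphan <- dplyr::filter(panel, !is.na(.data$deaths) &
                            (is.na(.data$population) | .data$population == 0))
  if (nrow(orphan) > 0) {
    abort(paste0("deaths without population for (year, age): ",
                 paste(head(paste0(orphan$year, "/", orphan$age), 5),
                       collapse = ", ")))
  }
  dplyr::filter(panel, !is.na(.data$population)) |>
    dplyr::mutate(deaths = dplyr::coalesce(.data$deaths, 0))
}

#' Splice archive and STMF death sources into one annual demography panel
#'
#' Deaths come from the annual archive for years before `switch_year` and
#' from the annualized STMF weekly file from `switch_year` on. Populations
#' come from the archive; years beyond archive coverage (typically the
#' most recent pandemic years) are filled per band by the configured
#' extrapolation. Every cell records its provenance.
#'
#' @param archive Annual demography panel (five bands) from the archive:
#'   `country`, `year`, `band`, `deaths`, `population`.
#' @param stmf_deaths Partial panel (`country`, `year`, `band`, `deaths`)
#'   from [annualize_stmf()].
#' @param switch_year First year whose deaths are taken from STMF.
#'   Default: the first year after archive coverage ends.
#' @param population_fill How to fill populations for years the archive
#'   lacks: `"linear"` (default) extrapolates per band from the last two
#'   archive years; `"carry_forward"` repeats the last archive value.
#' @return An annual demography tibble `country`, `year`, `band`,
#'   `deaths`, `population`, `rate`, `source` (deaths provenance,
#'   `"archive"` or `"stmf"`) and `population_source` (`"archive"` or
#'   the fill method). Years covered by neither source are an error.
#' @export
merge_sources <- function(archive, stmf_deaths, switch_year = NULL,
                          population_fill = c("linear", "carry_forward")) {
  population_fill <- match.arg(population_fill)
  check_demography(archive, arg = "archive")
  check_demography(stmf_deaths, require_population = FALSE, arg = "stmf_deaths")
  countries <- union(unique(archive$country), unique(stmf_deaths$country))
  out <- purrr::map(countries, function(cc) {
    arc <- dplyr::filter(archive, .data$country == cc)
    stm <- dplyr::filter(stmf_deaths, .data$country == cc)
    if (nrow(arc) == 0 || nrow(stm) == 0) {
      abort(paste0("country ", cc, " missing from one source"))
    }
    sw <- switch_year %||% (max(arc$year) + 1L)
    years <- seq(min(arc$year), max(c(arc$year, stm$year)))
    gap <- setdiff(years, union(arc$year[arc$year < sw], stm$year[stm$year >= sw]))
    if (length(gap) > 0) {
      abort(paste0("year(s) ", paste(gap, collapse = ", "),
                   " covered by neither source for ", cc))
    }
    deaths <- dplyr::bind_rows(
      arc |> dplyr::filter(.data$year < sw) |>
        dplyr::select("country", "year", "band", "deaths") |>
        dplyr::mutate(source = "archive"),
      stm |> dplyr::filter(.data$year >= sw) |>
        dplyr::select("country", "year", "band", "deaths") |>
        dplyr::mutate(source = "stmf")
    )
    pop <- arc |>
      dplyr::select("country", "year", "band", "population") |>
      dplyr::mutate(population_source = "archive")
    miss_years <- setdiff(years, pop$year)
    if (length(miss_years) > 0) {
      fill <- arc |>
        dplyr::group_by(.data$band) |>
        dplyr::arrange(.data$year, .by_group = TRUE) |>
        dplyr::summarise(
          n_last = dplyr::last(.data$population),
          slope = if (dplyr::n() >= 2 && population_fill == "linear") {
            dplyr::last(.data$population) - dplyr::nth(.data$population, dplyr::n() - 1)
          } else 0,
          last_year = dplyr::last(.data$year),
          .groups = "drop"
        )
      extra <- tidyr::expand_grid(year = miss_years, fill) |>
        dplyr::mutate(
          country = cc,
          population = .data$n_last + (.data$year - .data$last_year) * .data$slope,
          population_source = population_fill
        ) |>
        dplyr::select("country", "year", "band", "population", "population_source")
      if (any(extra$population <= 0)) {
        abort("population extrapolation produced non-positive values")
      }
      pop <- dplyr::bind_rows(pop, extra)
    }
    dplyr::inner_join(deaths, pop, by = c("country", "year", "band"))
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(rate = .data$deaths / .data$population) |>
    dplyr::arrange(.data$country, .data$year, match(.data$band, band_labels())) |>
    dplyr::select("country", "year", "band", "deaths", "population", "rate",
                  "source", "population_source")
  check_demography(out, arg = "merged panel")
  out
}
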