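test_that("enumerate_windows returns every consecutive span exactly once", {
  w <- enumerate_windows(2009, 2019)
  expect_equal(nrow(w), 66)
  expect_equal(nrow(dplyr::distinct(w)), 66)
  expect_true(all(w$window_start <= w$window_end))
  # deterministic order: by start, then end
  expect_equal(w, dplyr::arrange(w, window_start, window_end))

  expect_equal(nrow(enumerate_windows(2009, 2009)), 1)
  expect_error(enumerate_windows(2019, 2009), "first")

  # n(n+1)/2 windows for candidate ranges of n = 1..11 years
  for (n in 1:11) {
    expect_equal(nrow(enumerate_windows(2009, 2009 + n - 1)), n * (n + 1) / 2)
  }
})

test_that("excluding projected years removes exactly the intersecting windows", {
  # brute-force oracle: enumerate all spans, drop by explicit intersection
  brute <- function(first, last, excl) {
    count <- 0
    for (a in first:last) for (b in a:last) {
      if (!any(a:b %in% excl)) count <- count + 1
    }
    count
  }
  expect_equal(nrow(enumerate_windows(2009, 2019, 2019:2021)), 55)
  expect_equal(nrow(enumerate_windows(2009, 2019, 2018:2021)), 45)
  for (excl in list(2019, 2015, c(2010, 2017), 2012:2014)) {
    expect_equal(nrow(enumerate_windows(2009, 2019, excl)),
                 brute(2009, 2019, excl))
  }
})

test_that("baseline_rates averages annual band rates over the window", {
  demo <- random_panel(1)
  one <- baseline_rates(demo, c(2015, 2015))
  direct <- demo |> dplyr::filter(year == 2015)
  expect_equal(one$rate[match(direct$band, one$band)], direct$rate)

  two_year <- tibble::tibble(
    country = "X", year = c(2010, 2011), band = "15-64",
    deaths = c(10, 20), population = c(1000, 1000),
    rate = c(0.010, 0.020)
  )
  expect_equal(baseline_rates(two_year, c(2010, 2011))$rate, 0.015)

  # brute-force per-band loop oracle on a random panel
  panel <- random_panel(2, years = 2009:2014)
  got <- baseline_rates(panel, c(2009, 2014))
  for (b in age_bands()$band) {
    rates <- c()
    for (y in 2009:2014) {
      row <- panel[panel$year == y & panel$band == b, ]
      rates <- c(rates, row$deaths / row$population)
    }
    expect_equal(got$rate[got$band == b], mean(rates), tolerance = 1e-12)
  }

  expect_error(baseline_rates(demo, c(2005, 2010)), "2005")
})

test_that("expected_deaths applies baseline rates to period populations", {
  single <- tibble::tibble(country = "X", year = 2020, band = "85+",
                           deaths = 0, population = 1000, rate = 0)
  rates <- tibble::tibble(country = "X", band = "85+", rate = 0.01)
  expect_equal(expected_deaths(rates, single, 2020)$expected, 10)

  # linearity: two identical years double E
  double <- dplyr::bind_rows(single, dplyr::mutate(single, year = 2021))
  expect_equal(expected_deaths(rates, double, c(2020, 2021))$expected, 20)

  expect_error(expected_deaths(rates, single, c(2020, 2021)), "2021")
})

test_that("vectorized expected deaths equal an independent double-loop oracle", {
  for (seed in 1:50) {
    panel <- random_panel(seed)
    window <- sort(sample(2009:2019, 2, replace = TRUE))
    period <- c(2020, 2021)
    rates <- baseline_rates(panel, window)
    got <- expected_deaths(rates, panel, period)$expected
    expect_equal(got, oracle_expected(panel, window, period),
                 tolerance = 1e-12)
  }
})

test_that("the grid engine agrees with the per-window rate/expectation chain", {
  # run_multiverse computes E over the window axis in one sweep; the
  # baseline_rates -> expected_deaths chain recomputes each window
  # independently. Both routes must agree on random panels.
  for (seed in c(3, 14, 27)) {
    panel <- random_panel(seed)
    grid <- run_multiverse(panel, c(2020, 2021))
    idx <- sample(nrow(grid), 10)
    for (i in idx) {
      rates <- baseline_rates(panel, c(grid$window_start[i], grid$window_end[i]))
      e <- expected_deaths(rates, panel, c(2020, 2021))$expected
      expect_equal(grid$E[i], e, tolerance = 1e-12)
    }
  }
})

test_that("relative_excess follows 100 (D - E) / E and its monotonicity", {
  expect_equal(relative_excess(100, 100), 0)
  expect_equal(relative_excess(110, 100), 10)
  expect_equal(relative_excess(95, 100), -5)
  expect_error(relative_excess(10, 0), "positive")
  expect_error(relative_excess(10, -5), "positive")
  # strictly increasing in D, strictly decreasing in E
  D <- seq(50, 150, by = 10)
  expect_true(all(diff(relative_excess(D, 100)) > 0))
  E <- seq(50, 150, by = 10)
  expect_true(all(diff(relative_excess(100, E)) < 0))
})

test_that("run_multiverse: stationary demography gives p = 0 in every window", {
  demo <- stationary_demography()
  grid <- run_multiverse(demo, c(2020, 2021))
  expect_equal(nrow(grid), 66)
  expect_equal(grid$p_pct, rep(0, 66), tolerance = 1e-12)
})

test_that("a multiplicative rate shock is recovered exactly by every window", {
  demo <- shock_demography(list("2020" = 1.12))
  grid <- run_multiverse(demo, 2020)
  expect_equal(grid$p_pct, rep(12, nrow(grid)), tolerance = 1e-9)
})

test_that("run_multiverse chains the three formulas as a hand computation", {
  # one band, one window: E = mean rate x population, p = 100 (D - E)/E
  demo <- tibble::tibble(
    country = "X", year = 2018:2020, band = "65-74",
    deaths = c(20, 30, 40), population = c(1000, 1000, 800)
  ) |> dplyr::mutate(rate = deaths / population)
  grid <- run_multiverse(demo, 2020,
                         windows = tibble::tibble(window_start = 2018,
                                                  window_end = 2019))
  E <- mean(c(20 / 1000, 30 / 1000)) * 800
  expect_equal(grid$E, E)
  expect_equal(grid$D, 40)
  expect_equal(grid$p_pct, 100 * (40 - E) / E)
})

test_that("windows intersecting the projected period are a hard error", {
  demo <- stationary_demography()
  w <- tibble::tibble(window_start = 2018, window_end = 2020)
  expect_error(run_multiverse(demo, c(2020, 2021), windows = w), "intersect")
  expect_silent(run_multiverse(demo, c(2020, 2021), windows = w,
                               allow_overlap = TRUE))
})

test_that("p is scale invariant and multi-year p is the E-weighted mean of years", {
  demo <- simulate_country(scenario_spec(seed = 5))
  grid <- run_multiverse(demo, c(2020, 2021))
  scaled <- demo |> dplyr::mutate(deaths = deaths * 7, population = population * 7)
  grid_scaled <- run_multiverse(scaled, c(2020, 2021))
  expect_equal(grid$p_pct, grid_scaled$p_pct, tolerance = 1e-12)

  g20 <- run_multiverse(demo, 2020, windows = grid[c("window_start", "window_end")])
  g21 <- run_multiverse(demo, 2021, windows = grid[c("window_start", "window_end")])
  ew <- (g20$p_pct * g20$E + g21$p_pct * g21$E) / (g20$E + g21$E)
  expect_equal(grid$p_pct, ew, tolerance = 1e-9)
  expect_true(all(grid$p_pct >= pmin(g20$p_pct, g21$p_pct) - 1e-9))
  expect_true(all(grid$p_pct <= pmax(g20$p_pct, g21$p_pct) + 1e-9))
})

test_that("summarize_multiverse matches textbook statistics", {
  demo <- stationary_demography()
  single <- run_multiverse(
    demo, 2020, windows = tibble::tibble(window_start = 2019, window_end = 2019))
  s1 <- summarize_multiverse(single)
  expect_false(s1$sd_defined)
  expect_true(is.na(s1$sd))
  expect_equal(s1$min, s1$max)
  expect_equal(s1$min, s1$mean)

  two <- tibble::tibble(country = "X", period_start = 2020, period_end = 2020,
                        p_pct = c(0, 10))
  s2 <- summarize_multiverse(two)
  expect_equal(s2$mean, 5)
  expect_equal(s2$range, 10)

  set.seed(9)
  vals <- rnorm(66, 5, 3)
  g <- tibble::tibble(country = "X", period_start = 2020, period_end = 2020,
                      p_pct = vals)
  s <- summarize_multiverse(g)
  expect_equal(s$mean, mean(vals))
  expect_equal(s$sd, sd(vals))
  expect_equal(s$median, median(vals))
  expect_equal(s$q1, quantile(vals, 0.25, names = FALSE))
  expect_equal(s$q3, quantile(vals, 0.75, names = FALSE))
  expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$max)
  expect_error(summarize_multiverse(g[0, ]), "no estimates")
})

test_that("yearly_envelope tracks the multiverse distribution per year", {
  demo <- stationary_demography()
  env <- yearly_envelope(demo, 2009:2021)
  expect_equal(nrow(env), 13)
  expect_equal(env$n_windows, rep(66, 13))
  for (col in c("min", "q1", "median", "q3", "max")) {
    expect_equal(env[[col]], rep(0, 13), tolerance = 1e-12)
  }

  # monotone declining rates, fixed population: median p declines with year
  spec <- stationary_spec()
  spec$rate_decline <- rep(0.97, 5)
  declining <- simulate_country(spec)
  env_d <- yearly_envelope(declining, 2009:2021, window_policy = "all_66")
  expect_true(all(diff(env_d$median) < 0))

  # single-window policy edge: min = median = max
  one <- yearly_envelope(demo, 2020, baseline_range = c(2019, 2019))
  expect_equal(one$min, one$max)
  expect_equal(one$min, one$median)

  # exclude_overlap drops windows containing the projected year
  env_x <- yearly_envelope(demo, 2015, window_policy = "exclude_overlap")
  expect_equal(env_x$n_windows, nrow(enumerate_windows(2009, 2019, 2015)))
})
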