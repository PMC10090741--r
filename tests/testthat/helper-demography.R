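# Shared synthetic panels for the tests. All are built in code; nothing is
# read from disk except fixtures the tests themselves write.

# Stationary country: constant rates and populations, exact deaths.
stationary_spec <- function(country = "SYN", years = 2009:2021) {
  scenario_spec(country = country, years = years,
                pop_growth = rep(1, 5), rate_decline = rep(1, 5),
                sigma = 0, shocks = NULL, deterministic = TRUE)
}

stationary_demography <- function(country = "SYN", years = 2009:2021) {
  simulate_country(stationary_spec(country, years))
}

# Stationary except a multiplicative rate shock in chosen years.
shock_demography <- function(shocks = list("2020" = 1.12), country = "SYN",
                             years = 2009:2021) {
  spec <- stationary_spec(country, years)
  spec$shocks <- lapply(shocks, function(s) if (length(s) == 1) rep(s, 5) else s)
  simulate_country(spec)
}

# Random but valid annual demography panel (uniform rates/populations),
# for loop-oracle comparisons.
random_panel <- function(seed, country = "RND", years = 2009:2021) {
  set.seed(seed)
  tidyr::expand_grid(country = country, year = years, band = age_bands()$band) |>
    dplyr::mutate(
      population = runif(dplyr::n(), 1e4, 1e6),
      rate = runif(dplyr::n(), 1e-4, 0.2),
      deaths = rate * population
    )
}

# Independent double-loop oracle for expected deaths: plain for-loops over
# years and bands, no vectorized arithmetic shared with the implementation.
oracle_expected <- function(panel, window, period) {
  bands <- unique(panel$band)
  total <- 0
  for (b in bands) {
    rates <- c()
    for (y in seq(window[1], window[2])) {
      row <- panel[panel$year == y & panel$band == b, ]
      rates <- c(rates, row$deaths / row$population)
    }
    mbar <- sum(rates) / length(rates)
    for (y in seq(period[1], period[2])) {
      row <- panel[panel$year == y & panel$band == b, ]
      total <- total + mbar * row$population
    }
  }
  total
}
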