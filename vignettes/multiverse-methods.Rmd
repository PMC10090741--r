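---
title: "Multiverse excess-mortality estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiverse excess-mortality estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvexcess)
```

## The estimand and the multiverse

Excess mortality compares observed deaths D in a projected period with
the deaths E expected had past mortality conditions persisted. Both the
reference baseline (which past years define "past conditions") and the
projected period (one calendar year, or several) are free analytical
choices, and published estimates are notoriously sensitive to them.
Rather than defending one choice, `mvexcess` evaluates **all** of them
within a candidate range: every span of consecutive calendar years
$[a, b]$ with $\mathrm{first} \le a \le b \le \mathrm{last}$ is a
baseline window. An $n$-year candidate range yields $n(n+1)/2$ windows;
the default range 2009–2019 yields 66.

For window $w$ and band $b$, the baseline mortality is the unweighted
mean of the annual band rates over the window years,
$\bar m_b(w) = \frac{1}{|w|}\sum_{y \in w} m_{b,y}$, with
$m_{b,y} = D_{b,y} / N_{b,y}$. This is deliberately a mean of rates,
not pooled deaths over pooled population: each calendar year is one
equally weighted observation of "mortality conditions", so a large-population
year does not dominate the baseline. Expected deaths for projected
period $T$ apply those frozen rates to the period's actual populations,

$$E(w, T) = \sum_{y \in T} \sum_{b} \bar m_b(w)\, N_{b,y},$$

so demographic change (ageing, growth) is accounted for while mortality
conditions are held at baseline. The reported unit is the relative
excess (P-score) $p\% = 100\,(D - E)/E$, which is invariant to
population scale and therefore comparable across countries.

Two exclusion rules keep the counterfactual clean: pandemic years (2020
and 2021 in the default configuration) never serve as baselines, and a
projected year is never part of its own baseline — when 2019–2021 is
projected, windows containing 2019 are dropped (55 remain; 45 for
2018–2021). Exclusion is the job of `enumerate_windows(exclude = )`;
`run_multiverse()` treats an overlapping window as a hard error rather
than silently dropping it, so the rule lives in exactly one place.

No time-trend model (linear, spline, Lee–Carter) is superimposed on the
baseline. That is a deliberate assumption, not an omission: mortality
trends differ sharply across countries and there is no verifiable way
to pick the "right" anticipated trend. Short windows near the period
capture recent conditions; long or old windows embed a decade of
mortality improvement into the counterfactual. The spread across the 66
windows *is* the sensitivity analysis.

### One projected period vs. per-year estimates

For a multi-year period, $D$ and $E$ are summed before the ratio, which
makes the multi-year P-score the E-weighted mean of the constituent
single-year P-scores — it always lies between their minimum and
maximum (a tested invariant). This is why lengthening the projected
period attenuates one-year peaks: `attenuation_table()` quantifies the
drop from the worst single pandemic year to the 2-, 3- and 4-year
estimates. Strong attenuation is the signature of mortality
displacement (deaths of people with short remaining life expectancy);
persistence of the peak under a 4-year window indicates the opposite.

## Down-weighting older reference years

An equal-weights multiverse average lets 2009-only baselines count as
much as 2019-only ones. Three schemes discount older reference years,
anchored at the last pre-pandemic year (default 2019, parameterized so
the method extends to other eras):

| scheme | per-year weight $w(y)$ | 2018–2019 window | units |
|--------|------------------------|------------------|-------|
| `dw1`  | $\max(0,\, 1 - 0.10\,(A - y))$ | 0.95 | fraction |
| `dw2`  | $\max(0,\, 1 - 0.05\,(A - y))$ | 0.975 | fraction |
| `dw3`  | $0.5^{A-y}$ | 0.75 | fraction |

A window's weight is the arithmetic mean of its years' weights, and the
weighted multiverse average is $\sum_i w_i p_i / \sum_i w_i$, normalized
over the included windows. Under `dw1` the 2009-only window has weight
exactly 0 and contributes nothing; the normalization stays well defined
because other windows carry positive weight. The `dw2` formula is
clamped at zero beyond 20 years before the anchor so that weights stay
in $[0, 1]$ for any anchor; within the default 2009–2019 range the
clamp never binds. `dw3` decays fastest initially (2017 already at
0.25), which is why its weighted averages sit closest to
recent-baseline estimates.

## Ranking and its stability

Within each window, countries are ranked by P-score, rank 1 = highest
excess. `rank_distribution()` aggregates the 66 per-window rankings
into per-country average rank, rank SD and a rank-occurrence histogram;
a concentrated diagonal in the heat map (`autoplot()`) means the
*relative* standing of countries is robust to the baseline choice even
when absolute estimates are not. Ties are broken lexicographically by
country code and flagged (`tied`): on real data exact ties have
probability zero, but synthetic and degenerate inputs must rank
reproducibly. Output is ordered worst-first (ascending numeric average
rank). No concordance statistic is computed — the histogram is the
result.

## Data ingestion

Weekly STMF files are summed to annual band deaths using the file's own
year labels verbatim; no ISO re-dating is attempted, so 53-week years
contribute 53 weekly values. The `both` sex stratum is the default and
the analysis is not sex-stratified. Rows flagged as forecast are kept by
default (a `strict` mode drops them); rows whose band sum disagrees
with the rounded `DTotal` by more than 0.5 are reported, never silently
dropped. Fractional death counts are legal throughout (the source
splits deaths of unknown age proportionally).

Annual archive tables (`Deaths_1x1` / `Population` dialects, 1-year
ages, `110+` open-ended) are joined, validated (deaths without
population, negative values ⇒ errors) and collapsed onto the five
bands by summation. Where a population file carries two estimates at a
boundary year, the estimate labelled for 1 January of that year under
the current territorial definition is used by default (`boundary =
"plus"`), switchable.

`merge_sources()` splices the two death sources at a configurable
`switch_year` (default: the first year after archive coverage) and
records provenance per cell. Populations for years beyond the archive —
typically the pandemic years — are extrapolated per band, linearly from
the last two archive years by default, with carry-forward as the
alternative. Linear extrapolation is the least-surprising demographic
default over a 1–2 year horizon; it is an acknowledged source of
uncertainty, which is why the choice is explicit, logged in the output
(`population_source`), and replaceable by user-supplied populations in
the panel.

## The synthetic generator: what it emulates, what it does not

`scenario_spec()`/`simulate_country()` generate the study conditions
every test runs under: five-band populations with deterministic
exponential growth $N_{b,t} = N_{b,0} g_b^t$, rates
$m_{b,t} = m_{b,0} d_b^t s_{b,t} e^{\varepsilon}$ with
$\varepsilon \sim N(0, \sigma^2)$ and year-specific multiplicative
shocks $s$, and deaths either Poisson with mean $mN$ (integer,
realistically dispersed) or exactly $mN$ (for analytic oracles). The
defaults are a realistic mid-size high-income country: 10 M people
split (1.6, 6.6, 1.0, 0.55, 0.2) M across the bands, band mortality
(0.03%, 0.3%, 1.8%, 5%, 15%) per year declining 1.5% annually — the
typical pre-2020 improvement in such countries — ageing via faster
growth of the 65+ bands, $\sigma = 0.02$ (2% year-to-year rate noise),
and pandemic shocks +10% (2020) and +5% (2021), in the mid-range of
observed national peaks. Seeds fix every realization, and the generator
restores the caller's RNG state.

Two constructions make sharp oracles possible. A *stationary* scenario
($d = g = 1$, $\sigma = 0$, deterministic deaths, no shock) forces
$D = E$ under every window, hence $p = 0$ exactly. A stationary
scenario with a single multiplicative shock $s$ in the projected year
forces $p = 100(s-1)$ under every window to floating precision; with
Poisson deaths the same recovery holds within Monte-Carlo error
($\mathrm{sd}(p) \approx 100/\sqrt{\lambda}$, $\lambda$ = expected
total deaths). Passing these tests shows the arithmetic chain is
correct and unbiased under the generator's assumptions. It does *not*
validate the method against features of real mortality data the
generator omits: seasonality and within-year timing (annual resolution
only), correlated band shocks, flu/heat-wave years, migration-driven
population revisions, late registration, or territorial changes. The
ingestion layer is separately exercised on the exact file dialects, but
real-data idiosyncrasies beyond those dialects are out of scope.

`write_fixtures()` serializes any panel into the STMF and archive
dialects: annual deaths are split over 52/53 ISO weeks with random
proportions that conserve totals exactly (the last week absorbs the
floating remainder), and band values are spread uniformly over the
constituent single-year ages, so read → collapse → annualize
round-trips to the panel.

## Numerical choices and degenerate inputs

* **Quartiles.** `stats::quantile()` type 7 (linear interpolation), the
  R default, switchable via `quartile_type`; published IQR bands do not
  name a method, and on 66 points the difference between types is well
  below reporting precision.
* **SD.** Sample standard deviation ($n-1$) throughout, matching the
  cross-country dispersion statistics in the reference tables.
* **Single-window summaries.** `sd` is `NA` with `sd_defined = FALSE`,
  never 0.
* **Envelope policy.** For historical years, `yearly_envelope()`
  defaults to `all_66`: the projected year may sit inside its own
  baseline, matching the convention of showing each year against all 66
  reference sets. Because `run_multiverse()` treats overlap as an
  error by contract, the envelope passes `allow_overlap = TRUE`
  explicitly; `exclude_overlap` is available and the two policies are
  not asserted to agree. The same duality appears in `worst_periods()`
  (`exclude_scanned`, the default and the choice consistent with the
  pandemic-year rule, vs `all_windows`).
* **Ties.** Rank and worst-period ties fall back to country code /
  chronology and carry an explicit flag.
* **Degenerate inputs.** Empty estimate sets, all-zero weights,
  incomplete country × window grids, gap years between death sources,
  deaths without population, and $E \le 0$ all raise immediate errors
  naming the offending cells; nothing is silently imputed.

## Problem sizes

The shipped tests run on single- to five-country synthetic panels over
2009–2021 (65 band-year cells per country, the same shape as the real
application), the full 66-window multiverse per period, 50-panel
oracle sweeps for the expected-death computation, and the packaged
33-country reference tables; the whole suite completes in a few
minutes on one CPU. Real-data runs at 33 countries × 66 windows × 13
years are a few hundred thousand rate-products and take seconds.

## Known limitations

Annual resolution only (no weekly excess); no trend extrapolation by
design, so a country with a steep genuine mortality decline will show
negative excess under old baselines — that is information, not error;
populations for post-archive years rest on a stated extrapolation;
cross-country differences in death registration quality are not
modelled; and the reference tables ship printed-precision values, so
statistics recomputed from them can differ in the last digit from
unrounded originals.
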