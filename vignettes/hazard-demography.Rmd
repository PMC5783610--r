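---
title: "Estimating age-specific mortality from censored colony records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating age-specific mortality from censored colony records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(lifehaz)
library(dplyr)
```

## The question this package operationalises

Most mammals age demographically: after reproductive maturity their
per-day risk of death grows exponentially, following the Gompertz-Makeham
law

$$h(t) = \alpha e^{\beta t} + \gamma,$$

where $\alpha$ scales the intrinsic (aging) hazard, $\beta$ is the rate of
aging — $\ln(2)/\beta$ is the hazard doubling time, about 7–8.5 years in
humans — and $\gamma$ is a constant extrinsic hazard that can mask the
Gompertzian term early in life. For an exceptionally long-lived eusocial
rodent such as the naked mole-rat, multi-decade colony records make it
possible to ask whether the hazard rises at all. If it does not, the
population follows an exponential-decay (constant-hazard) law, the notion
of a "maximal lifespan" loses its usual meaning, and the meaningful summary
becomes a demographic half-life $\ln(2)/\lambda$: at $\lambda = 10^{-4}$
per day that is `r round(log(2)/1e-4)` days, roughly 19 years.

`lifehaz` implements the full chain needed to pose that question to colony
spreadsheets: record parsing with a deterministic date-imputation
hierarchy, Kaplan-Meier survival, exposure-day hazard estimation with
continuity-corrected Wilson intervals, censoring-aware maximum-likelihood
model fits, a day-by-day cohort simulator, and cross-species life-table
comparison on a maturity-rescaled age axis.

## The analysis clock and censorship rules

All analyses run on a post-maturity clock. Day-of-life is counted 0-based
from the birth date; animals enter observation at `start_day` (183 days by
default, the species' age of reproductive maturity), and any death or
censorship strictly before that day is excluded and logged — identifiers
are only assigned some weeks after birth, so pre-maturity demography is
incompletely observed and is not estimated. An event on day 183 itself is
kept.

Censorship is applied in three situations: transfer out of the collection
(`SOLD/GIVEN AWAY`), sacrifice of a healthy animal for research (`KFR`),
and being alive when a spreadsheet was compiled, in which case the end
date is the spreadsheet's compile date. A row labelled both dead and KFR
is treated as a KFR censorship and logged as a conflict, since the KFR
label marks the death as an experimental endpoint rather than an observed
mortality event.

## Multi-resolution dates and stringency tiers

Colony records accumulate over decades and many dates survive only at
month, season, year, range or inequality resolution. Rather than discard
or silently guess, the package resolves them deterministically:

| recorded as            | resolves to                              |
|------------------------|------------------------------------------|
| `1995-06` / `June 1995`| the 15th of the month                    |
| `1997` (or `~1997`)    | July 2 of that year                      |
| `Fall 1999`            | November 7 (Winter: Feb 5, Spring: May 6, Summer: Aug 6) |
| `A to B`               | middle date of the span                  |
| `A or B`               | midpoint of the two options              |
| `>1997`                | January 1, 1998 (nearest satisfying date) |

The seasonal midpoints are the astronomical-season midpoints, chosen to be
internally consistent with the Fall convention. Approximate markers (`~`)
are treated as the exact form. July 2 is used in leap years too; the
one-day distinction is far below the resolution of a year-only record.

Records are admitted in four nested *stringency tiers* — `day`, `month`,
`low` (season/year/range/two-option), `inequality` — so an analysis can be
repeated with increasingly permissive data and checked for stability.
Inequality-derived dates are the worst case (unbounded on one side); they
are resolved to the nearest satisfying date and should only ever be used
as a sensitivity bound.

```{r}
resolve_date(c("June 1995", "1997", "Fall 1999", ">1997"), tier = "inequality")
```

## Hazard estimation from exposure days

For each half-open age bin $[s, e)$, the per-day hazard estimate is the
number of events in the bin divided by the animal-days of observation in
it. An animal alive across the bin contributes $e - s$ days; an animal
whose death or censorship falls inside contributes the days up to *and
including* the event day. Counting the event day keeps the estimator
consistent with the likelihood convention below. Confidence intervals are
continuity-corrected Wilson score intervals on events/exposure-days; for
rare events (death probabilities near $10^{-4}$/day against 10^5^–10^6^
exposure days) the Wilson form is well behaved where a Wald interval would
collapse to zero width.

Three binning schemes are provided. `fixed_width` lays regular windows
(with a partial leading window when the anchor exceeds the entry day, e.g.
200-day windows from day 200 with a `[183, 200)` stub). `explicit_edges`
reproduces any externally specified binning. `adaptive` starts with the
fixed early-life bin `[183, 400)` — kept separate because juvenile
mortality is visibly elevated before day 400 — and thereafter closes a bin
once it holds 30 deaths (configurable), widening the windows as the
population thins so that the confidence intervals stay roughly even. The
same machinery estimates *censorship* probabilities by reversing the roles
of death and censoring (`event_of_interest = "censor"`).

```{r}
coll <- generate_collection(synth_config(n_colonies = 12, seed = 7))
obs <- parse_collection(coll$records) |> build_observations(tier = "day")
interval_hazard(obs, bin_scheme("adaptive", min_deaths = 30)) |> head(4)
```

## Model fitting and comparison

`fit_mortality_model()` maximises the right-censored likelihood of the
constant, Gompertz ($\gamma = 0$) or full Gompertz-Makeham hazard on the
post-entry clock, using the continuous survival function
$S(t) = \exp(-\gamma t - \frac{\alpha}{\beta}(e^{\beta t} - 1))$.
Durations count the event day, so the constant model's closed-form MLE is
exactly deaths/exposure-days — the same number the interval estimator
reports for a single all-covering bin. Because the constant model is
nested in both richer ones, `mortality_lrt()` gives a likelihood-ratio
test of "does hazard increase with age" ($\chi^2_1$ for constant vs
Gompertz). Optimisation runs Nelder-Mead from several starts including a
near-degenerate constant-hazard start, which guarantees the fitted
log-likelihood never falls below the constant model's; a fitted $|\beta|$
below $10^{-8}$/day is flagged as numerically zero. $\alpha$ and $\gamma$
are kept positive by log-parameterisation; $\beta$ is unconstrained, so a
genuinely declining hazard shows up as $\beta < 0$ rather than being
forced to zero.

```{r}
fc <- fit_mortality_model(obs, "constant")
fg <- fit_mortality_model(obs, "gompertz")
glance(fc); tidy(fg)
mortality_lrt(fc, fg)
```

## The cohort simulator

The simulator reproduces the observed-data generating process literally:
for each day from day 183, each surviving and uncensored individual first
draws against that day's censorship probability for its stratum, then —
only if not censored — against the death probability; survivors at day
12,000 are censored there. Draws are made in stable ID order (censorship
draws for all alive individuals, then death draws for the survivors), so
a seed reproduces a simulation bit for bit; ensembles spawn one child
seed per simulation from the master seed.

The default model (`default_simulation_model()`) encodes the package's
reference scenario: non-breeder mortality $10^{-4}$/day, breeder mortality
$10^{-5}$/day (breeders enjoy roughly tenfold lower mortality), an
elevated early-life bin `[183, 400)` at $2\times10^{-4}$/day, and a
censorship schedule with a baseline rate, a strong pulse over days
`[2250, 2500)` — the age at which a large birth-year cohort collectively
reaches the record-compilation date — and a raised ongoing rate
afterwards. These are package defaults for a plausible captive colony,
not estimates from any particular dataset, and every value can be
overridden or rebuilt from estimated hazard tables with
`build_simulation_model()`, which records per-bin provenance (female-only
vs combined-sex source, preferring female estimates except where they
rest on fewer events than a configurable threshold, because female breeder
labels are reliable while male ones are not).

Ensembles are summarised as envelopes (median, quartiles, 5th/95th
percentiles of simulated survival every 50 days). Populations that reach
0% survival keep contributing zeros; a switch excludes
censorship-exhausted populations instead, since the two conventions
genuinely differ late in the curve, and `n_included` reports how many
simulations inform each day. `envelope_coverage()` scores how much of an
observed Kaplan-Meier curve lies inside the 5th–95th band, and
`mixture_experiment()` runs the hidden-breeder scenario: a cohort reported
as uniformly non-breeding but containing a chosen number of individuals
that actually follow the breeder schedule.

## The synthetic-data generator

`generate_collection()` exists so that every pipeline stage can be tested
against known ground truth. It emulates the statistical structure the
analysis assumes: eusocial colonies (one queen, 1–3 breeding males, ~60
animals per colony), stratum-specific constant (optionally Gompertz)
hazards with the elevated `[183, 400)` bin, per-day censorship plus
compile-date truncation, birth years 1981–2015 with a pulse year (2010,
20% of births) that *produces* the censorship pulse naturally once the
compile dates truncate that cohort, breeding-male mislabelling (default
68%, i.e. roughly two of every three breeding males recorded as
non-breeders), and planted defects: missing births (6%), dead-with-unknown
date rows, one-per-few-thousand garbled rows, and date degradation to
month/low/inequality resolution in proportions matching a realistic mix
(1.6% / 3.6% / 1.8%). Ground truth is written as a sidecar CSV under
`ground_truth/`, kept out of the analysis path by directory convention.

What the generator does *not* emulate: colony genealogy and queen
succession (individuals are independent given their stratum — exactly the
independence the simulator assumes), multi-institution record quirks, and
any correlation between data quality and mortality. Passing closed-loop
tests therefore demonstrates estimator correctness under the model's own
assumptions, not robustness to structure the model excludes.

## Cross-species comparison

`life_table_hazard()` ingests published life tables (deaths and at-risk
counts per age interval, or precomputed hazards), pooling multiple tables
by summing numerators and denominators when intervals align.
`survival_from_life_table()` rebuilds survival from maturity by iterative
multiplication of one minus the age-specific hazard, and
`lifespan_summary()` reports the median and the operational "maximal"
lifespan (the 95th percentile of post-maturity lifespans), flagging
percentiles a table never reaches rather than extrapolating. For species
comparison, `rescale_by_tsex()` divides the age axis by each species' age
of reproductive maturity (183 days for the naked mole-rat, 42 days for
mice, 3 years for horses, 16 years for human females) and leaves hazards
untouched, so a bin at day 4575 sits at 25 maturity-multiples. Annual
hazards convert to per-day by compounding, $(1-q) = (1-h)^{365.25}$, with
simple division available for comparison.

## Numerical choices and problem sizes

Tolerances and conventions that matter:

* Bins are half-open `[start, end)`; the event day contributes one
  exposure day to the bin containing it.
* Ties on a day are processed deaths-before-censorings (standard
  product-limit convention, via the survival package).
* Wilson intervals are clipped to `[0, 1]`, with exact endpoints at 0
  successes (lower bound 0) and all-successes (upper bound 1).
* Per-day geometric and continuous-exponential forms of constant-hazard
  survival differ by $O(\lambda)$ per day; the geometric form is the
  default because the simulator is a per-day Bernoulli process.
* Gompertz likelihood evaluations guard $\beta t > 500$ against overflow
  and reject negative $\alpha, \gamma$ outright.

The test suite and the acceptance script size their simulations to run on
a single CPU in a few minutes while keeping Monte-Carlo error well inside
the asserted tolerances: closed-form checks use cohorts of 4,000–10,000;
coverage properties use 30–100 replicate cohorts of 1,500–3,000; the
likelihood-ratio discrimination study uses 100 cohorts of 2,000 per
scenario; ensemble experiments use 100 simulations of 1,747 individuals,
matching the reference mixture scenario (175 hidden breeders among 1,747).

## Known limitations

* No left-truncation beyond the common entry day, no Cox regression, no
  smoothed hazard estimators: the package estimates piecewise-constant
  hazards and parametric laws only.
* Late-life mortality deceleration is deliberately out of scope; with
  heavy late-life censorship the confidence intervals there are wide, and
  inequality-tier records — the only ones that could suggest a hazard
  drop — carry the weakest date information.
* The hidden-breeder analysis is a forward simulation experiment, not an
  estimator of the number of unlabelled breeders; no fitting criterion is
  defined for it.
* Calendar-time effects (husbandry changes across decades) are not
  modelled; age is the only clock.
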