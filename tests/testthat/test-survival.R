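test_that("Kaplan-Meier equals the empirical survival without censoring", {
  obs <- make_obs(183 + (1:10) * 100, rep("death", 10))
  km <- km_estimate(obs)
  steps <- km$surv[km$n_event > 0]
  expect_equal(steps, seq(0.9, 0, by = -0.1))

  set.seed(8)
  for (rep in 1:5) {
    exits <- 183 + sample(1:5000, 200, replace = TRUE)
    km <- km_estimate(make_obs(exits, rep("death", 200)))
    emp <- vapply(km$day, function(d) mean(exits > d), 0)
    expect_equal(km$surv, emp, tolerance = 1e-12)
  }
})

test_that("a fully censored cohort has survival identically one", {
  km <- km_estimate(make_obs(183 + (1:10) * 50, rep("censor", 10)))
  expect_true(all(km$surv == 1))
})

test_that("the five-animal worked example matches hand-computed product limits", {
  # deaths at 200, 300, 400; censorings at 250, 350:
  #   S(200) = 4/5, S(300) = 4/5 * 2/3, S(400) = 0
  obs <- make_obs(c(200, 250, 300, 350, 400),
                  c("death", "censor", "death", "censor", "death"))
  km <- km_estimate(obs)
  at_deaths <- km$surv[km$n_event > 0]
  expect_equal(at_deaths, c(4 / 5, 4 / 5 * 2 / 3, 0), tolerance = 1e-15)
  expect_equal(km$n_risk[km$n_event > 0], c(5L, 3L, 1L))
})

test_that("ties on a day are processed deaths before censorings", {
  obs <- make_obs(c(300, 300, 300, 500), c("death", "death", "censor", "censor"))
  km <- km_estimate(obs)
  row <- km[km$day == 300, ]
  expect_equal(row$surv, 1 - 2 / 4)  # both deaths see the full risk set
})

test_that("interval hazard is events over exposure days, counting event days", {
  # one bin [183, 1183): two animals die on day 682 (500 exposure days
  # each), one survives the bin (1000 days) -> 2 deaths / 2000 days
  obs <- make_obs(c(682, 682, 2000), c("death", "death", "censor"))
  hz <- interval_hazard(obs, bin_scheme("explicit_edges",
                                        edges = c(183, 1183, 2001)))
  expect_equal(hz$exposure[1], 500 + 500 + 1000)
  expect_equal(hz$hazard[1], 2 / 2000)
  expect_equal(hz$events[2], 0)
  expect_equal(hz$hazard[2], 0)
  expect_equal(hz$ci_low[2], 0)
})

test_that("per-bin exposures sum to total observation days", {
  set.seed(42)
  obs <- make_obs(183 + sample(0:6000, 300, replace = TRUE),
                  sample(c("death", "censor"), 300, replace = TRUE))
  for (edges in list(c(183, 400, 1000, 3000, 6200),
                     seq(183, 6433, by = 250))) {
    hz <- interval_hazard(obs, bin_scheme("explicit_edges", edges = edges))
    expect_equal(sum(hz$exposure), sum(obs$exit_day - obs$entry_day + 1))
  }
})

test_that("censorship hazard is the death hazard of the label-swapped data", {
  set.seed(9)
  obs <- make_obs(183 + sample(0:4000, 200, replace = TRUE),
                  sample(c("death", "censor"), 200, replace = TRUE))
  swapped <- obs
  swapped$event <- factor(ifelse(obs$event == "death", "censor", "death"),
                          levels = c("death", "censor"))
  sch <- bin_scheme("explicit_edges", edges = c(183, 1000, 2500, 4200))
  cens <- interval_hazard(obs, sch, event_of_interest = "censor")
  dead <- interval_hazard(swapped, sch, event_of_interest = "death")
  expect_equal(cens$hazard, dead$hazard)
  expect_equal(cens$ci_low, dead$ci_low)
  expect_equal(cens$exposure, dead$exposure)
})

test_that("interval hazard CIs cover a known constant hazard", {
  # replicate cohorts at 8e-5/day with coarse bins; the 95% Wilson CI
  # should cover the truth in at least 90% of bins
  lambda <- 8e-5
  set.seed(13)
  hits <- 0L; total <- 0L
  for (r in 1:30) {
    exits <- 183 + rgeom(2000, lambda)
    keep <- exits < 6000
    obs <- make_obs(pmin(exits, 6000),
                    ifelse(keep, "death", "censor"))
    hz <- interval_hazard(obs, bin_scheme("explicit_edges",
                                          edges = c(183, 2000, 4000, 6001)))
    covered <- hz$ci_low <= lambda & lambda <= hz$ci_high
    hits <- hits + sum(covered); total <- total + nrow(hz)
  }
  expect_gte(hits / total, 0.90)
})

test_that("Wilson continuity-corrected bounds match independent evaluation", {
  # frozen from a direct evaluation of Newcombe's closed forms
  ci <- wilson_interval(5, 100)
  expect_equal(ci$low, 0.01855256372171766, tolerance = 1e-12)
  expect_equal(ci$high, 0.1182994638690079, tolerance = 1e-12)
  ci2 <- wilson_interval(1, 10000)
  expect_equal(ci2$low, 5.220036653770449e-06, tolerance = 1e-9)
  expect_equal(ci2$high, 6.492406059425874e-04, tolerance = 1e-9)

  expect_equal(wilson_interval(0, 50)$low, 0)
  expect_equal(wilson_interval(50, 50)$high, 1)
  expect_error(wilson_interval(1, 0), "positive")
})

test_that("Wilson interval coverage sits in the nominal band for rare events", {
  set.seed(99)
  p <- 1e-4; n <- 10000
  x <- rbinom(1000, n, p)
  ci <- wilson_interval(x, n)
  coverage <- mean(ci$low <= p & p <= ci$high)
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.99)
})

test_that("adaptive binning keeps the fixed first window and fills by deaths", {
  set.seed(5)
  exits <- 183 + rgeom(3000, 1e-4)
  obs <- make_obs(pmin(exits, 9000), ifelse(exits < 9000, "death", "censor"))
  hz <- interval_hazard(obs, bin_scheme("adaptive", min_deaths = 40))
  expect_equal(hz$bin_start[1], 183)
  expect_equal(hz$bin_end[1], 400)
  interior <- hz$events[-c(1, nrow(hz))]
  expect_true(all(interior >= 40))
  # widths grow as the population thins
  widths <- hz$bin_end - hz$bin_start
  expect_gt(widths[nrow(hz) - 1], widths[2])
})

test_that("fixed-width schemes produce the partial leading window", {
  obs <- make_obs(c(300, 450, 700), c("death", "death", "death"))
  hz <- interval_hazard(obs, bin_scheme("fixed_width", width = 200,
                                        anchor = 200))
  expect_equal(hz$bin_start[1:2], c(183, 200))
  expect_equal(hz$bin_end[1], 200)
})

test_that("lifespan summaries recover closed-form percentiles", {
  lambda <- 1e-3
  grid <- tibble::tibble(day = 0:20000, surv = exp(-lambda * (0:20000)))
  s <- lifespan_summary(grid, t_sex = 0)
  expect_lt(abs(s$median_age - log(2) / lambda), 1)
  expect_lt(abs(s$max_age - log(20) / lambda), 1)
  expect_true(s$median_achieved && s$max_achieved)

  # a curve that never reaches the 95th percentile reports not-achieved
  short <- tibble::tibble(day = 0:100, surv = seq(1, 0.6, length.out = 101))
  s2 <- lifespan_summary(short, t_sex = 0)
  expect_false(s2$median_achieved)
  expect_true(is.na(s2$max_age))
})

test_that("uniform deaths give order-statistic percentiles", {
  obs <- make_obs(183 + (1:100) * 10, rep("death", 100))
  s <- lifespan_summary(km_estimate(obs), t_sex = 183)
  expect_equal(s$median_age, 183 + 50 * 10)
  expect_equal(s$max_age, 183 + 95 * 10)
})

test_that("the at-risk threshold day matches a brute-force scan", {
  obs <- make_obs(rep(500, 10), rep("death", 10))
  km <- km_estimate(obs)
  expect_equal(at_risk_threshold_day(km, 5), 500L)
  expect_true(is.na(at_risk_threshold_day(km, 0)))

  set.seed(3)
  exits <- 183 + sample(0:3000, 120, replace = TRUE)
  events <- sample(c("death", "censor"), 120, replace = TRUE)
  obs2 <- make_obs(exits, events)
  km2 <- km_estimate(obs2)
  thr <- 40
  # oracle: first day d with #({exit > d}) < threshold, scanning all days
  days <- sort(unique(exits))
  oracle <- days[which(vapply(days, function(d) sum(exits > d), 0) < thr)[1]]
  expect_equal(at_risk_threshold_day(km2, thr), oracle)
})
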