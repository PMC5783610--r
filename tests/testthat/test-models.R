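test_that("the Gompertz-Makeham hazard evaluates its closed form", {
  p <- gompertz_params(alpha = 2e-5, beta = 0, gamma = 3e-5)
  expect_equal(hazard_at(p, c(0, 100, 5000)), rep(5e-5, 3))

  # hazard doubling time ln(2)/beta: an 8-year doubling sits in the
  # human-like range
  beta <- log(2) / (8 * 365.25)
  p2 <- gompertz_params(alpha = 1e-5, beta = beta)
  expect_equal(hazard_at(p2, 8 * 365.25) / hazard_at(p2, 0), 2)
  expect_equal(hazard_at(p2, 0), 1e-5)

  expect_error(hazard_at(gompertz_params(1e-5, 1), 1e6), "overflow")
  expect_error(gompertz_params(-1, 0, 0), "non-negative")
})

test_that("constant-hazard survival matches a per-day product oracle", {
  expect_equal(constant_hazard_survival(0, 183, 5000), 1)
  expect_equal(constant_hazard_survival(1, 183, 184), 0)
  # brute force: iterative multiplication over 1000 days
  oracle <- prod(rep(1 - 8e-5, 1000))
  expect_equal(constant_hazard_survival(8e-5, 0, 1000), oracle,
               tolerance = 1e-12)
  expect_equal(constant_hazard_survival(8e-5, 0, 1000, form = "exponential"),
               exp(-8e-5 * 1000))
})

test_that("constant-hazard median lifespan is ln(2)/lambda", {
  expect_equal(constant_hazard_median(log(2)), 1)
  expect_equal(constant_hazard_median(1e-4) * 2,
               constant_hazard_median(5e-5))
  expect_equal(constant_hazard_median(0), Inf)
  # the geometric variant differs by less than a day at small hazards
  expect_lt(abs(constant_hazard_median(1e-4, "geometric") -
                  constant_hazard_median(1e-4)), 1)
})

test_that("the constant-model MLE equals deaths over exposure days", {
  set.seed(17)
  exits <- 183 + rgeom(2000, 1e-4)
  cens <- exits > 8000
  obs <- make_obs(pmin(exits, 8000), ifelse(cens, "censor", "death"))
  fit <- fit_mortality_model(obs, "constant")
  d_over_e <- sum(obs$event == "death") / sum(obs$exit_day - obs$entry_day + 1)
  expect_equal(tidy(fit)$estimate, d_over_e, tolerance = 1e-10)
  # and lies inside the Wilson interval of the same ratio
  ci <- wilson_interval(sum(obs$event == "death"),
                        sum(obs$exit_day - obs$entry_day + 1))
  expect_true(ci$low <= tidy(fit)$estimate && tidy(fit)$estimate <= ci$high)
  expect_true(glance(fit)$converged)
})

test_that("Gompertz fitting recovers the rate of aging", {
  set.seed(11)
  t <- rgompertz_makeham(2000, alpha = 1e-5, beta = 0.005)
  obs <- make_obs(183 + floor(pmin(t, 11817)),
                  ifelse(t <= 11817, "death", "censor"))
  fit <- fit_mortality_model(obs, "gompertz")
  beta_hat <- tidy(fit)$estimate[tidy(fit)$term == "beta"]
  expect_lt(abs(beta_hat - 0.005) / 0.005, 0.3)
})

test_that("log-likelihood is non-decreasing across nested mortality models", {
  set.seed(23)
  for (r in 1:5) {
    exits <- 183 + sample(1:6000, 400, replace = TRUE)
    obs <- make_obs(exits, sample(c("death", "censor"), 400, replace = TRUE,
                                  prob = c(0.4, 0.6)))
    fc <- fit_mortality_model(obs, "constant")
    fg <- fit_mortality_model(obs, "gompertz")
    fgm <- fit_mortality_model(obs, "gompertz_makeham")
    expect_gte(fg$loglik, fc$loglik - 1e-6)
    expect_gte(fgm$loglik, fc$loglik - 1e-6)
    expect_gte(mortality_lrt(fc, fgm)$statistic, -1e-6)
  }
})

test_that("fitting requires at least one death", {
  obs <- make_obs(c(1000, 2000), c("censor", "censor"))
  expect_error(fit_mortality_model(obs, "constant"), "zero death")
})

test_that("life tables pool deaths and at-risk counts across sources", {
  t1 <- tibble::tibble(age_start = 0, age_end = 1, deaths = 5, at_risk = 100)
  expect_equal(life_table_hazard(t1)$hazard, 0.05)
  t2 <- tibble::tibble(age_start = 0, age_end = 1, deaths = 10, at_risk = 100)
  pooled <- life_table_hazard(list(t1, t2))
  expect_equal(pooled$hazard, 15 / 200)
  t3 <- tibble::tibble(age_start = 1, age_end = 2, deaths = 1, at_risk = 10)
  expect_error(life_table_hazard(list(t1, t3)), "do not match")
})

test_that("life-table survival is the cumulative product of interval survival", {
  lt <- life_table_hazard(tibble::tibble(
    age_start = 0:19, age_end = 1:20, hazard = rep(0.1, 20)))
  sv <- survival_from_life_table(lt, t_sex = 0)
  expect_equal(sv$surv, c(1, 0.9^(1:20)))

  lt2 <- life_table_hazard(tibble::tibble(
    age_start = 0:4, age_end = 1:5, hazard = c(0.2, 1, 0.1, 0.1, 0.1)))
  sv2 <- survival_from_life_table(lt2, t_sex = 0)
  expect_true(all(sv2$surv[3:6] == 0))

  s <- lifespan_summary(sv, t_sex = 0)
  expect_equal(s$median_age, 7)   # 0.9^7 = 0.478 first <= 0.5
  expect_false(lifespan_summary(survival_from_life_table(lt, 15),
                                t_sex = 15)$max_achieved)
})

test_that("a day-resolution life table from interval hazards reproduces KM", {
  set.seed(31)
  exits <- 183 + sample(1:60, 40, replace = TRUE)
  obs <- make_obs(exits, rep("death", 40))
  km <- km_estimate(obs)
  hz <- interval_hazard(obs, bin_scheme("explicit_edges",
                                        edges = 183:(max(exits) + 1)))
  lt <- life_table_hazard(tibble::tibble(
    age_start = hz$bin_start, age_end = hz$bin_end,
    deaths = hz$events, at_risk = hz$n_start), unit = "day")
  sv <- survival_from_life_table(lt, t_sex = 183)
  expect_equal(km_survival_at(km, sv$age - 1), sv$surv, tolerance = 1e-12)
})

test_that("annual hazards convert to daily by compounding", {
  q <- 0.3
  h <- annual_to_daily_hazard(q)
  expect_equal((1 - h)^365.25, 1 - q, tolerance = 1e-12)
  expect_equal(annual_to_daily_hazard(0.6, "simple"), 0.6 / 365.25)
})

test_that("maturity rescaling divides ages and leaves hazards untouched", {
  hz <- tibble::tibble(bin_start = c(183, 4575), bin_end = c(400, 4775),
                       hazard = c(2e-4, 5e-5))
  r <- rescale_by_tsex(hz, t_sex = 183)
  expect_equal(r$bin_start[2], 25)
  expect_equal(r$hazard, hz$hazard)
  expect_equal(rescale_by_tsex(tibble::tibble(day = 840, hazard = 1e-3),
                               t_sex = 42)$day, 20)
  expect_equal(rescale_by_tsex(hz, t_sex = 1)$bin_start, hz$bin_start)
})
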