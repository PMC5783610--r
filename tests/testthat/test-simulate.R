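test_that("simulation models must tile the window with valid probabilities", {
  bins <- tibble::tibble(stratum = "non_breeder", bin_start = 183L,
                         bin_end = 5000L, p_death = 1e-4, p_censor = 0)
  expect_error(simulation_model(bins), "tile")
  bins$p_death <- 2
  expect_error(simulation_model(dplyr::mutate(bins, bin_end = 12000L)),
               "\\[0, 1\\]")
  m <- default_simulation_model()
  expect_s3_class(m, "nmr_simmodel")
})

test_that("per-day outcome probabilities are conserved", {
  m <- default_simulation_model()
  p_stay <- (1 - m$p_censor) * (1 - m$p_death)
  p_censor <- m$p_censor
  p_death <- (1 - m$p_censor) * m$p_death
  expect_equal(p_stay + p_censor + p_death, rep(1, nrow(m)))
})

test_that("degenerate models force the prescribed outcomes", {
  m0 <- flat_model(p_death = 0, p_censor = 0)
  sim <- simulate_population(m0, 5, 2, seed = 1)
  expect_true(all(sim$exit_day == 12000L))
  expect_true(all(sim$event == "censor"))
  expect_equal(attr(sim, "termination"), "reached_end_day")

  m1 <- simulation_model(tibble::tibble(
    stratum = rep(c("non_breeder", "breeder"), each = 2),
    bin_start = rep(c(183L, 400L), 2), bin_end = rep(c(400L, 12000L), 2),
    p_death = c(1, 1e-4, 1, 1e-4), p_censor = 0))
  sim1 <- simulate_population(m1, 10, 0, seed = 1)
  expect_true(all(sim1$exit_day == 183L))
  expect_true(all(sim1$event == "death"))
  expect_equal(attr(sim1, "termination"), "exhausted")
})

test_that("identical seeds reproduce a simulation bit for bit", {
  m <- default_simulation_model()
  a <- simulate_population(m, 200, 20, seed = 77)
  b <- simulate_population(m, 200, 20, seed = 77)
  expect_identical(a$exit_day, b$exit_day)
  expect_identical(a$event, b$event)
  c <- simulate_population(m, 200, 20, seed = 78)
  expect_false(identical(a$exit_day, c$exit_day))
})

test_that("constant-hazard simulation hits the closed-form median", {
  m <- flat_model(p_death = 1e-4, p_censor = 0)
  sim <- simulate_population(m, 4000, 0, seed = 5)
  km <- km_estimate(as_observations(sim))
  target_day <- 183 + round(log(2) / 1e-4)
  se3 <- 3 * sqrt(0.25 / 4000)
  expect_lt(abs(km_survival_at(km, target_day) - 0.5), se3)
})

test_that("interval hazards recover the simulating probabilities", {
  m <- flat_model(p_death = 1e-4, p_censor = 2e-4, end_day = 9000L)
  edges <- c(183, 1500, 3000, 5000, 9000)
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    sim <- simulate_population(m, 3000, 0, seed = 100 + s)
    hz <- interval_hazard(as_observations(sim),
                          bin_scheme("explicit_edges", edges = edges))
    ok <- !hz$undefined
    hits <- hits + sum(hz$ci_low[ok] <= 1e-4 & 1e-4 <= hz$ci_high[ok])
    total <- total + sum(ok)
  }
  expect_gte(hits / total, 0.9)
})

test_that("ensembles are deterministic and ordered", {
  m <- flat_model(p_death = 2e-4, p_censor = 1e-4, end_day = 3000L)
  e1 <- simulate_ensemble(m, 150, 10, n_sims = 8, seed = 42, grid_by = 200)
  e2 <- simulate_ensemble(m, 150, 10, n_sims = 8, seed = 42, grid_by = 200)
  expect_identical(e1$median, e2$median)
  expect_true(all(e1$p5 <= e1$q1 & e1$q1 <= e1$median &
                    e1$median <= e1$q3 & e1$q3 <= e1$p95))
  expect_true(all(e1$n_included == 8))

  single <- simulate_ensemble(m, 100, 0, n_sims = 1, seed = 9, grid_by = 200)
  km <- km_estimate(as_observations(attr(single, "sims")[[1]]))
  expect_equal(single$median, km_survival_at(km, single$day))
  expect_equal(single$p5, single$p95)
})

test_that("the mixture experiment degenerates to plain ensembles", {
  m <- flat_model(p_death = c(3e-4, 3e-5), p_censor = 0, end_day = 2500L)
  mix0 <- mixture_experiment(m, 120, 0, n_sims = 5, seed = 4, grid_by = 250)
  plain <- simulate_ensemble(m, 120, 0, n_sims = 5, seed = 4, grid_by = 250)
  expect_identical(mix0$median, plain$median)
  mixall <- mixture_experiment(m, 120, 120, n_sims = 5, seed = 4,
                               grid_by = 250)
  allb <- simulate_ensemble(m, 0, 120, n_sims = 5, seed = 4, grid_by = 250)
  expect_identical(mixall$median, allb$median)
  expect_error(mixture_experiment(m, 10, 11, n_sims = 2, seed = 1), "exceed")
})

test_that("envelope coverage scores containment of an observed curve", {
  m <- flat_model(p_death = 2e-4, p_censor = 0, end_day = 3000L)
  env <- simulate_ensemble(m, 300, 0, n_sims = 20, seed = 31, grid_by = 250)
  # the envelope median viewed as an observed curve is fully contained
  med <- tibble::tibble(day = env$day, surv = env$median)
  expect_equal(envelope_coverage(med, env, env$day), 1.0)
  dead <- tibble::tibble(day = c(183, 400), surv = c(0, 0))
  expect_equal(envelope_coverage(dead, env, env$day[env$day > 400]), 0.0)
  expect_error(envelope_coverage(med, env, integer(0)), "non-empty")
})

test_that("independent censorship does not bias the ensemble median", {
  m_plain <- flat_model(p_death = 3e-4, p_censor = 0, end_day = 3000L)
  m_cens <- flat_model(p_death = 3e-4, p_censor = 4e-4, end_day = 3000L)
  e1 <- simulate_ensemble(m_plain, 400, 0, n_sims = 30, seed = 8,
                          grid_by = 500)
  e2 <- simulate_ensemble(m_cens, 400, 0, n_sims = 30, seed = 9,
                          grid_by = 500)
  # compare at day 1683 (S ~ 0.64); Monte-Carlo tolerance ~4 SE
  s1 <- e1$median[e1$day == 1683]
  s2 <- e2$median[e2$day == 1683]
  expect_lt(abs(s1 - s2), 4 * sqrt(0.64 * 0.36 / 400) / sqrt(30) * 5)
})

test_that("model assembly from hazard tables records provenance and gaps", {
  mk <- function(h, events = 50) tibble::tibble(
    bin_start = c(183, 400), bin_end = c(400, 12000),
    hazard = h, events = events)
  model <- build_simulation_model(
    death = list(non_breeder = list(female = mk(c(2e-4, 1e-4)),
                                    both = mk(c(3e-4, 1.5e-4))),
                 breeder = list(female = mk(c(1e-5, 1e-5), events = 2),
                                both = mk(c(2e-5, 2e-5)))),
    censor = list(non_breeder = mk(c(2e-4, 2e-4)),
                  breeder = mk(c(1e-4, 1e-4))))
  nb <- model[model$stratum == "non_breeder", ]
  br <- model[model$stratum == "breeder", ]
  expect_equal(nb$p_death, c(2e-4, 1e-4))       # female source kept
  expect_equal(unique(nb$source_death), "female")
  expect_equal(br$p_death, c(2e-5, 2e-5))       # low power -> combined sex
  expect_equal(unique(br$source_death), "both_sex")

  short <- tibble::tibble(bin_start = 183, bin_end = 5000, hazard = 1e-4,
                          events = 50)
  expect_error(build_simulation_model(
    death = list(non_breeder = short, breeder = short),
    censor = list(non_breeder = short, breeder = short)), "cover")
})
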