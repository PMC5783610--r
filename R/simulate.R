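# Per-day stochastic cohort simulation under age-binned death and
# censorship probabilities, with breeder/non-breeder strata and
# simulation-ensemble survival envelopes.

.strata <- c("non_breeder", "breeder")

#' Construct an age-binned simulation model
#'
#' A simulation model assigns, per stratum (`non_breeder`, `breeder`) and
#' per contiguous half-open age bin `[start_day, end_day)`, a per-day
#' probability of censorship and a per-day probability of death.  Each bin
#' carries a provenance tag recording which source population its value
#' was estimated from.
#'
#' @param bins A data frame with columns `stratum`, `bin_start`, `bin_end`,
#'   `p_death`, `p_censor` and optionally `source_death`, `source_censor`.
#' @param start_day,end_day Global simulation window (defaults 183 and
#'   12000).  Each stratum's bins must tile `[start_day, end_day)` exactly.
#' @return A tibble of class `nmr_simmodel`.
#' @seealso [default_simulation_model()], [build_simulation_model()]
#' @export
simulation_model <- function(bins, start_day = 183L, end_day = 12000L) {
  bins <- as_tibble(bins)
  req <- c("stratum", "bin_start", "bin_end", "p_death", "p_censor")
  if (!all(req %in% names(bins)))
    abort(paste("simulation model bins need columns:",
                paste(req, collapse = ", ")))
  if (!all(bins$stratum %in% .strata))
    abort("stratum must be 'non_breeder' or 'breeder'")
  if (any(bins$p_death < 0 | bins$p_death > 1 |
          bins$p_censor < 0 | bins$p_censor > 1))
    abort("per-day probabilities must lie in [0, 1]")
  for (s in unique(bins$stratum)) {
    b <- bins[bins$stratum == s, ]
    b <- b[order(b$bin_start), ]
    gaps <- !(b$bin_start[1] == start_day &&
                b$bin_end[nrow(b)] == end_day &&
                all(b$bin_end[-nrow(b)] == b$bin_start[-1]))
    if (gaps)
      abort(paste0("bins for stratum '", s, "' must tile [", start_day,
                   ", ", end_day, ") contiguously"))
  }
  if (!"source_death" %in% names(bins)) bins$source_death <- "unspecified"
  if (!"source_censor" %in% names(bins)) bins$source_censor <- "unspecified"
  bins <- bins[order(bins$stratum, bins$bin_start), ]
  class(bins) <- c("nmr_simmodel", class(bins))
  attr(bins, "start_day") <- as.integer(start_day)
  attr(bins, "end_day") <- as.integer(end_day)
  bins
}

#' Default colony simulation model
#'
#' A constant-with-age mortality model with the package's default rates:
#' non-breeder death 1e-4/day, breeder death 1e-5/day, an elevated
#' early-life bin `[183, 400)` at 2e-4/day for non-breeders, and a
#' censorship schedule with a baseline rate, a high-censorship pulse over
#' days `[2250, 2500)` (mimicking a cohort-entry pulse reaching the record
#' compilation date together) and a raised post-pulse rate.  These defaults
#' are package choices for a plausible captive colony; every value can be
#' overridden via [simulation_model()].
#'
#' @param end_day Simulation horizon (default 12000).
#' @return An `nmr_simmodel` tibble.
#' @export
default_simulation_model <- function(end_day = 12000L) {
  nb <- tibble(
    stratum = "non_breeder",
    bin_start = c(183L, 400L, 2250L, 2500L),
    bin_end = c(400L, 2250L, 2500L, end_day),
    p_death = c(2e-4, 1e-4, 1e-4, 1e-4),
    p_censor = c(2e-4, 2e-4, 2e-3, 3e-4)
  )
  br <- tibble(
    stratum = "breeder",
    bin_start = c(183L, 2250L, 2500L),
    bin_end = c(2250L, 2500L, end_day),
    p_death = c(1e-5, 1e-5, 1e-5),
    p_censor = c(1e-4, 1e-3, 1.5e-4)
  )
  simulation_model(dplyr::bind_rows(nb, br), end_day = end_day)
}

#' Assemble a simulation model from estimated hazard tables
#'
#' Builds the per-stratum, per-bin death and censorship probabilities from
#' interval hazard estimates (see [interval_hazard()]), recording the
#' source population of every value.  For each field a female-only
#' estimate is preferred; bins whose female estimate rests on fewer than
#' `min_events` events fall back to the combined-sex estimate when one is
#' supplied, so that low-power bins borrow strength without letting
#' male-labelling artefacts into the model.
#'
#' @param death,censor Named lists with elements `non_breeder` and
#'   `breeder`; each element is either a hazard table or a list with
#'   entries `female` and (optionally) `both` hazard tables sharing the
#'   same bin edges.
#' @param start_day,end_day Simulation window; the supplied bins must
#'   cover it contiguously or the gaps are reported as a fatal error.
#' @param min_events Minimum events for a female-only estimate to be used
#'   as-is (default 10).
#' @return An `nmr_simmodel` tibble with provenance columns
#'   `source_death` and `source_censor` (`"female"` or `"both_sex"`).
#' @export
build_simulation_model <- function(death, censor, start_day = 183L,
                                   end_day = 12000L, min_events = 10L) {
  pick <- function(entry, field) {
    if (is.data.frame(entry)) {
      tibble(bin_start = entry$bin_start, bin_end = entry$bin_end,
             p = entry$hazard, src = "unspecified")
    } else {
      fem <- entry$female
      both <- entry$both
      if (is.null(fem)) abort("each stratum entry needs at least a female (or single) hazard table")
      p <- fem$hazard
      src <- rep("female", nrow(fem))
      if (!is.null(both)) {
        if (!identical(as.integer(fem$bin_start), as.integer(both$bin_start)))
          abort("female and combined-sex tables must share bin edges")
        weak <- fem$events < min_events
        p[weak] <- both$hazard[weak]
        src[weak] <- "both_sex"
      }
      tibble(bin_start = fem$bin_start, bin_end = fem$bin_end, p = p,
             src = src)
    }
  }
  rows <- lapply(.strata, function(s) {
    d <- pick(death[[s]], "death")
    cns <- pick(censor[[s]], "censor")
    if (!identical(as.integer(d$bin_start), as.integer(cns$bin_start)))
      abort("death and censorship tables must share bin edges within a stratum")
    covered <- d$bin_start[1] <= start_day &&
      d$bin_end[nrow(d)] >= end_day
    if (!covered) {
      abort(paste0("hazard tables for stratum '", s, "' do not cover [",
                   start_day, ", ", end_day, "): have [", d$bin_start[1],
                   ", ", d$bin_end[nrow(d)], ")"))
    }
    tibble(stratum = s,
           bin_start = pmax(d$bin_start, start_day),
           bin_end = pmin(d$bin_end, end_day),
           p_death = d$p, p_censor = cns$p,
           source_death = d$src, source_censor = cns$src)
  })
  bins <- dplyr::bind_rows(rows)
  bins <- bins[bins$bin_end > bins$bin_start, ]
  if (anyNA(bins$p_death) || anyNA(bins$p_censor))
    abort("hazard tables contain undefined (zero-exposure) bins inside the simulation window")
  simulation_model(bins, start_day = start_day, end_day = end_day)
}

# expand a model stratum into per-day probability vectors over
# [start_day, end_day)
.daily_probs <- function(model, stratum) {
  b <- model[model$stratum == stratum, ]
  list(p_death = rep(b$p_death, b$bin_end - b$bin_start),
       p_censor = rep(b$p_censor, b$bin_end - b$bin_start))
}

#' Simulate one cohort day by day
#'
#' For every day from the model's start day, and for every individual
#' still alive and uncensored, a uniform draw is compared with that day's
#' censorship probability for the individual's stratum; if below, the
#' individual is censored that day.  Otherwise a second draw is compared
#' with the death probability, and the individual dies that day if below.
#' Individuals surviving to the model's end day are censored there.
#' Within a day, censorship draws are made for all alive individuals in
#' stable ID order (non-breeders first), then death draws for those not
#' censored, so a given seed reproduces the simulation exactly.
#'
#' @param model An `nmr_simmodel`.
#' @param n_nonbreeders,n_breeders Cohort composition at entry.
#' @param seed Optional integer seed.
#' @return A tibble of class `nmr_sim` with columns `id`, `stratum`,
#'   `exit_day`, `event`; attributes `termination` (`"exhausted"` if the
#'   population emptied before the end day, else `"reached_end_day"`),
#'   `start_day`, `end_day`, `seed`.
#' @examples
#' m <- default_simulation_model(end_day = 1000L)
#' sim <- simulate_population(m, n_nonbreeders = 50, n_breeders = 5, seed = 1)
#' table(sim$event)
#' @export
simulate_population <- function(model, n_nonbreeders, n_breeders,
                                seed = NULL) {
  if (n_nonbreeders < 0 || n_breeders < 0) abort("counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  start_day <- attr(model, "start_day")
  end_day <- attr(model, "end_day")
  n <- n_nonbreeders + n_breeders

  stratum <- rep(c(1L, 2L), c(n_nonbreeders, n_breeders))
  id <- c(sprintf("N%05d", seq_len(n_nonbreeders)),
          sprintf("B%05d", seq_len(n_breeders)))
  pn <- .daily_probs(model, "non_breeder")
  pb <- .daily_probs(model, "breeder")
  pc_by <- list(pn$p_censor, pb$p_censor)
  pd_by <- list(pn$p_death, pb$p_death)

  exit_day <- integer(n)
  event <- character(n)
  alive <- seq_len(n)

  n_days <- end_day - start_day
  for (k in seq_len(n_days)) {
    if (length(alive) == 0L) break
    day <- start_day + k - 1L
    strat <- stratum[alive]
    pc <- c(pc_by[[1]][k], pc_by[[2]][k])[strat]
    u1 <- runif(length(alive))
    cens <- u1 < pc
    if (any(cens)) {
      idx <- alive[cens]
      exit_day[idx] <- day
      event[idx] <- "censor"
    }
    rest <- alive[!cens]
    if (length(rest) > 0L) {
      pd <- c(pd_by[[1]][k], pd_by[[2]][k])[stratum[rest]]
      u2 <- runif(length(rest))
      died <- u2 < pd
      if (any(died)) {
        idx <- rest[died]
        exit_day[idx] <- day
        event[idx] <- "death"
      }
      alive <- rest[!died]
    } else {
      alive <- rest
    }
  }
  if (length(alive) > 0L) {
    exit_day[alive] <- end_day
    event[alive] <- "censor"
    termination <- "reached_end_day"
  } else {
    termination <- "exhausted"
  }

  out <- tibble(
    id = id,
    stratum = .strata[stratum],
    exit_day = exit_day,
    event = factor(event, levels = c("death", "censor"))
  )
  class(out) <- c("nmr_sim", class(out))
  attr(out, "termination") <- termination
  attr(out, "start_day") <- start_day
  attr(out, "end_day") <- end_day
  attr(out, "seed") <- seed
  out
}

#' Convert a simulated cohort to analysis-ready observations
#'
#' @param sim An `nmr_sim` tibble.
#' @return An `nmr_observations`-compatible tibble (`animal_id`,
#'   `entry_day`, `exit_day`, `event`, `breeder`), usable by
#'   [km_estimate()], [interval_hazard()] and [fit_mortality_model()].
#' @export
as_observations <- function(sim) {
  obs <- tibble(
    animal_id = sim$id,
    entry_day = attr(sim, "start_day"),
    exit_day = sim$exit_day,
    event = sim$event,
    sex = NA_character_,
    breeder = sim$stratum == "breeder",
    tier = "day"
  )
  class(obs) <- c("nmr_observations", class(obs))
  attr(obs, "start_day") <- attr(sim, "start_day")
  obs
}

#' Simulate an ensemble of cohorts and summarise its survival envelope
#'
#' Runs `n_sims` independent simulations (child seeds spawned
#' deterministically from the master seed) and evaluates each cohort's
#' Kaplan-Meier survival on a regular day grid.  The envelope reports the
#' median, quartiles and 5th/95th percentiles of simulated survival at
#' every grid day.  By default every simulation contributes at every day
#' (a population that died out contributes survival 0); with
#' `include_terminated = FALSE`, simulations whose population was
#' exhausted purely by censorship before a given day are excluded there,
#' and `n_included` records how many simulations inform each day.
#'
#' @param model An `nmr_simmodel`.
#' @param n_nonbreeders,n_breeders Cohort composition.
#' @param n_sims Number of simulations (default 100).
#' @param seed Master seed.
#' @param grid_by Evaluation-grid spacing in days (default 50).
#' @param include_terminated Include censorship-exhausted populations at
#'   all days (default `TRUE`).
#' @return A tibble of class `nmr_envelope`: `day`, `p5`, `q1`, `median`,
#'   `q3`, `p95`, `n_included`; the per-simulation results are attached as
#'   attribute `"sims"` (list of `nmr_sim` tibbles).
#' @export
simulate_ensemble <- function(model, n_nonbreeders, n_breeders,
                              n_sims = 100L, seed = NULL, grid_by = 50L,
                              include_terminated = TRUE) {
  if (n_sims < 1L) abort("n_sims must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_sims)
  start_day <- attr(model, "start_day")
  end_day <- attr(model, "end_day")
  grid <- seq(start_day, end_day, by = grid_by)

  sims <- vector("list", n_sims)
  surv <- matrix(NA_real_, nrow = n_sims, ncol = length(grid))
  exhausted_by_censor_at <- rep(Inf, n_sims)
  for (i in seq_len(n_sims)) {
    sim <- simulate_population(model, n_nonbreeders, n_breeders,
                               seed = child_seeds[i])
    sims[[i]] <- sim
    km <- km_estimate(as_observations(sim))
    surv[i, ] <- km_survival_at(km, grid)
    if (attr(sim, "termination") == "exhausted" &&
        km$surv[nrow(km)] > 0) {
      exhausted_by_censor_at[i] <- max(sim$exit_day)
    }
  }

  rows <- lapply(seq_along(grid), function(j) {
    vals <- surv[, j]
    keep <- rep(TRUE, n_sims)
    if (!include_terminated)
      keep <- grid[j] <= exhausted_by_censor_at
    vals <- vals[keep]
    qs <- quantile(vals, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    tibble(day = grid[j], p5 = qs[1], q1 = qs[2], median = qs[3],
           q3 = qs[4], p95 = qs[5], n_included = sum(keep))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nmr_envelope", class(out))
  attr(out, "sims") <- sims
  attr(out, "n_sims") <- n_sims
  attr(out, "seed") <- seed
  out
}

#' Hidden-breeder mixture experiment
#'
#' Simulates ensembles of `n_total` individuals of which
#' `n_hidden_breeders` follow the breeder hazard schedule while all are
#' reported unlabelled, emulating a population in which some breeding
#' males were recorded as non-breeders.
#'
#' @param model An `nmr_simmodel`.
#' @param n_total Total cohort size.
#' @param n_hidden_breeders Number simulated under the breeder schedule
#'   (`<= n_total`).
#' @inheritParams simulate_ensemble
#' @return An `nmr_envelope` tibble.
#' @export
mixture_experiment <- function(model, n_total, n_hidden_breeders,
                               n_sims = 100L, seed = NULL, grid_by = 50L,
                               include_terminated = TRUE) {
  if (n_hidden_breeders > n_total)
    abort("n_hidden_breeders cannot exceed n_total")
  simulate_ensemble(model, n_total - n_hidden_breeders, n_hidden_breeders,
                    n_sims = n_sims, seed = seed, grid_by = grid_by,
                    include_terminated = include_terminated)
}

#' Fraction of an observed survival curve inside an ensemble envelope
#'
#' @param observed An `nmr_km` curve (or tibble with `day`, `surv`).
#' @param envelope An `nmr_envelope`.
#' @param checkpoints Days at which to check containment (non-empty).
#' @return The fraction of checkpoint days at which the observed survival
#'   lies within the envelope's 5th-95th percentile band.
#' @export
envelope_coverage <- function(observed, envelope, checkpoints) {
  if (length(checkpoints) == 0L) abort("checkpoints must be non-empty")
  s <- km_survival_at(observed, checkpoints)
  lo <- stepfun(envelope$day, c(envelope$p5[1], envelope$p5))(checkpoints)
  hi <- stepfun(envelope$day, c(envelope$p95[1], envelope$p95))(checkpoints)
  mean(s >= lo & s <= hi)
}
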