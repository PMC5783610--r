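# Synthetic colony-record generator: produces spreadsheets with the
# statistical structure the analysis pipeline assumes (eusocial colony
# composition, stratum-specific hazards, compile-date censorship, KFR and
# transfer dispositions, multi-resolution date degradation) together with
# a ground-truth sidecar, so every pipeline stage can be tested end to end.

#' Configuration for the synthetic colony generator
#'
#' Defaults emulate a large captive eusocial-rodent collection: ~64
#' colonies averaging 60 animals each (one queen plus 1-3 breeding males
#' per colony, the rest non-breeders), constant per-day mortality of
#' 1e-4/day for non-breeders and 1e-5/day for breeders with an elevated
#' early-life bin over days `[183, 400)`, ongoing per-day censorship
#' (research sacrifice and transfers), birth years spanning 1981-2015 with
#' a pulse year (2010) holding an outsized share of births so that
#' compile-date censorship produces a cohort-entry censorship pulse, and
#' small fractions of rows with missing, unparseable or
#' resolution-degraded dates.
#'
#' @param n_colonies Number of colonies.
#' @param colony_size_mean Mean animals per colony.
#' @param breeding_males_range Breeding males per colony (sampled
#'   uniformly from this integer range).
#' @param male_mislabel_frac Probability a breeding male is recorded as a
#'   non-breeder (queens are always labelled).
#' @param hazard_nonbreeder,hazard_breeder Per-day death probabilities.
#' @param hazard_early Elevated non-breeder death probability over
#'   `[start_day, 400)`; set equal to `hazard_nonbreeder` to disable.
#' @param gompertz Optional list `(alpha, beta)` replacing the constant
#'   non-breeder hazard with a Gompertz hazard discretised to 50-day bins.
#' @param censor_nonbreeder,censor_breeder Baseline per-day censorship
#'   probabilities (KFR + transfers).
#' @param kfr_frac Named vector: probability a pre-compile censorship is
#'   labelled `KFR` rather than `SOLD/GIVEN AWAY`, per stratum.
#' @param birth_years Calendar years births are drawn from (uniform).
#' @param pulse_year,pulse_frac Pulse year and the fraction of all births
#'   assigned to it (0 disables the pulse).
#' @param compile_dates Spreadsheet compilation dates; one is assigned to
#'   each colony and censors its still-alive animals.
#' @param early_event_frac Fraction of animals dying/censored before
#'   `start_day` (73% deaths among them).
#' @param missing_birth_frac,unknown_death_frac,unparseable_frac Fractions
#'   of rows planted with a missing birth date, a dead disposition with no
#'   death date, and a garbled birth date.
#' @param degrade_fracs Named fractions of remaining day-resolution rows
#'   whose birth date is degraded to `month`, `low` (season/year/range/
#'   two-option) or `inequality` resolution.
#' @param start_day,end_day Lifespan simulation window (days of life).
#' @param seed Master seed; the same configuration and seed reproduce the
#'   collection exactly.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_colonies = 64L,
                         colony_size_mean = 60,
                         breeding_males_range = 1:3,
                         male_mislabel_frac = 0.68,
                         hazard_nonbreeder = 1e-4,
                         hazard_breeder = 1e-5,
                         hazard_early = 2e-4,
                         gompertz = NULL,
                         censor_nonbreeder = 2.5e-4,
                         censor_breeder = 1e-4,
                         kfr_frac = c(non_breeder = 0.5, breeder = 0.2),
                         birth_years = 1981:2015,
                         pulse_year = 2010L,
                         pulse_frac = 0.2,
                         compile_dates = as.Date(c("2016-04-14",
                                                   "2016-04-20",
                                                   "2016-05-17")),
                         early_event_frac = 0.008,
                         missing_birth_frac = 0.06,
                         unknown_death_frac = 0.005,
                         unparseable_frac = 0.0005,
                         degrade_fracs = c(month = 0.016, low = 0.036,
                                           inequality = 0.018),
                         start_day = 183L,
                         end_day = 12000L,
                         seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$male_mislabel_frac, cfg$pulse_frac, cfg$early_event_frac,
             cfg$missing_birth_frac, cfg$unknown_death_frac,
             cfg$unparseable_frac, cfg$degrade_fracs, cfg$kfr_frac)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1]")
  if (sum(cfg$degrade_fracs) > 1) abort("degrade fractions must sum to <= 1")
  structure(cfg, class = "synth_config")
}

.synth_model <- function(cfg) {
  sd <- cfg$start_day
  ed <- cfg$end_day
  if (is.null(cfg$gompertz)) {
    nb <- tibble(stratum = "non_breeder",
                 bin_start = c(sd, 400L), bin_end = c(400L, ed),
                 p_death = c(cfg$hazard_early, cfg$hazard_nonbreeder),
                 p_censor = cfg$censor_nonbreeder)
  } else {
    edges <- unique(c(seq(sd, ed, by = 50L), ed))
    mids <- (edges[-length(edges)] + edges[-1]) / 2 - sd
    nb <- tibble(stratum = "non_breeder",
                 bin_start = edges[-length(edges)], bin_end = edges[-1],
                 p_death = pmin(cfg$gompertz$alpha *
                                  exp(cfg$gompertz$beta * mids), 1),
                 p_censor = cfg$censor_nonbreeder)
  }
  br <- tibble(stratum = "breeder", bin_start = sd, bin_end = ed,
               p_death = cfg$hazard_breeder, p_censor = cfg$censor_breeder)
  simulation_model(dplyr::bind_rows(nb, br), start_day = sd, end_day = ed)
}

.sample_birth_dates <- function(n, cfg) {
  years <- cfg$birth_years
  probs <- rep(1, length(years))
  if (cfg$pulse_frac > 0 && cfg$pulse_year %in% years) {
    probs <- rep((1 - cfg$pulse_frac) / (length(years) - 1), length(years))
    probs[years == cfg$pulse_year] <- cfg$pulse_frac
  }
  y <- sample(years, n, replace = TRUE, prob = probs)
  start <- as.Date(sprintf("%d-01-01", y))
  ndays <- as.integer(as.Date(sprintf("%d-12-31", y)) - start)
  start + sapply(ndays, function(k) sample.int(k + 1L, 1L)) - 1L
}

#' Generate a synthetic colony collection with known ground truth
#'
#' Draws colony rosters, true lifespans (via the day-by-day cohort
#' simulator on the *true* breeder/non-breeder strata), calendar birth
#' dates, compile-date censorship for animals still alive at spreadsheet
#' compilation, disposition labels (`DEAD`, `ALIVE`, `KFR`,
#' `SOLD/GIVEN AWAY`), breeding-male mislabelling, and planted data
#' defects (missing/garbled dates, resolution degradation).  The observed
#' records never contain a death occurring after a censorship for the same
#' animal, and the generated composition is returned so that parsing
#' reports can be checked against it exactly.
#'
#' @param config A [synth_config()].
#' @return A list of class `nmr_synth`: `records` (tibble in the canonical
#'   spreadsheet schema, all columns character), `truth` (ground-truth
#'   tibble with true dates, strata, events and planted defect category)
#'   and `config`.
#' @examples
#' coll <- generate_collection(synth_config(n_colonies = 4, seed = 42))
#' head(coll$records)
#' @export
generate_collection <- function(config) {
  cfg <- config
  set.seed(cfg$seed)

  sizes <- pmax(stats::rpois(cfg$n_colonies, cfg$colony_size_mean), 4L)
  n <- sum(sizes)
  colony <- rep(seq_len(cfg$n_colonies), sizes)
  colony_compile <- sample(cfg$compile_dates, cfg$n_colonies, replace = TRUE)

  # colony roles: one queen, 1-3 breeding males, remainder non-breeders
  role <- character(n)
  sex <- character(n)
  for (cid in seq_len(cfg$n_colonies)) {
    idx <- which(colony == cid)
    nb_males <- min(sample(cfg$breeding_males_range, 1L), length(idx) - 1L)
    queen <- idx[1]
    males <- idx[1 + seq_len(nb_males)]
    rest <- setdiff(idx, c(queen, males))
    role[queen] <- "queen"
    role[males] <- "breeding_male"
    role[rest] <- "helper"
    sex[queen] <- "female"
    sex[males] <- "male"
    sex[rest] <- sample(c("female", "male"), length(rest), replace = TRUE)
  }
  true_breeder <- role %in% c("queen", "breeding_male")
  labeled_breeder <- true_breeder
  mislabel <- role == "breeding_male" &
    runif(n) < cfg$male_mislabel_frac
  labeled_breeder[mislabel] <- FALSE

  birth <- .sample_birth_dates(n, cfg)
  compile <- colony_compile[colony]

  # true post-maturity lifespans from the day-by-day simulator
  model <- .synth_model(cfg)
  n_b <- sum(true_breeder)
  n_nb <- n - n_b
  sim <- simulate_population(model, n_nb, n_b)
  exit <- integer(n)
  event <- character(n)
  exit[!true_breeder] <- sim$exit_day[sim$stratum == "non_breeder"]
  event[!true_breeder] <- as.character(sim$event[sim$stratum == "non_breeder"])
  exit[true_breeder] <- sim$exit_day[sim$stratum == "breeder"]
  event[true_breeder] <- as.character(sim$event[sim$stratum == "breeder"])

  # planted pre-maturity events
  early <- runif(n) < cfg$early_event_frac
  exit[early] <- sample(0:(cfg$start_day - 1L), sum(early), replace = TRUE)
  event[early] <- ifelse(runif(sum(early)) < 0.73, "death", "censor")

  # calendar truncation: events after the colony compile date become
  # alive-at-compile censorships
  end_date <- birth + exit
  alive_at_compile <- end_date > compile
  exit[alive_at_compile] <- as.integer(compile[alive_at_compile] -
                                         birth[alive_at_compile])
  event[alive_at_compile] <- "censor"
  end_date[alive_at_compile] <- compile[alive_at_compile]
  # animals that would only be born (or reach no event) after compile are
  # regenerated as plainly alive juveniles is unnecessary: a negative or
  # tiny exit simply stays as an early censorship
  exit <- pmax(exit, 0L)
  end_date <- birth + exit

  disposition <- ifelse(event == "death", "DEAD", NA_character_)
  cens <- which(event == "censor")
  kfr_p <- cfg$kfr_frac[ifelse(true_breeder[cens], "breeder", "non_breeder")]
  lab <- ifelse(alive_at_compile[cens], "ALIVE",
                ifelse(runif(length(cens)) < kfr_p, "KFR",
                       "SOLD/GIVEN AWAY"))
  disposition[cens] <- lab

  animal_id <- sprintf("%09d", sample.int(999999999L, n))

  records <- tibble(
    animal_id = animal_id,
    sex = sex,
    breeder = ifelse(labeled_breeder, "TRUE", "FALSE"),
    date_of_birth = format(birth, "%Y-%m-%d"),
    # alive animals are written with a blank end date: the parser fills in
    # the compile date, as the record-keeping convention dictates
    date_of_end = ifelse(disposition == "ALIVE", "",
                         format(end_date, "%Y-%m-%d")),
    disposition = disposition,
    compile_date = format(compile, "%Y-%m-%d")
  )

  category <- rep("clean", n)

  # planted defects
  pool <- seq_len(n)
  take <- function(frac, pool) {
    k <- round(frac * n)
    picked <- if (k > 0) sample(pool, min(k, length(pool))) else integer(0)
    picked
  }
  miss <- take(cfg$missing_birth_frac, pool)
  records$date_of_birth[miss] <- ""
  category[miss] <- "missing_birth"
  pool <- setdiff(pool, miss)

  unk_pool <- intersect(pool, which(disposition == "DEAD"))
  unk <- take(cfg$unknown_death_frac, unk_pool)
  records$date_of_end[unk] <- "unknown"
  category[unk] <- "unknown_death_date"
  pool <- setdiff(pool, unk)

  garb <- take(cfg$unparseable_frac, pool)
  records$date_of_birth[garb] <- "##garbled##"
  category[garb] <- "unparseable"
  pool <- setdiff(pool, garb)

  degraded <- degrade_dates(records[pool, ], cfg$degrade_fracs)
  records[pool, ] <- as_tibble(degraded)[, names(records)]
  deg_info <- attr(degraded, "degraded")
  if (nrow(deg_info) > 0) {
    category[match(deg_info$animal_id, records$animal_id)] <-
      paste0("degraded_", deg_info$tier)
  }

  truth <- tibble(
    animal_id = animal_id,
    colony = colony,
    sex = sex,
    role = role,
    true_breeder = true_breeder,
    labeled_breeder = labeled_breeder,
    birth_date = birth,
    end_date = end_date,
    exit_day = exit,
    event = event,
    category = category
  )

  structure(list(records = records, truth = truth, config = cfg),
            class = "nmr_synth")
}

#' Degrade day-resolution dates to lower-resolution forms
#'
#' Rewrites a random subset of birth dates to month, season, year, range,
#' two-option or inequality forms such that the true date remains
#' consistent with the degraded text (a range always contains it; an
#' inequality is satisfied by it and unbounded on one side).
#'
#' @param records A records tibble in the canonical schema with
#'   day-resolution `date_of_birth` strings.
#' @param fractions Named fractions (`month`, `low`, `inequality`) of rows
#'   to degrade to each tier; must sum to at most 1.
#' @param seed Optional seed (for standalone use; inside
#'   [generate_collection()] the master seed governs).
#' @return The records tibble with degraded `date_of_birth` strings and an
#'   attribute `"degraded"`: tibble of `animal_id`, `tier`, `form`.
#' @export
degrade_dates <- function(records, fractions = c(month = 0.02, low = 0.04,
                                                 inequality = 0.02),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(fractions) > 1) abort("fractions must sum to <= 1")
  eligible <- which(grepl("^\\d{4}-\\d{2}-\\d{2}$", records$date_of_birth))
  n <- nrow(records)
  k <- vapply(fractions, function(f) round(f * n), 0)
  picked <- sample(eligible, min(sum(k), length(eligible)))
  tiers <- rep(names(fractions), k)[seq_along(picked)]

  deg <- character(length(picked))
  forms <- character(length(picked))
  for (j in seq_along(picked)) {
    d <- as.Date(records$date_of_birth[picked[j]])
    y <- as.integer(format(d, "%Y"))
    m <- as.integer(format(d, "%m"))
    if (tiers[j] == "month") {
      deg[j] <- format(d, "%Y-%m")
      forms[j] <- "month"
    } else if (tiers[j] == "low") {
      form <- sample(c("year", "range", "season", "two_options"), 1,
                     prob = c(0.70, 0.26, 0.015, 0.025))
      if (form == "season" && !(m %in% 3:11)) form <- "month"
      deg[j] <- switch(
        form,
        year = sprintf("%d", y),
        month = format(d, "%Y-%m"),
        range = {
          a <- d - sample(30:400, 1)
          b <- d + sample(30:400, 1)
          paste(format(a, "%Y-%m-%d"), "to", format(b, "%Y-%m-%d"))
        },
        season = {
          season <- c(rep("Spring", 3), rep("Summer", 3),
                      rep("Fall", 3))[m - 2L]
          paste(season, y)
        },
        two_options = {
          a <- d - sample(10:200, 1)
          b <- d + sample(10:200, 1)
          paste(format(a, "%Y-%m-%d"), "or", format(b, "%Y-%m-%d"))
        }
      )
      forms[j] <- form
    } else {
      if (runif(1) < 0.5) {
        deg[j] <- sprintf(">%d", y - sample(1:3, 1))
      } else {
        deg[j] <- sprintf("<%d", y + sample(1:3, 1))
      }
      forms[j] <- "inequality"
    }
  }
  records$date_of_birth[picked] <- deg
  # a low-tier pick that fell back to a month form is a month-tier record
  tiers[forms == "month"] <- "month"
  attr(records, "degraded") <- tibble(
    animal_id = records$animal_id[picked],
    tier = tiers,
    form = forms
  )
  records
}

#' Write a synthetic collection to disk
#'
#' Writes the observed records (`records.csv`), a configuration echo
#' (`config.yaml`) and the ground truth under a `ground_truth/`
#' subdirectory, keeping truth out of the analysis path by directory
#' convention.
#'
#' @param collection An `nmr_synth` list from [generate_collection()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(file.path(dir, "ground_truth"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(collection$records, file.path(dir, "records.csv"))
  readr::write_csv(collection$truth,
                   file.path(dir, "ground_truth", "truth.csv"))
  cfg <- collection$config
  cfg$compile_dates <- format(cfg$compile_dates, "%Y-%m-%d")
  cfg$gompertz <- if (is.null(cfg$gompertz)) NULL else cfg$gompertz
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
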