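# shared fixture builders: everything is generated in code at test time

make_obs <- function(exit_day, event, entry_day = 183L,
                     sex = "female", breeder = FALSE) {
  obs <- tibble::tibble(
    animal_id = sprintf("A%04d", seq_along(exit_day)),
    entry_day = as.integer(entry_day),
    exit_day = as.integer(exit_day),
    event = factor(event, levels = c("death", "censor")),
    sex = sex,
    breeder = breeder,
    tier = "day"
  )
  class(obs) <- c("nmr_observations", class(obs))
  attr(obs, "start_day") <- as.integer(entry_day)
  obs
}

# a single-stratum constant-hazard model over [183, end)
flat_model <- function(p_death, p_censor = 0, end_day = 12000L) {
  simulation_model(tibble::tibble(
    stratum = rep(c("non_breeder", "breeder"), each = 1),
    bin_start = 183L, bin_end = as.integer(end_day),
    p_death = p_death, p_censor = p_censor
  ), end_day = as.integer(end_day))
}

# canonical-schema records tibble with day-resolution dates
make_records_df <- function(n = 20, seed = 1, compile = "2016-05-17") {
  set.seed(seed)
  birth <- as.Date("2000-01-01") + sample(0:3000, n, replace = TRUE)
  life <- sample(200:5000, n, replace = TRUE)
  tibble::tibble(
    animal_id = sprintf("%09d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    breeder = sample(c("TRUE", "FALSE"), n, replace = TRUE, prob = c(.1, .9)),
    date_of_birth = format(birth, "%Y-%m-%d"),
    date_of_end = format(birth + life, "%Y-%m-%d"),
    disposition = sample(c("DEAD", "KFR", "SOLD/GIVEN AWAY"), n,
                         replace = TRUE),
    compile_date = compile
  )
}
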