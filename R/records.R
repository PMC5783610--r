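# Colony lifespan spreadsheets -> analysis-ready censored observations.
#
# Canonical CSV schema: animal_id, sex, breeder, date_of_birth, date_of_end,
# disposition, compile_date.  A format_config list can remap differently
# named columns and switch the exact-day date dialect.

.dispositions <- c("dead", "alive_at_compile", "sold_given_away", "kfr",
                   "unknown_death_date")

.normalise_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("f", "female") ~ "female",
    x %in% c("m", "male") ~ "male",
    TRUE ~ "unknown"
  )
}

.normalise_breeder <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "yes", "y", "1", "breeder")
}

.normalise_disposition <- function(x) {
  x <- toupper(trimws(as.character(x)))
  dplyr::case_when(
    grepl("KFR", x) ~ "kfr",
    grepl("SOLD|GIVEN", x) ~ "sold_given_away",
    grepl("ALIVE", x) ~ "alive_at_compile",
    grepl("DEAD|DIED", x) ~ "dead",
    TRUE ~ NA_character_
  )
}

#' Parse a colony lifespan spreadsheet into animal records
#'
#' Reads a CSV (or takes an already-loaded data frame) in the canonical
#' schema `animal_id, sex, breeder, date_of_birth, date_of_end,
#' disposition, compile_date`, parses both date columns into
#' multi-resolution specifications, classifies every row, and attaches a
#' stringency report.  No row is silently dropped: rows that cannot enter
#' any analysis are kept with `included = FALSE` and an `exclude_reason`
#' (`missing_birth`, `unknown_death_date`, `unparseable`).
#'
#' Disposition handling follows colony record-keeping practice: animals
#' still alive at spreadsheet compilation are censored at the compile date
#' (a missing end date on an `ALIVE` row is filled with `compile_date`);
#' animals labelled `SOLD/GIVEN AWAY` or `KFR` (killed for research) are
#' right-censored, not deaths.  A row labelled both dead and KFR is treated
#' as KFR (censor) and flagged in the exclusion/conflict log.
#'
#' @param x Path to a CSV file, or a data frame.
#' @param format_config Optional list with elements `columns` (named
#'   character vector mapping canonical names to the file's column names)
#'   and `dialect` (exact-day date dialect passed to [parse_date_spec()]).
#' @return A tibble of class `nmr_records`, one row per input row, with
#'   parsed date specification columns (`birth_resolution`, `birth_start`,
#'   `birth_end`, likewise `end_*`), the minimal stringency `tier` at which
#'   the record becomes usable, `included` and `exclude_reason`.  The
#'   stringency report is attached as attribute `"report"` (see
#'   [stringency_report()]) and a conflict log as attribute `"conflicts"`.
#' @examples
#' cfg <- synth_config(n_colonies = 3, seed = 1)
#' records <- parse_collection(generate_collection(cfg)$records)
#' stringency_report(records)
#' @export
parse_collection <- function(x, format_config = NULL) {
  dialect <- format_config$dialect %||% "iso"
  canonical <- c("animal_id", "sex", "breeder", "date_of_birth",
                 "date_of_end", "disposition", "compile_date")

  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(paste0("file not found: ", x))
    x <- readr::read_csv(x, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  }
  df <- as_tibble(x)

  if (!is.null(format_config$columns)) {
    map <- format_config$columns
    missing_map <- setdiff(names(map), names(df))
    for (canon in names(map)) {
      if (!map[[canon]] %in% names(df))
        abort(paste0("mapped column not found in input: ", map[[canon]]))
      names(df)[names(df) == map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(canonical, names(df))
  if (length(missing_cols) > 0L)
    abort(paste0("input is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))

  if (anyDuplicated(df$animal_id))
    abort("animal_id values must be unique within a collection")

  disposition <- .normalise_disposition(df$disposition)
  conflict <- grepl("KFR", toupper(as.character(df$disposition))) &
    grepl("DEAD|DIED", toupper(as.character(df$disposition)))

  birth <- parse_date_spec(as.character(df$date_of_birth), dialect = dialect)
  end <- parse_date_spec(as.character(df$date_of_end), dialect = dialect)
  compile_date <- as.Date(as.character(df$compile_date),
                          format = switch(dialect, iso = "%Y-%m-%d",
                                          dmy = "%d/%m/%Y", mdy = "%m/%d/%Y"))

  # living animals are censored at the compile date of their spreadsheet
  alive <- !is.na(disposition) & disposition == "alive_at_compile"
  if (any(alive & is.na(compile_date)))
    abort("rows with disposition ALIVE require a compile_date")
  fill <- alive & end$resolution == "missing"
  end$resolution[fill] <- "day"
  end$start[fill] <- compile_date[fill]
  end$end[fill] <- compile_date[fill]

  # dead animals with no usable death date are a distinct exclusion class
  dead_no_date <- !is.na(disposition) & disposition == "dead" &
    end$resolution == "missing"
  disposition[dead_no_date] <- "unknown_death_date"

  exclude_reason <- dplyr::case_when(
    birth$resolution == "unparseable" | end$resolution == "unparseable" |
      is.na(disposition) ~ "unparseable",
    birth$resolution == "missing" ~ "missing_birth",
    disposition == "unknown_death_date" | end$resolution == "missing" ~
      "unknown_death_date",
    TRUE ~ NA_character_
  )
  included <- is.na(exclude_reason)

  tier <- rep(NA_character_, nrow(df))
  btier <- .resolution_tier[birth$resolution]
  etier <- .resolution_tier[end$resolution]
  tier[included] <- .tier_levels[pmax(match(btier, .tier_levels),
                                      match(etier, .tier_levels))[included]]

  records <- tibble(
    animal_id = as.character(df$animal_id),
    sex = .normalise_sex(df$sex),
    breeder = .normalise_breeder(df$breeder),
    disposition = disposition,
    compile_date = compile_date,
    birth_raw = birth$raw, birth_resolution = birth$resolution,
    birth_start = birth$start, birth_end = birth$end,
    end_raw = end$raw, end_resolution = end$resolution,
    end_start = end$start, end_end = end$end,
    tier = tier,
    included = included,
    exclude_reason = exclude_reason
  )

  class(records) <- c("nmr_records", class(records))
  attr(records, "report") <- .build_report(records)
  attr(records, "conflicts") <- tibble(
    animal_id = records$animal_id[conflict],
    note = rep("labelled both dead and KFR; treated as KFR censor",
               sum(conflict))
  )
  records
}

.build_report <- function(records) {
  tier_counts <- function(t) {
    idx <- records$included & records$tier == t
    tibble(category = paste0(ifelse(t == "day", "included_", "added_"), t),
           n = sum(idx),
           deaths = sum(idx & records$disposition == "dead"),
           censors = sum(idx & records$disposition != "dead"))
  }
  excl <- function(reason, label) {
    idx <- !records$included & records$exclude_reason %in% reason
    tibble(category = label, n = sum(idx), deaths = NA_integer_,
           censors = NA_integer_)
  }
  dplyr::bind_rows(
    tibble(category = "total", n = nrow(records), deaths = NA_integer_,
           censors = NA_integer_),
    tier_counts("day"), tier_counts("month"), tier_counts("low"),
    tier_counts("inequality"),
    excl(c("missing_birth"), "excluded_missing_birth"),
    excl(c("unknown_death_date"), "excluded_unknown_death_date"),
    excl(c("unparseable"), "excluded_unparseable")
  )
}

#' Stringency report for a parsed collection
#'
#' Counts of records available at each stringency tier (with death/censor
#' splits from the disposition labels) and of each exclusion class.  The
#' tier and exclusion categories always sum to the total row count.
#'
#' @param records An `nmr_records` tibble from [parse_collection()].
#' @return A tibble with columns `category`, `n`, `deaths`, `censors`.
#' @export
stringency_report <- function(records) {
  rep <- attr(records, "report")
  if (is.null(rep)) abort("no stringency report attached; run parse_collection()")
  rep
}

#' Build analysis-ready lifespan observations at a stringency tier
#'
#' Resolves birth and end dates with the midpoint hierarchy at the
#' requested tier, computes each animal's lifespan in whole days as the
#' calendar difference (day-of-life is 0-based from the birth date), and
#' emits right-censored observations on the post-maturity clock.  Deaths
#' and censorships occurring strictly before `start_day` are dropped (an
#' event on `start_day` itself is kept), as are records whose resolved end
#' precedes their resolved birth; both are logged in the `"exclusions"`
#' attribute, never silently.
#'
#' @param records An `nmr_records` tibble from [parse_collection()].
#' @param tier Stringency tier (see [resolve_date()]); each tier admits a
#'   superset of the records of the previous one.
#' @param start_day Entry day-of-life (reproductive maturity; default 183).
#' @return A tibble of class `nmr_observations` with columns `animal_id`,
#'   `entry_day`, `exit_day`, `event` (`"death"` or `"censor"`), `sex`,
#'   `breeder`, `tier` (the record's own minimal tier).
#' @examples
#' cfg <- synth_config(n_colonies = 3, seed = 1)
#' recs <- parse_collection(generate_collection(cfg)$records)
#' obs <- build_observations(recs, tier = "low")
#' dplyr::count(obs, event)
#' @export
build_observations <- function(records,
                               tier = c("day", "month", "low", "inequality"),
                               start_day = 183L) {
  tier <- match.arg(tier)
  rank <- .tier_rank(tier)
  usable <- records[records$included &
                      match(records$tier, .tier_levels) <= rank, ]

  birth <- resolve_date(
    tibble(resolution = usable$birth_resolution,
           start = usable$birth_start, end = usable$birth_end), tier)
  end <- resolve_date(
    tibble(resolution = usable$end_resolution,
           start = usable$end_start, end = usable$end_end), tier)

  exit_day <- as.integer(end - birth)
  event <- ifelse(usable$disposition == "dead", "death", "censor")

  status <- dplyr::case_when(
    is.na(exit_day) ~ "unresolved_at_tier",
    exit_day < 0L ~ "invalid_negative_lifespan",
    exit_day < start_day ~ "pre_entry_event",
    TRUE ~ "ok"
  )

  obs <- tibble(
    animal_id = usable$animal_id[status == "ok"],
    entry_day = as.integer(start_day),
    exit_day = exit_day[status == "ok"],
    event = factor(event[status == "ok"], levels = c("death", "censor")),
    sex = usable$sex[status == "ok"],
    breeder = usable$breeder[status == "ok"],
    tier = usable$tier[status == "ok"]
  )
  class(obs) <- c("nmr_observations", class(obs))
  attr(obs, "start_day") <- as.integer(start_day)
  attr(obs, "exclusions") <- tibble(
    animal_id = usable$animal_id[status != "ok"],
    event = event[status != "ok"],
    reason = status[status != "ok"]
  )
  obs
}

#' Partition observations into sex-by-breeder strata
#'
#' @param observations An observation tibble (needs `sex` and/or `breeder`).
#' @param by Character vector of stratifying variables, a subset of
#'   `c("sex", "breeder")`.
#' @param unknown_sex `"keep"` places unknown-sex animals in their own
#'   strata; `"drop"` excludes them (logged via attribute `"dropped"`).
#' @return A named list of tibbles, one per stratum; empty strata are
#'   present (zero-row tibbles), and every observation appears in exactly
#'   one stratum.
#' @export
stratify <- function(observations, by = c("sex", "breeder"),
                     unknown_sex = c("keep", "drop")) {
  unknown_sex <- match.arg(unknown_sex)
  by <- match.arg(by, c("sex", "breeder"), several.ok = TRUE)
  obs <- observations
  dropped <- obs[0, ]
  if ("sex" %in% by && unknown_sex == "drop") {
    dropped <- obs[obs$sex == "unknown", ]
    obs <- obs[obs$sex != "unknown", ]
  }
  levels_list <- list(
    sex = if (unknown_sex == "keep") c("female", "male", "unknown")
          else c("female", "male"),
    breeder = c("breeder", "nonbreeder")
  )
  key_parts <- lapply(by, function(v) {
    val <- if (v == "breeder") ifelse(obs$breeder, "breeder", "nonbreeder")
           else obs$sex
    factor(val, levels = levels_list[[v]])
  })
  key <- interaction(key_parts, sep = "_", drop = FALSE)
  out <- split(obs, key)
  attr(out, "dropped") <- dropped
  out
}

#' Write observations to CSV
#'
#' @param observations An `nmr_observations` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(as_tibble(observations), path)
  invisible(path)
}

#' Read observations written by [write_observations()]
#'
#' @param path CSV path.
#' @param start_day Entry day recorded for the observations (default 183).
#' @return An `nmr_observations` tibble.
#' @export
read_observations <- function(path, start_day = 183L) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  obs <- tibble(
    animal_id = as.character(df$animal_id),
    entry_day = as.integer(df$entry_day),
    exit_day = as.integer(df$exit_day),
    event = factor(df$event, levels = c("death", "censor")),
    sex = if ("sex" %in% names(df)) df$sex else NA_character_,
    breeder = if ("breeder" %in% names(df)) df$breeder else NA,
    tier = if ("tier" %in% names(df)) df$tier else NA_character_
  )
  class(obs) <- c("nmr_observations", class(obs))
  attr(obs, "start_day") <- as.integer(start_day)
  obs
}
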