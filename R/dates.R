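# Multi-resolution date specifications and the deterministic midpoint
# imputation hierarchy used to admit low-resolution records.

# Seasonal midpoints: Fall maps to November 7 (midpoint of the astronomical
# season); the other three use the analogous astronomical-season midpoints.
.season_midpoint <- c(winter = "02-05", spring = "05-06",
                      summer = "08-06", fall = "11-07")

# Month spans used when a season bounds a range or inequality.  Winter YYYY
# is taken as Dec 1 (YYYY-1) through end of Feb YYYY.
.season_months <- list(winter = c(12L, 1L, 2L), spring = 3:5,
                       summer = 6:8, fall = 9:11)

.tier_levels <- c("day", "month", "low", "inequality")

.resolution_tier <- c(day = "day", month = "month", season_year = "low",
                      year = "low", range = "low", two_options = "low",
                      inequality = "inequality")

.tier_rank <- function(tier) {
  tier <- match.arg(tier, .tier_levels)
  match(tier, .tier_levels)
}

.month_from_name <- function(x) {
  m <- match(tolower(x), tolower(month.name))
  if (is.na(m)) m <- match(tolower(x), tolower(month.abb))
  m
}

.last_dom <- function(year, month) {
  first_next <- if (month == 12L) {
    as.Date(sprintf("%04d-01-01", year + 1L))
  } else {
    as.Date(sprintf("%04d-%02d-01", year, month + 1L))
  }
  first_next - 1L
}

.parse_exact_day <- function(s, dialect) {
  fmt <- switch(dialect, iso = "%Y-%m-%d", dmy = "%d/%m/%Y", mdy = "%m/%d/%Y")
  d <- as.Date(s, format = fmt)
  # round-trip to reject impossible dates such as 2001-02-30
  if (is.na(d) || format(d, fmt) != s) return(NULL)
  d
}

# parse one raw string into list(resolution, start, end); start/end bound
# the span of calendar dates consistent with the specification.
.parse_one_date <- function(s, dialect) {
  miss <- list(resolution = "missing", start = as.Date(NA), end = as.Date(NA))
  bad <- list(resolution = "unparseable", start = as.Date(NA), end = as.Date(NA))
  if (is.na(s)) return(miss)
  s <- trimws(s)
  if (s == "" || tolower(s) %in% c("unknown", "na", "n/a")) return(miss)

  # approximate markers are treated identically to the exact form
  s <- sub("^~\\s*", "", s)

  if (grepl("^[<>]", s)) {
    dir <- substr(s, 1L, 1L)
    inner <- .parse_one_date(sub("^[<>]\\s*", "", s), dialect)
    if (!inner$resolution %in% c("day", "month", "season_year", "year"))
      return(bad)
    if (dir == ">") {
      list(resolution = "inequality", start = inner$end + 1L, end = as.Date(NA))
    } else {
      list(resolution = "inequality", start = as.Date(NA), end = inner$start - 1L)
    }
  } else if (grepl("(?i) to ", s, perl = TRUE)) {
    parts <- trimws(strsplit(s, "(?i) to ", perl = TRUE)[[1]])
    if (length(parts) != 2L) return(bad)
    a <- .parse_one_date(parts[1], dialect)
    b <- .parse_one_date(parts[2], dialect)
    ok <- c("day", "month", "season_year", "year")
    if (!a$resolution %in% ok || !b$resolution %in% ok) return(bad)
    if (a$start > b$end) return(bad)
    list(resolution = "range", start = a$start, end = b$end)
  } else if (grepl("(?i) or ", s, perl = TRUE)) {
    parts <- trimws(strsplit(s, "(?i) or ", perl = TRUE)[[1]])
    if (length(parts) != 2L) return(bad)
    a <- .parse_one_date(parts[1], dialect)
    b <- .parse_one_date(parts[2], dialect)
    ok <- c("day", "month", "year")
    if (!a$resolution %in% ok || !b$resolution %in% ok) return(bad)
    list(resolution = "two_options",
         start = min(a$start, b$start), end = max(a$end, b$end))
  } else if (grepl("^(?i)(winter|spring|summer|fall|autumn)[ ,]+\\d{4}$", s,
                   perl = TRUE)) {
    season <- tolower(sub("[ ,]+\\d{4}$", "", s))
    if (season == "autumn") season <- "fall"
    year <- as.integer(sub("^\\D+[ ,]+", "", s))
    months <- .season_months[[season]]
    if (season == "winter") {
      start <- as.Date(sprintf("%04d-12-01", year - 1L))
      end <- .last_dom(year, 2L)
    } else {
      start <- as.Date(sprintf("%04d-%02d-01", year, months[1]))
      end <- .last_dom(year, months[3])
    }
    list(resolution = "season_year", start = start, end = end)
  } else if (grepl("^\\d{4}-\\d{1,2}$", s)) {
    year <- as.integer(substr(s, 1L, 4L))
    month <- as.integer(sub("^\\d{4}-", "", s))
    if (month < 1L || month > 12L) return(bad)
    list(resolution = "month",
         start = as.Date(sprintf("%04d-%02d-01", year, month)),
         end = .last_dom(year, month))
  } else if (grepl("^[A-Za-z]+[ ,]+\\d{4}$", s)) {
    month <- .month_from_name(sub("[ ,]+\\d{4}$", "", s))
    year <- as.integer(sub("^[A-Za-z]+[ ,]+", "", s))
    if (is.na(month)) return(bad)
    list(resolution = "month",
         start = as.Date(sprintf("%04d-%02d-01", year, month)),
         end = .last_dom(year, month))
  } else if (grepl("^\\d{4}$", s)) {
    year <- as.integer(s)
    list(resolution = "year",
         start = as.Date(sprintf("%04d-01-01", year)),
         end = as.Date(sprintf("%04d-12-31", year)))
  } else {
    d <- .parse_exact_day(s, dialect)
    if (is.null(d)) bad else list(resolution = "day", start = d, end = d)
  }
}

#' Parse raw date strings into multi-resolution date specifications
#'
#' Colony records frequently carry dates at less than single-day resolution:
#' a month (`"1995-06"`, `"June 1995"`), a season (`"Fall 1999"`), a year
#' (`"1997"`), a range (`"1994-01-01 to 1996-12-31"`), two candidate dates
#' (`"1995-03-01 or 1995-05-01"`) or a one-sided inequality (`">1997"`).
#' An `~` prefix marks an approximate month or year and is treated the same
#' as the exact form.  Each string is classified by resolution and bounded
#' by the first and last calendar dates consistent with it.
#'
#' @param x Character vector of raw date strings.  Empty strings, `NA` and
#'   `"unknown"` become resolution `"missing"`.
#' @param dialect Format of exact-day dates: `"iso"` (`YYYY-MM-DD`,
#'   default), `"dmy"` (`DD/MM/YYYY`) or `"mdy"` (`MM/DD/YYYY`).
#' @return A tibble with one row per element: `raw`, `resolution` (one of
#'   `day`, `month`, `season_year`, `year`, `range`, `two_options`,
#'   `inequality`, `missing`, `unparseable`) and the bounding dates
#'   `start`, `end` (`NA` on the unbounded side of an inequality).
#' @examples
#' parse_date_spec(c("2001-05-17", "June 1995", "Fall 1999", ">1997"))
#' @seealso [resolve_date()] for turning a specification into a single
#'   imputed calendar date at a chosen stringency tier.
#' @export
parse_date_spec <- function(x, dialect = c("iso", "dmy", "mdy")) {
  dialect <- match.arg(dialect)
  x <- as.character(x)
  parsed <- lapply(x, .parse_one_date, dialect = dialect)
  tibble(
    raw = x,
    resolution = vapply(parsed, `[[`, character(1), "resolution"),
    start = as.Date(vapply(parsed, function(p) as.numeric(p$start), 0)),
    end = as.Date(vapply(parsed, function(p) as.numeric(p$end), 0))
  )
}

#' Resolve a date specification to a single imputed calendar date
#'
#' Applies the deterministic midpoint hierarchy: month resolves to the 15th;
#' a bare year to July 2; a season to its fixed midpoint (Winter Feb 5,
#' Spring May 6, Summer Aug 6, Fall Nov 7); a range or pair of candidate
#' dates to the middle date of the full span (`start + floor((end-start)/2)`
#' days); an inequality to the nearest date satisfying it (so `">1997"`
#' resolves to January 1, 1998).  A specification whose resolution class is
#' not admitted at the requested stringency tier resolves to `NA`
#' (unresolved), which is a value rather than an error.
#'
#' @param spec A tibble from [parse_date_spec()] (or a character vector,
#'   which is parsed with the default dialect).
#' @param tier Stringency tier: `"day"` admits only day-resolution dates;
#'   `"month"` additionally admits months; `"low"` additionally admits
#'   seasons, years, ranges and two-option dates; `"inequality"` admits
#'   everything.
#' @return A `Date` vector, `NA` where unresolved at `tier`.
#' @examples
#' resolve_date("June 1995", tier = "month")   # 1995-06-15
#' resolve_date("1997", tier = "low")          # 1997-07-02
#' resolve_date("1997", tier = "day")          # NA: not admitted at day tier
#' @export
resolve_date <- function(spec, tier = c("day", "month", "low", "inequality")) {
  tier <- match.arg(tier)
  if (is.character(spec)) spec <- parse_date_spec(spec)
  stopifnot(all(c("resolution", "start", "end") %in% names(spec)))
  rank <- .tier_rank(tier)

  out <- rep(as.Date(NA), nrow(spec))
  res <- spec$resolution
  admissible <- res %in% names(.resolution_tier) &
    match(.resolution_tier[res], .tier_levels) <= rank
  admissible[is.na(admissible)] <- FALSE

  for (i in which(admissible)) {
    out[i] <- switch(
      res[i],
      day = spec$start[i],
      month = spec$start[i] + 14L,
      year = as.Date(sprintf("%s-07-02", format(spec$start[i], "%Y"))),
      # midpoint carries the year of the season's end (matters for winter)
      season_year = .resolve_season(spec$start[i], spec$end[i]),
      range = spec$start[i] + floor(as.numeric(spec$end[i] - spec$start[i]) / 2),
      two_options = spec$start[i] +
        floor(as.numeric(spec$end[i] - spec$start[i]) / 2),
      inequality = if (is.na(spec$end[i])) spec$start[i] else spec$end[i],
      as.Date(NA)
    )
  }
  out
}

.resolve_season <- function(start, end) {
  year <- as.integer(format(end, "%Y"))
  start_month <- as.integer(format(start, "%m"))
  season <- switch(as.character(start_month),
                   "12" = "winter", "3" = "spring", "6" = "summer",
                   "9" = "fall")
  as.Date(sprintf("%04d-%s", year, .season_midpoint[[season]]))
}
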