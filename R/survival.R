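# Kaplan-Meier survival and exposure-day interval hazard estimation.

#' Kaplan-Meier survival curve for a common-entry cohort
#'
#' Product-limit estimate for right-censored observations sharing a common
#' entry day.  Ties at a day are processed deaths-before-censorings (the
#' standard convention).  Estimation is delegated to
#' [survival::survfit()]; the curve is returned as a tidy step table.
#'
#' @param observations A tibble with columns `entry_day`, `exit_day` and
#'   `event` (`"death"`/`"censor"`), e.g. from [build_observations()].
#' @return A tibble of class `nmr_km` with columns `day`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (the survival probability *after* the
#'   events of that day; right-continuous step function).  The entry day is
#'   included with `surv = 1` unless events occur on it.  Attributes:
#'   `entry_day`, `n`.
#' @examples
#' obs <- tibble::tibble(entry_day = 183, exit_day = c(200, 250, 300, 350, 400),
#'                       event = c("death", "censor", "death", "censor", "death"))
#' km_estimate(obs)
#' @export
km_estimate <- function(observations) {
  if (nrow(observations) == 0L) abort("cannot estimate survival from zero observations")
  entry <- unique(observations$entry_day)
  if (length(entry) != 1L)
    abort("all observations must share a common entry day")
  if (any(observations$exit_day < entry))
    abort("exit_day must be >= entry_day for every observation")

  fit <- survival::survfit(
    survival::Surv(exit_day, event == "death") ~ 1,
    data = tibble(exit_day = observations$exit_day,
                  event = as.character(observations$event))
  )
  curve <- tibble(
    day = as.integer(fit$time),
    n_risk = as.integer(fit$n.risk),
    n_event = as.integer(fit$n.event),
    n_censor = as.integer(fit$n.censor),
    surv = fit$surv
  )
  if (curve$day[1] > entry) {
    curve <- dplyr::bind_rows(
      tibble(day = as.integer(entry), n_risk = nrow(observations),
             n_event = 0L, n_censor = 0L, surv = 1),
      curve
    )
  }
  class(curve) <- c("nmr_km", class(curve))
  attr(curve, "entry_day") <- as.integer(entry)
  attr(curve, "n") <- nrow(observations)
  curve
}

#' Evaluate a Kaplan-Meier curve at arbitrary days
#'
#' @param curve An `nmr_km` tibble (or any tibble with `day` and `surv`).
#' @param days Integer vector of days-of-life.
#' @return Survival probabilities; 1 before the first tabulated day, and the
#'   last tabulated value beyond the end of the curve.
#' @export
km_survival_at <- function(curve, days) {
  f <- stepfun(curve$day, c(1, curve$surv), right = FALSE)
  f(days)
}

#' Construct an age-binning scheme for interval hazard estimation
#'
#' @param mode `"fixed_width"` lays half-open windows of `width` days from
#'   `anchor` (with a partial first window `[start_day, anchor)` when
#'   `anchor` exceeds the cohort entry day); `"explicit_edges"` uses the
#'   supplied `edges` verbatim; `"adaptive"` starts with the fixed first
#'   bin `[start_day, first_bin_end)` and thereafter closes each bin once
#'   it holds at least `min_deaths` deaths (or at the end of the data),
#'   widening the windows as the population thins so that confidence
#'   intervals stay roughly even.
#' @param width Bin width in days (fixed_width).
#' @param edges Strictly increasing integer day edges (explicit_edges).
#' @param anchor First full-window start (fixed_width); defaults to the
#'   cohort entry day.
#' @param min_deaths Deaths per adaptive bin (default 30).
#' @param first_bin_end End of the fixed first adaptive bin (default 400).
#' @return A `bin_scheme` list.
#' @export
bin_scheme <- function(mode = c("fixed_width", "explicit_edges", "adaptive"),
                       width = NULL, edges = NULL, anchor = NULL,
                       min_deaths = 30L, first_bin_end = 400L) {
  mode <- match.arg(mode)
  if (mode == "fixed_width" && (is.null(width) || width < 1))
    abort("fixed_width scheme requires a positive width")
  if (mode == "explicit_edges") {
    if (is.null(edges) || length(edges) < 2L || any(diff(edges) <= 0))
      abort("explicit_edges scheme requires >= 2 strictly increasing edges")
  }
  structure(list(mode = mode, width = width, edges = edges, anchor = anchor,
                 min_deaths = min_deaths, first_bin_end = first_bin_end),
            class = "bin_scheme")
}

.scheme_edges <- function(scheme, observations) {
  entry <- min(observations$entry_day)
  max_exit <- max(observations$exit_day)
  switch(
    scheme$mode,
    explicit_edges = as.integer(scheme$edges),
    fixed_width = {
      anchor <- as.integer(scheme$anchor %||% entry)
      if (anchor < entry) abort("anchor must be >= the cohort entry day")
      full <- seq(anchor, by = scheme$width,
                  length.out = ceiling((max_exit + 1 - anchor) / scheme$width) + 1)
      edges <- if (anchor > entry) c(entry, full) else full
      as.integer(edges[edges <= max(full)])
    },
    adaptive = {
      edges <- c(entry, as.integer(scheme$first_bin_end))
      deaths <- sort(observations$exit_day[observations$event == "death"])
      repeat {
        last <- edges[length(edges)]
        if (last > max_exit) break
        remaining <- deaths[deaths >= last]
        if (length(remaining) >= scheme$min_deaths) {
          nxt <- remaining[scheme$min_deaths] + 1L
          if (nxt > max_exit) nxt <- max_exit + 1L
          edges <- c(edges, nxt)
        } else {
          edges <- c(edges, max_exit + 1L)
        }
      }
      unique(as.integer(edges))
    }
  )
}

#' Age-binned per-day hazard estimates from exposure days
#'
#' For each half-open age bin `[start, end)` the estimator is the number of
#' events of interest in the bin divided by the total animal-days of
#' observation in the bin.  An animal alive across the whole bin
#' contributes its full width; an animal that dies or is censored inside
#' the bin contributes the days up to *and including* the event day.  The
#' point estimate is therefore a per-day event probability; its 95%
#' confidence interval is the continuity-corrected Wilson score interval
#' with the bin's exposure days as trials.  With
#' `event_of_interest = "censor"` the roles of death and censorship are
#' reversed and the same machinery estimates the per-day censorship
#' probability.
#'
#' @param observations Observation tibble (`entry_day`, `exit_day`, `event`).
#' @param scheme A [bin_scheme()].
#' @param event_of_interest `"death"` (default) or `"censor"`.
#' @param conf_level Confidence level for the Wilson interval.
#' @return A tibble of class `nmr_hazard`: `bin_start`, `bin_end`,
#'   `n_start` (animals under observation at bin start), `events`,
#'   `exposure` (animal-days), `hazard`, `ci_low`, `ci_high`, `undefined`
#'   (`TRUE` for bins with zero exposure, whose estimate is `NA`).
#' @examples
#' obs <- tibble::tibble(entry_day = 183, exit_day = c(400, 900, 1400),
#'                       event = c("death", "censor", "death"))
#' interval_hazard(obs, bin_scheme("explicit_edges", edges = c(183, 1000, 1500)))
#' @export
interval_hazard <- function(observations, scheme,
                            event_of_interest = c("death", "censor"),
                            conf_level = 0.95) {
  event_of_interest <- match.arg(event_of_interest)
  if (nrow(observations) == 0L) abort("no observations")
  edges <- .scheme_edges(scheme, observations)
  entry <- observations$entry_day
  exit <- observations$exit_day
  is_event <- observations$event == event_of_interest

  rows <- lapply(seq_len(length(edges) - 1L), function(i) {
    s <- edges[i]; e <- edges[i + 1L]
    lo <- pmax(s, entry)
    hi <- pmin(exit, e - 1L)
    expo <- sum(pmax(hi - lo + 1L, 0L))
    d <- sum(is_event & exit >= s & exit < e)
    n_start <- sum(exit >= s & entry < e)
    if (expo > 0) {
      ci <- wilson_interval(d, expo, conf_level)
      tibble(bin_start = s, bin_end = e, n_start = n_start, events = d,
             exposure = expo, hazard = d / expo,
             ci_low = ci$low, ci_high = ci$high, undefined = FALSE)
    } else {
      tibble(bin_start = s, bin_end = e, n_start = n_start, events = d,
             exposure = 0, hazard = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, undefined = TRUE)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nmr_hazard", class(out))
  attr(out, "event_of_interest") <- event_of_interest
  attr(out, "conf_level") <- conf_level
  out
}

#' Wilson score interval with continuity correction
#'
#' Continuity-corrected Wilson score bounds for a binomial proportion
#' (Newcombe's formulation), clipped to `[0, 1]`; the lower bound is 0 when
#' there are no successes and the upper bound is 1 when every trial
#' succeeds.  Used here to put confidence intervals on per-day event
#' probabilities with exposure days as trials.
#'
#' @param successes Number of successes (vectorised).
#' @param trials Number of trials (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with columns `low`, `high`.
#' @examples
#' wilson_interval(5, 100)
#' @export
wilson_interval <- function(successes, trials, conf_level = 0.95) {
  if (any(trials <= 0)) abort("trials must be positive")
  if (any(successes < 0 | successes > trials))
    abort("successes must lie in [0, trials]")
  z <- qnorm(1 - (1 - conf_level) / 2)
  n <- as.numeric(trials)
  x <- as.numeric(successes)
  p <- x / n
  q <- 1 - p
  low <- (2 * n * p + z^2 - 1 -
            z * sqrt(pmax(z^2 - 2 - 1 / n + 4 * p * (n * q + 1), 0))) /
    (2 * (n + z^2))
  high <- (2 * n * p + z^2 + 1 +
             z * sqrt(pmax(z^2 + 2 - 1 / n + 4 * p * (n * q - 1), 0))) /
    (2 * (n + z^2))
  low[x == 0] <- 0
  high[x == n] <- 1
  tibble(low = pmin(pmax(low, 0), 1), high = pmin(pmax(high, 0), 1))
}

#' Median and maximal lifespan on the post-maturity clock
#'
#' Summarises a survival curve by the ages at which it first drops to or
#' below 0.5 (median) and `1 - max_quantile` (the operational "maximal
#' lifespan", by default the 95th percentile of post-maturity lifespans).
#' A percentile the curve never reaches is reported as not achieved
#' (`NA` age with an explicit flag) rather than extrapolated.
#'
#' @param x An `nmr_km` curve, or any data frame with a time column
#'   (`day` or `age`) and `surv`.
#' @param t_sex Age at reproductive maturity, on the same time scale as the
#'   curve; the entry attribute of an `nmr_km` curve is used by default.
#' @param max_quantile Quantile defining maximal lifespan (default 0.95).
#' @return A one-row tibble: `t_sex`, `median_age`, `median_post_tsex`,
#'   `max_age`, `max_post_tsex`, `median_achieved`, `max_achieved`, and
#'   `segment_ratio` = (max_age - median_age) / (median_age - t_sex), the
#'   length of the upper half of the survival curve relative to the lower.
#' @export
lifespan_summary <- function(x, t_sex = NULL, max_quantile = 0.95) {
  time_col <- intersect(c("day", "age"), names(x))[1]
  if (is.na(time_col)) abort("x needs a `day` or `age` column")
  if (is.null(t_sex)) t_sex <- attr(x, "entry_day")
  if (is.null(t_sex)) abort("t_sex must be supplied")
  tt <- x[[time_col]]
  ss <- x$surv

  cross <- function(level) {
    idx <- which(ss <= level)
    if (length(idx) == 0L) NA_real_ else tt[min(idx)]
  }
  median_age <- cross(0.5)
  max_age <- cross(1 - max_quantile)
  tibble(
    t_sex = t_sex,
    median_age = median_age,
    median_post_tsex = median_age - t_sex,
    max_age = max_age,
    max_post_tsex = max_age - t_sex,
    median_achieved = !is.na(median_age),
    max_achieved = !is.na(max_age),
    segment_ratio = (max_age - median_age) / (median_age - t_sex)
  )
}

#' First day the at-risk population drops below a threshold
#'
#' Scans the Kaplan-Meier step table for the first day after whose events
#' the number of animals still under observation falls below `threshold`.
#'
#' @param curve An `nmr_km` tibble.
#' @param threshold Positive integer population size.
#' @return The day-of-life (integer), or `NA` if the at-risk count never
#'   falls below `threshold` within the curve (always `NA` for
#'   `threshold <= 0`).
#' @export
at_risk_threshold_day <- function(curve, threshold) {
  if (threshold <= 0) return(NA_integer_)
  after <- curve$n_risk - curve$n_event - curve$n_censor
  idx <- which(after < threshold)
  if (length(idx) == 0L) NA_integer_ else curve$day[min(idx)]
}
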