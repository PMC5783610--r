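# Gompertz-Makeham and constant-hazard mortality models: closed forms,
# censoring-aware maximum likelihood, life-table ingestion and the
# reproductive-maturity-rescaled hazard axis.

#' Gompertz-Makeham parameter set
#'
#' The Gompertz-Makeham law gives the age-specific hazard
#' `h(t) = alpha * exp(beta * t) + gamma`: `alpha` scales the intrinsic
#' (aging) component, `beta` is the rate of aging (hazard doubling time
#' `ln(2)/beta`), and `gamma` is a constant extrinsic hazard.  `beta = 0`
#' and/or `alpha = 0` reduce the law to a constant hazard.
#'
#' @param alpha Intrinsic hazard coefficient, per day, `>= 0`.
#' @param beta Rate of aging, per day (may be 0).
#' @param gamma Extrinsic (Makeham) hazard, per day, `>= 0`.
#' @return A `gompertz_params` list.
#' @examples
#' # a human-like rate of aging: hazard doubling every 8 years
#' gompertz_params(alpha = 1e-5, beta = log(2) / (8 * 365.25), gamma = 1e-4)
#' @export
gompertz_params <- function(alpha, beta = 0, gamma = 0) {
  if (alpha < 0 || gamma < 0) abort("alpha and gamma must be non-negative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "gompertz_params")
}

#' Gompertz-Makeham hazard at an age
#'
#' @param params A [gompertz_params()] object.
#' @param t Age(s) in days, `>= 0`.
#' @return Per-day hazard `alpha * exp(beta * t) + gamma`.  Arguments that
#'   would overflow the exponential (`beta * t > 500`) raise an error
#'   rather than silently returning `Inf`.
#' @export
hazard_at <- function(params, t) {
  if (any(t < 0)) abort("t must be non-negative")
  if (any(params$beta * t > 500))
    abort("beta * t too large: hazard evaluation would overflow")
  params$alpha * exp(params$beta * t) + params$gamma
}

#' Survival probability under a constant per-day hazard
#'
#' @param lambda Per-day death probability in `[0, 1]`.
#' @param from_day,to_day Day span (`to_day >= from_day`).
#' @param form `"geometric"` (default) multiplies the daily survival
#'   probability, `(1 - lambda)^(to_day - from_day)`, matching a per-day
#'   Bernoulli death process; `"exponential"` uses the continuous form
#'   `exp(-lambda * (to_day - from_day))`.
#' @return Probability of surviving from `from_day` to `to_day`.
#' @export
constant_hazard_survival <- function(lambda, from_day, to_day,
                                     form = c("geometric", "exponential")) {
  form <- match.arg(form)
  if (any(lambda < 0 | lambda > 1)) abort("lambda must lie in [0, 1]")
  if (any(to_day < from_day)) abort("to_day must be >= from_day")
  span <- to_day - from_day
  switch(form,
         geometric = (1 - lambda)^span,
         exponential = exp(-lambda * span))
}

#' Median lifespan (half-life) under a constant hazard
#'
#' Under a never-increasing hazard the meaningful lifespan summary is a
#' half-life rather than a "maximal lifespan".  The continuous form
#' `ln(2) / lambda` is returned by default; the geometric (per-day
#' Bernoulli) variant `log(0.5) / log(1 - lambda)` is available.
#'
#' @param lambda Per-day hazard, `> 0` (0 returns `Inf`).
#' @param form `"continuous"` (default) or `"geometric"`.
#' @return Median lifespan in days.
#' @examples
#' constant_hazard_median(1e-4)  # ~6931 days, i.e. ~19 years
#' @export
constant_hazard_median <- function(lambda,
                                   form = c("continuous", "geometric")) {
  form <- match.arg(form)
  if (any(lambda < 0)) abort("lambda must be non-negative")
  out <- switch(form,
                continuous = log(2) / lambda,
                geometric = log(0.5) / log1p(-lambda))
  out[lambda == 0] <- Inf
  out
}

# duration under observation on the post-entry clock, counting the
# event/censor day itself (so the constant-model MLE equals the
# deaths/exposure estimator of interval_hazard exactly)
.obs_durations <- function(observations) {
  t <- observations$exit_day - observations$entry_day + 1
  if (any(t < 1)) abort("exit_day must be >= entry_day")
  as.numeric(t)
}

.cumhaz_gompertz <- function(a, b, t) {
  if (abs(b) < 1e-12) a * t else a / b * expm1(b * t)
}

.ll_gm <- function(a, b, g, t, dead) {
  if (a < 0 || g < 0) return(-Inf)
  if (b * max(t) > 500) return(-Inf)
  hz <- a * exp(b * t[dead]) + g
  if (any(hz <= 0)) return(-Inf)
  sum(log(hz)) - sum(.cumhaz_gompertz(a, b, t)) - g * sum(t)
}

#' Fit a mortality model to censored observations by maximum likelihood
#'
#' Fits a constant-hazard (exponential), Gompertz (`gamma = 0`) or full
#' Gompertz-Makeham hazard to right-censored lifespans on the post-entry
#' clock, using the continuous survival function
#' `S(t) = exp(-gamma t - alpha/beta (e^{beta t} - 1))`.  Durations count
#' the event day, so the constant model's closed-form MLE equals
#' deaths/exposure-days, the same estimator used by [interval_hazard()].
#' The constant model is nested in both richer models, so fitted
#' log-likelihoods are non-decreasing in model complexity and
#' likelihood-ratio tests via [mortality_lrt()] are well defined.
#'
#' @param observations Observation tibble (`entry_day`, `exit_day`,
#'   `event`); at least one death is required.
#' @param model `"constant"`, `"gompertz"` or `"gompertz_makeham"`.
#' @return An object of class `mortality_fit`: parameter tibble (`term`,
#'   `estimate`), `loglik`, `n`, `n_deaths`, `exposure`, `convergence`
#'   (0 = converged) and `near_zero_beta` (fitted `|beta|` below 1e-8/day).
#'   Supports [tidy()] and [glance()].
#' @examples
#' obs <- tibble::tibble(entry_day = 0,
#'                       exit_day = c(rexp(50, 1e-3), rep(2000, 20)),
#'                       event = rep(c("death", "censor"), c(50, 20)))
#' fit_mortality_model(obs, "constant")
#' @export
fit_mortality_model <- function(observations,
                                model = c("constant", "gompertz",
                                          "gompertz_makeham")) {
  model <- match.arg(model)
  t <- .obs_durations(observations)
  dead <- observations$event == "death"
  n_deaths <- sum(dead)
  if (n_deaths == 0L)
    abort("cannot fit a mortality model with zero death events")
  exposure <- sum(t)
  lambda_hat <- n_deaths / exposure

  if (model == "constant") {
    ll <- n_deaths * log(lambda_hat) - lambda_hat * exposure
    return(.new_mortality_fit(model,
                              tibble(term = "lambda", estimate = lambda_hat),
                              ll, length(t), n_deaths, exposure,
                              convergence = 0L, near_zero_beta = NA))
  }

  if (model == "gompertz") {
    obj <- function(par) -.ll_gm(exp(par[1]), par[2], 0, t, dead)
    starts <- list(c(log(lambda_hat), 1e-10), c(log(lambda_hat), 1e-4),
                   c(log(lambda_hat) - 2, 1e-3), c(log(lambda_hat) - 4, 5e-3))
  } else {
    obj <- function(par) -.ll_gm(exp(par[1]), par[2], exp(par[3]), t, dead)
    starts <- list(
      c(log(1e-12), 1e-10, log(lambda_hat)),     # constant-hazard degenerate
      c(log(lambda_hat / 2), 1e-4, log(lambda_hat / 2)),
      c(log(lambda_hat / 10), 1e-3, log(lambda_hat / 2)),
      c(log(lambda_hat / 100), 5e-3, log(lambda_hat / 2))
    )
  }

  best <- NULL
  for (s in starts) {
    fit <- suppressWarnings(
      optim(s, obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12))
    )
    # a start can itself dominate a stalled optimisation
    cand <- list(list(par = fit$par, value = fit$value,
                      convergence = fit$convergence),
                 list(par = s, value = obj(s), convergence = 0L))
    for (cc in cand) {
      if (is.null(best) || cc$value < best$value) best <- cc
    }
  }

  par <- best$par
  if (model == "gompertz") {
    params <- tibble(term = c("alpha", "beta"),
                     estimate = c(exp(par[1]), par[2]))
    beta_hat <- par[2]
  } else {
    params <- tibble(term = c("alpha", "beta", "gamma"),
                     estimate = c(exp(par[1]), par[2], exp(par[3])))
    beta_hat <- par[2]
  }
  .new_mortality_fit(model, params, -best$value, length(t), n_deaths,
                     exposure, convergence = best$convergence,
                     near_zero_beta = abs(beta_hat) < 1e-8)
}

.new_mortality_fit <- function(model, params, loglik, n, n_deaths, exposure,
                               convergence, near_zero_beta) {
  structure(list(model = model, params = params, loglik = loglik, n = n,
                 n_deaths = n_deaths, exposure = exposure,
                 convergence = convergence, near_zero_beta = near_zero_beta),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat("Mortality model fit (", x$model, ")\n", sep = "")
  cat("  n =", x$n, " deaths =", x$n_deaths,
      " exposure =", format(x$exposure), "animal-days\n")
  for (i in seq_len(nrow(x$params)))
    cat(sprintf("  %-6s %.6g\n", x$params$term[i], x$params$estimate[i]))
  cat("  log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested mortality models
#'
#' @param null_fit,alt_fit `mortality_fit` objects, `null_fit` nested in
#'   `alt_fit` (e.g. constant within Gompertz).
#' @return A one-row tibble: `statistic` (twice the log-likelihood
#'   difference), `df` (parameter-count difference) and `p_value` from the
#'   chi-squared reference distribution.
#' @export
mortality_lrt <- function(null_fit, alt_fit) {
  df <- nrow(alt_fit$params) - nrow(null_fit$params)
  if (df <= 0) abort("alt_fit must have more parameters than null_fit")
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' @method tidy mortality_fit
#' @export
tidy.mortality_fit <- function(x, ...) x$params

#' @method glance mortality_fit
#' @export
glance.mortality_fit <- function(x, ...) {
  tibble(model = x$model, logLik = x$loglik,
         AIC = 2 * nrow(x$params) - 2 * x$loglik,
         n = x$n, n_deaths = x$n_deaths, exposure = x$exposure,
         converged = x$convergence == 0L)
}

#' Draw lifespans from a Gompertz-Makeham hazard
#'
#' Inverse-CDF sampling from `h(t) = alpha e^{beta t} + gamma` on the
#' post-entry clock (closed form when `gamma = 0`; bisection otherwise).
#'
#' @param n Number of draws.
#' @param alpha,beta,gamma Hazard parameters (per day).
#' @return Numeric vector of event times in days since entry.
#' @export
rgompertz_makeham <- function(n, alpha, beta, gamma = 0) {
  u <- runif(n)
  target <- -log(u)
  if (gamma == 0 && abs(beta) > 1e-12) {
    log1p(beta * target / alpha) / beta
  } else if (abs(beta) < 1e-12) {
    target / (alpha + gamma)
  } else {
    cum <- function(t) .cumhaz_gompertz(alpha, beta, t) + gamma * t
    vapply(target, function(tg) {
      hi <- 1
      while (cum(hi) < tg) hi <- hi * 2
      stats::uniroot(function(t) cum(t) - tg, c(0, hi), tol = 1e-8)$root
    }, 0)
  }
}

#' Ingest (and optionally pool) species life tables
#'
#' A life table gives deaths and at-risk counts (or a precomputed hazard)
#' per contiguous age interval.  When several tables are combined, their
#' intervals must align exactly and numerators/denominators are pooled
#' before the hazard is recomputed, i.e. the pooled hazard is total deaths
#' over total at-risk per interval.
#'
#' @param tables A data frame or list of data frames with columns
#'   `age_start`, `age_end`, and either `deaths` + `at_risk` or `hazard`.
#' @param combine Pool multiple tables (default `TRUE`).
#' @param unit Time unit of the age columns (`"year"` or `"day"`).
#' @return A tibble of class `nmr_lifetable` with per-interval `hazard`.
#' @examples
#' t1 <- tibble::tibble(age_start = 0:2, age_end = 1:3,
#'                      deaths = c(5, 4, 3), at_risk = c(100, 90, 80))
#' life_table_hazard(t1)
#' @export
life_table_hazard <- function(tables, combine = TRUE,
                              unit = c("year", "day")) {
  unit <- match.arg(unit)
  if (is.data.frame(tables)) tables <- list(tables)
  tables <- lapply(tables, as_tibble)

  norm <- lapply(tables, function(tb) {
    if (!all(c("age_start", "age_end") %in% names(tb)))
      abort("life table needs age_start and age_end columns")
    if (any(diff(tb$age_start) <= 0) ||
        any(abs(tb$age_end[-nrow(tb)] - tb$age_start[-1]) > 1e-9))
      abort("life table intervals must be contiguous and ordered")
    if (all(c("deaths", "at_risk") %in% names(tb))) {
      tb[c("age_start", "age_end", "deaths", "at_risk")]
    } else if ("hazard" %in% names(tb)) {
      tibble(age_start = tb$age_start, age_end = tb$age_end,
             deaths = NA_real_, at_risk = NA_real_, hazard = tb$hazard)
    } else {
      abort("life table needs deaths+at_risk or hazard columns")
    }
  })

  if (length(norm) > 1L && combine) {
    ref <- norm[[1]][c("age_start", "age_end")]
    for (k in seq_along(norm)[-1]) {
      if (!isTRUE(all.equal(ref, norm[[k]][c("age_start", "age_end")],
                            check.attributes = FALSE))) {
        abort(paste0("cannot combine life tables: intervals of table ", k,
                     " do not match table 1"))
      }
      if (!all(c("deaths", "at_risk") %in% names(norm[[k]])) ||
          anyNA(norm[[k]]$deaths))
        abort("cannot pool a table that only provides precomputed hazards")
    }
    pooled <- norm[[1]]
    for (k in seq_along(norm)[-1]) {
      pooled$deaths <- pooled$deaths + norm[[k]]$deaths
      pooled$at_risk <- pooled$at_risk + norm[[k]]$at_risk
    }
    norm <- list(pooled)
  }
  out <- norm[[1]]
  if (!"hazard" %in% names(out)) out$hazard <- out$deaths / out$at_risk
  if (any(out$hazard < 0 | out$hazard > 1, na.rm = TRUE))
    abort("per-interval hazard must lie in [0, 1]")
  class(out) <- c("nmr_lifetable", class(out))
  attr(out, "unit") <- unit
  out
}

#' Survival curve from a life table by iterative multiplication
#'
#' Starting at the age of reproductive maturity, survival is the cumulative
#' product of one minus the age-specific hazard over successive intervals.
#'
#' @param table An `nmr_lifetable` from [life_table_hazard()].
#' @param t_sex Starting age, on the table's own unit; must coincide with
#'   an interval boundary inside the table's range.
#' @return A tibble of class `nmr_lifetable_surv` with columns `age` (the
#'   interval end ages, prefixed by `t_sex` itself) and `surv`
#'   (`surv = 1` at `t_sex`).  Feed to [lifespan_summary()] for median and
#'   maximal (95th percentile) post-maturity lifespans; percentiles the
#'   table does not reach are reported as not achieved.
#' @examples
#' lt <- life_table_hazard(tibble::tibble(age_start = 0:9, age_end = 1:10,
#'                                        hazard = rep(0.1, 10)))
#' survival_from_life_table(lt, t_sex = 0)
#' @export
survival_from_life_table <- function(table, t_sex) {
  if (t_sex < min(table$age_start) || t_sex >= max(table$age_end))
    abort("t_sex must lie within the life table's age range")
  keep <- table$age_start >= t_sex - 1e-9
  if (!any(abs(table$age_start - t_sex) < 1e-9))
    abort("t_sex must coincide with a life-table interval boundary")
  sub <- table[keep, ]
  out <- tibble(age = c(t_sex, sub$age_end),
                surv = c(1, cumprod(1 - sub$hazard)))
  class(out) <- c("nmr_lifetable_surv", class(out))
  attr(out, "t_sex") <- t_sex
  attr(out, "unit") <- attr(table, "unit")
  out
}

#' Convert an annual hazard to a per-day hazard
#'
#' @param q Annual event probability in `[0, 1]`.
#' @param method `"compound"` (default) solves `(1 - q) = (1 - h)^365.25`;
#'   `"simple"` divides by 365.25.
#' @return Per-day hazard.
#' @export
annual_to_daily_hazard <- function(q, method = c("compound", "simple")) {
  method <- match.arg(method)
  if (any(q < 0 | q > 1)) abort("q must lie in [0, 1]")
  switch(method,
         compound = 1 - (1 - q)^(1 / 365.25),
         simple = q / 365.25)
}

#' Rescale a hazard series onto a reproductive-maturity-multiple axis
#'
#' Divides every age/time column by the species' age of reproductive
#' maturity so that hazard trajectories of species with very different
#' absolute lifespans can be overlaid; hazard values are untouched.
#'
#' @param x A data frame with one or more age columns among `day`, `age`,
#'   `bin_start`, `bin_end`, `age_start`, `age_end`.
#' @param t_sex Age of reproductive maturity in the same unit as the age
#'   columns (`> 0`).
#' @return `x` with the age columns divided by `t_sex` and an added
#'   attribute `t_sex`.
#' @export
rescale_by_tsex <- function(x, t_sex) {
  if (t_sex <= 0) abort("t_sex must be positive")
  cols <- intersect(c("day", "age", "bin_start", "bin_end",
                      "age_start", "age_end"), names(x))
  if (length(cols) == 0L) abort("no age columns found to rescale")
  for (cc in cols) x[[cc]] <- x[[cc]] / t_sex
  attr(x, "t_sex") <- t_sex
  x
}
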