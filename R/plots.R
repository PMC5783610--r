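# ggplot2 displays for the result types.

#' @import ggplot2
NULL

#' Plot a Kaplan-Meier survival curve
#'
#' @param object An `nmr_km` tibble.
#' @param ... Unused.
#' @return A ggplot: survival step curve on the day-of-life axis.
#' @method autoplot nmr_km
#' @export
autoplot.nmr_km <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$day, y = .data$surv)) +
    geom_step(colour = "#2a7e43", linewidth = 0.7) +
    scale_y_continuous(limits = c(0, 1), labels = function(x) paste0(100 * x, "%")) +
    labs(x = "Day of life", y = "Surviving fraction") +
    theme_minimal()
}

#' Plot age-binned hazard estimates with confidence intervals
#'
#' @param object An `nmr_hazard` tibble.
#' @param log_y Use a log10 hazard axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot: per-day hazard per bin with Wilson interval bars.
#' @method autoplot nmr_hazard
#' @export
autoplot.nmr_hazard <- function(object, log_y = TRUE, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  p <- ggplot(df[!df$undefined, ],
              aes(x = .data$mid, y = .data$hazard)) +
    geom_segment(aes(x = .data$bin_start, xend = .data$bin_end,
                     yend = .data$hazard), colour = "#2a7e43") +
    geom_errorbar(aes(ymin = pmax(.data$ci_low, 1e-7),
                      ymax = .data$ci_high),
                  width = 0, linetype = "dotted", colour = "#2a7e43") +
    labs(x = "Day of life",
         y = sprintf("Per-day %s probability",
                     attr(object, "event_of_interest") %||% "event")) +
    theme_minimal()
  if (log_y) p <- p + scale_y_log10()
  p
}

#' Plot a simulation-ensemble survival envelope
#'
#' @param object An `nmr_envelope` tibble.
#' @param observed Optional observed `nmr_km` curve to overlay.
#' @param ... Unused.
#' @return A ggplot: 5th-95th percentile ribbon, interquartile ribbon and
#'   median of simulated survival, with the observed curve on top if given.
#' @method autoplot nmr_envelope
#' @export
autoplot.nmr_envelope <- function(object, observed = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$day)) +
    geom_ribbon(aes(ymin = .data$p5, ymax = .data$p95), fill = "grey80") +
    geom_ribbon(aes(ymin = .data$q1, ymax = .data$q3), fill = "grey60") +
    geom_line(aes(y = .data$median), colour = "grey30") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Day of life", y = "Surviving fraction") +
    theme_minimal()
  if (!is.null(observed)) {
    p <- p + geom_step(data = as_tibble(observed),
                       aes(x = .data$day, y = .data$surv),
                       colour = "#c0392b", linewidth = 0.7)
  }
  p
}

#' Overlay species hazard trajectories on a maturity-rescaled axis
#'
#' @param series Named list of hazard tibbles already passed through
#'   [rescale_by_tsex()] (columns `bin_start`/`bin_end` or `age_start`/
#'   `age_end` in maturity multiples, plus `hazard`).
#' @return A ggplot of hazard (log10) against multiples of the age of
#'   reproductive maturity.
#' @export
plot_rescaled_hazards <- function(series) {
  df <- dplyr::bind_rows(lapply(names(series), function(nm) {
    x <- as_tibble(series[[nm]])
    s <- intersect(c("bin_start", "age_start"), names(x))[1]
    e <- intersect(c("bin_end", "age_end"), names(x))[1]
    tibble(species = nm, start = x[[s]], end = x[[e]], hazard = x$hazard)
  }))
  ggplot(df, aes(colour = .data$species)) +
    geom_segment(aes(x = .data$start, xend = .data$end,
                     y = .data$hazard, yend = .data$hazard)) +
    scale_y_log10() +
    labs(x = "Multiples of age at reproductive maturity",
         y = "Per-unit-time mortality hazard") +
    theme_minimal()
}
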