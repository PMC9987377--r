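# Monitoring-frequency sensitivity: re-estimate the total-activity-counts
# trajectory under cyclic reduced monitoring schedules (wD weeks of data,
# then wB weeks of break, repeating, anchored at each participant's own
# baseline day) and compare against the all-data fit.

#' The standard monitoring scenarios
#'
#' "all" plus the eight wD/wB cycles: 2 weeks data with 2/4/6/8-week breaks
#' and 1 week data with 2/4/6/8-week breaks.
#'
#' @return data.frame with columns label, weeks_data, weeks_break
#' @export
monitoring_scenarios <- function() {
  data.frame(
    label = c("all", "2wD+2wB", "2wD+4wB", "2wD+6wB", "2wD+8wB",
              "1wD+2wB", "1wD+4wB", "1wD+6wB", "1wD+8wB"),
    weeks_data = c(NA, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L),
    weeks_break = c(NA, 2L, 4L, 6L, 8L, 2L, 4L, 6L, 8L),
    stringsAsFactors = FALSE)
}

#' Days retained under a monitoring scenario
#'
#' Cyclic pattern anchored at each participant's day 0: keep the first
#' `weeks_data` weeks, drop the next `weeks_break` weeks, repeat. Weeks are
#' 7-day blocks of participant time, not calendar weeks. The "all" scenario
#' keeps everything.
#'
#' @param day_offsets integer days since the participant's baseline (0-based)
#' @param scenario one row of [monitoring_scenarios()] (or a list with
#'   `label`, `weeks_data`, `weeks_break`)
#' @return logical vector: TRUE where the day is retained
#' @export
scenario_mask <- function(day_offsets, scenario) {
  stopifnot(all(day_offsets >= 0))
  if (identical(scenario$label, "all")) return(rep(TRUE, length(day_offsets)))
  wd <- scenario$weeks_data; wb <- scenario$weeks_break
  stopifnot(wd >= 1, wb >= 0)
  cycle <- 7L * (wd + wb)
  (day_offsets %% cycle) < 7L * wd
}

#' Run the monitoring-frequency sensitivity analysis
#'
#' For each scenario, fits the trajectory LMM (measure ~ time, participant
#' random intercept and slope) on the retained days and reports the
#' baseline and monthly-change estimates, their percent deviation from the
#' all-data fit, and the slope's significance. Participants left with fewer
#' than 2 retained days are dropped from that scenario (with a message).
#'
#' @param daily long-format daily measure table (one measure, or filtered
#'   via `measure`)
#' @param measure measure name to analyze (default `"tac"`)
#' @param scenarios data.frame as [monitoring_scenarios()]
#' @param alpha significance level for the slope flag
#' @return data.table: label, baseline_est, slope_est, baseline_pct_dev,
#'   slope_pct_dev, slope_p, slope_significant, n_participants, n_days
#' @export
run_sensitivity <- function(daily, measure = "tac",
                            scenarios = monitoring_scenarios(),
                            alpha = 0.05) {
  daily <- data.table::as.data.table(daily)
  ms <- measure  # avoid capture by the `measure` column inside data.table
  d <- daily[daily$measure == ms & !is.na(daily$value), ]
  if (nrow(d) == 0)
    stop(sprintf("no daily values for measure '%s'", measure), call. = FALSE)
  d[, day_offset := as.integer(date - min(date)), by = participant_id]
  d$t_months <- d$day_offset / DAYS_PER_MONTH

  fit_scenario <- function(sc) {
    keep <- scenario_mask(d$day_offset, sc)
    dd <- d[keep]
    n_days_per <- table(dd$participant_id)
    drop <- names(n_days_per)[n_days_per < 2L]
    if (length(drop)) {
      message(sprintf("scenario %s: dropping %d participant(s) with < 2 retained days",
                      sc$label, length(drop)))
      dd <- dd[!dd$participant_id %in% drop]
    }
    fit <- fit_lmm(dd, outcome = "value", fixed = "t_months")
    est <- fit$fixed
    list(fit = fit,
         baseline = est$estimate[est$term == "(Intercept)"],
         slope = est$estimate[est$term == "t_months"],
         slope_p = est$p[est$term == "t_months"],
         n_participants = fit$n_participants, n_days = fit$n_obs)
  }

  res <- lapply(seq_len(nrow(scenarios)), function(i)
    fit_scenario(as.list(scenarios[i, ])))
  ref <- res[[which(scenarios$label == "all")]]
  data.table::rbindlist(lapply(seq_along(res), function(i) {
    r <- res[[i]]
    data.table::data.table(
      label = scenarios$label[i],
      baseline_est = r$baseline,
      slope_est = r$slope,
      baseline_pct_dev = 100 * abs(r$baseline - ref$baseline) / abs(ref$baseline),
      slope_pct_dev = 100 * abs(r$slope - ref$slope) / abs(ref$slope),
      slope_p = r$slope_p,
      slope_significant = !is.na(r$slope_p) & r$slope_p < alpha,
      n_participants = r$n_participants,
      n_days = r$n_days)
  }))
}
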