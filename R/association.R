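# Association between daily wearable measures and survey scores: each
# survey observation gets a covariate equal to the mean of the daily
# measure over the 15-day window centred on the survey date (7 days before
# and after, inclusive), standardized to zero mean and unit SD over the
# observations entering that model. The LMM is
#   score ~ covariate + (1 + covariate | participant),
# i.e. the random slope is on the covariate (per-participant association
# heterogeneity); time is not a fixed effect in these models.

#' Build windowed covariates for the association models
#'
#' For every (survey observation, measure) pair, averages the daily
#' measure's valid-day values over the window `[date - half_window,
#' date + half_window]` (inclusive; 15 calendar days at the default).
#' Surveys with no valid day in the window get `NA` and are dropped from
#' that measure's model.
#'
#' @param daily long-format daily measure table from [derive_all()]
#' @param surveys survey observations
#' @param half_window days on either side of the survey date (default 7)
#' @return data.table: participant_id, date, instrument, score, t_months,
#'   measure, covariate (raw window mean), n_days_in_window
#' @export
build_covariates <- function(daily, surveys, half_window = 7) {
  daily <- data.table::as.data.table(daily)
  surveys <- data.table::as.data.table(surveys)
  measures <- unique(daily$measure)
  out <- data.table::rbindlist(lapply(measures, function(ms) {
    dm <- daily[daily$measure == ms & !is.na(daily$value), ]
    res <- surveys[, c("participant_id", "date", "instrument",
                       "score", "t_months"), with = FALSE]
    cov <- numeric(nrow(res)); nd <- integer(nrow(res))
    for (i in seq_len(nrow(res))) {
      w <- dm[dm$participant_id == res$participant_id[i] &
                dm$date >= res$date[i] - half_window &
                dm$date <= res$date[i] + half_window, ]
      nd[i] <- nrow(w)
      cov[i] <- if (nrow(w)) mean(w$value) else NA_real_
    }
    res$measure <- ms
    res$covariate <- cov
    res$n_days_in_window <- nd
    res
  }))
  out
}

#' Standardize a covariate to zero mean and unit SD
#'
#' Pooled over all observations entering the model (not within
#' participant). SD uses the n-1 denominator. Constant input is an error:
#' the measure carries no information.
#'
#' @param x numeric vector (NAs passed through)
#' @return standardized vector
#' @export
standardize <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2L)
    stop("standardization needs >= 2 non-missing values", call. = FALSE)
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0)
    stop("covariate has zero spread; measure is uninformative", call. = FALSE)
  (x - mean(obs)) / s
}

#' Fit all measure-survey association models
#'
#' One LMM per (measure, instrument) combination present in the inputs:
#' survey score on the standardized windowed covariate, with participant
#' random intercept and random slope on the covariate. Records the
#' covariate estimate, CI, p, R2m/R2c, and a per-measure flag for
#' significance (p < 0.05) with both survey instruments.
#'
#' @param covariates table from [build_covariates()]
#' @param instruments survey instruments to model (default ALSFRS-RSE and
#'   ROADS)
#' @param alpha significance level for the both-surveys flag
#' @return data.table: measure, instrument, n_obs, estimate, ci_lo, ci_hi,
#'   p, r2m, r2c, converged, significant_both
#' @export
fit_associations <- function(covariates,
                             instruments = c("alsfrs_rse", "roads"),
                             alpha = 0.05) {
  covariates <- data.table::as.data.table(covariates)
  combos <- unique(covariates[instrument %in% instruments & !is.na(covariate),
                              c("measure", "instrument"), with = FALSE])
  if (nrow(combos) == 0)
    stop("no non-missing covariate observations for the requested instruments",
         call. = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    d <- covariates[covariates$measure == combos$measure[i] &
                      covariates$instrument == combos$instrument[i] &
                      !is.na(covariates$covariate), ]
    d$z <- standardize(d$covariate)
    fit <- tryCatch(
      fit_lmm(d, outcome = "score", fixed = "z", random_slope = "z"),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.table::data.table(
        measure = combos$measure[i], instrument = combos$instrument[i],
        n_obs = nrow(d), estimate = NA_real_, ci_lo = NA_real_,
        ci_hi = NA_real_, p = NA_real_, r2m = NA_real_, r2c = NA_real_,
        converged = FALSE))
    est <- fit$fixed[fit$fixed$term == "z", ]
    data.table::data.table(
      measure = combos$measure[i], instrument = combos$instrument[i],
      n_obs = fit$n_obs, estimate = est$estimate,
      ci_lo = est$ci_lo, ci_hi = est$ci_hi, p = est$p,
      r2m = fit$r2m, r2c = fit$r2c, converged = fit$converged)
  })
  out <- data.table::rbindlist(rows)
  sig <- out[, .(significant_both =
                   sum(!is.na(p) & p < alpha) == length(instruments) &&
                   .N == length(instruments)), by = measure]
  merge(out, sig, by = "measure")[order(measure, instrument)]
}
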