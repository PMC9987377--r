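# Study-level configuration: every generator and pipeline parameter with its
# default. Defaults encode the study conditions the package emulates: a
# 40-participant, 6-month ambulatory ALS cohort split evenly between a
# wrist-worn activity-count device ("actigraph") and an ankle-worn step-count
# device ("modus"), surveyed by smartphone every 2-4 weeks.

#' Days per month used to convert elapsed days to months
#'
#' Mean Gregorian month length, so that 6 months corresponds to ~182.6 days.
#' @export
DAYS_PER_MONTH <- 30.4375

#' Build a cohort configuration
#'
#' Returns the full parameter set controlling the synthetic cohort generator
#' and the downstream pipeline. Defaults are the population estimates the
#' models are expected to recover: survey baselines and monthly slopes
#' (staff ALSFRS-R 31.6 / -0.37, self-entry offset +2.86 with slope -0.48,
#' ROADS normed 84.9 / -1.26) and the activity-volume trajectory (daily total
#' activity counts 1,362,438 baseline, -58,631 per month).
#'
#' The self-entry ALSFRS (ALSFRS-RSE) is generated from the same latent
#' functional scale as the staff-administered ALSFRS-R: it adds the
#' `self_report_offset` to the staff baseline and uses its own slope, and the
#' two share participant random effects (they measure the same construct,
#' which is what makes them highly correlated within participant).
#'
#' @param n_participants number of participants (default 40)
#' @param observation_days length of follow-up in days (default 180)
#' @param device_split fraction assigned to the actigraph-like device
#' @param survey_interval_days length-2 integer range (days) between
#'   consecutive smartphone survey events, drawn uniformly per interval
#' @param instruments named list of per-instrument parameters; see Details
#' @param self_report_offset points added to the staff ALSFRS baseline for
#'   the self-entry version
#' @param activity list of activity-trajectory parameters (actigraph arm)
#' @param steps list of step-trajectory parameters (modus arm)
#' @param missingness list of non-wear / charging-gap parameters
#' @param latent_coupling in [0, 1]; loading of the shared latent severity
#'   process on both survey and activity random effects. 0 decouples them.
#' @param active_threshold activity-count cut: a minute is active iff AC
#'   strictly exceeds this (default 1853)
#' @param cadence_bands integer edges of the low/medium/high step bands,
#'   inclusive: low = 1..15, medium = 16..40, high = 41+
#' @param round_scores round survey scores to integers (instruments are
#'   integer-scored); disable for exact noiseless trajectories
#' @param start_date calendar date of study day 0
#' @param master_seed integer seed; every stochastic draw derives from it
#'
#' @details `instruments` entries (`alsfrs_r`, `alsfrs_rse`, `roads`) carry:
#'   `baseline` (points; `alsfrs_rse` derives its baseline as the staff
#'   baseline + offset and ignores its own entry), `slope_month`
#'   (points/month), `b0_sd`, `b1_sd` (random intercept/slope SDs),
#'   `b_corr` (intercept-slope correlation of the idiosyncratic component),
#'   `resid_sd` (residual SD) and `range` (admissible score range).
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_participants = 40L,
                          observation_days = 180L,
                          device_split = 0.5,
                          survey_interval_days = c(14L, 28L),
                          instruments = NULL,
                          self_report_offset = 2.86,
                          activity = NULL,
                          steps = NULL,
                          missingness = NULL,
                          latent_coupling = 0.6,
                          active_threshold = 1853,
                          cadence_bands = c(low_lo = 1L, low_hi = 15L,
                                            med_hi = 40L),
                          round_scores = TRUE,
                          start_date = as.Date("2021-01-01"),
                          master_seed = 20210101L) {
  defaults <- list(
    alsfrs_r  = list(baseline = 31.6, slope_month = -0.37,
                     b0_sd = 6, b1_sd = 0.5, b_corr = 0,
                     resid_sd = 1.5, range = c(0, 48)),
    alsfrs_rse = list(baseline = NA_real_, slope_month = -0.48,
                      b0_sd = 6, b1_sd = 0.5, b_corr = 0,
                      resid_sd = 1.5, range = c(0, 48)),
    roads = list(baseline = 84.9, slope_month = -1.26,
                 b0_sd = 15, b1_sd = 1.4, b_corr = 0,
                 resid_sd = 3, range = c(0, 146))
  )
  instruments <- modify_defaults(defaults, instruments)
  # self-entry baseline derives from the shared functional scale
  instruments$alsfrs_rse$baseline <-
    instruments$alsfrs_r$baseline + self_report_offset

  activity <- modify_defaults(list(
    tac_baseline = 1362438, tac_slope_month = -58631,
    b0_sd = 4e5, b1_sd = 2.5e4, b_corr = 0,
    daily_sd = 2e5,
    minute_shape = 1,        # gamma shape of minute-level noise (CV = 1/sqrt)
    wake_start = 6, wake_end = 22,  # hours of the circadian activity window
    night_mass = 0.02        # share of daily activity spent outside it
  ), activity)

  steps <- modify_defaults(list(
    steps_baseline = 1871, steps_slope_month = -57.79,
    b0_sd = 600, b1_sd = 30, b_corr = 0,
    daily_sd = 250,
    mean_cadence = 9.35,     # mean steps/minute over stepping minutes
    cadence_size = 0.9,      # NB dispersion of (cadence - 1)
    wake_start = 7, wake_end = 21,
    night_mass = 0.005
  ), steps)

  missingness <- modify_defaults(list(
    charge_gap_prob = 0.15,   # P(a day contains a charging gap)
    charge_gap_minutes = 240L,
    nonwear_rate = 1,         # mean non-wear blocks/day (Poisson)
    nonwear_minutes = 60L,    # mean block length (geometric)
    offday_prob_actigraph = 0.10,  # device fully off all day
    offday_prob_modus = 0.15
  ), missingness)

  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    observation_days = as.integer(observation_days),
    device_split = device_split,
    survey_interval_days = as.integer(survey_interval_days),
    instruments = instruments,
    self_report_offset = self_report_offset,
    activity = activity,
    steps = steps,
    missingness = missingness,
    latent_coupling = latent_coupling,
    active_threshold = active_threshold,
    cadence_bands = cadence_bands,
    round_scores = isTRUE(round_scores),
    start_date = as.Date(start_date),
    master_seed = as.integer(master_seed)
  ), class = "cohort_config")
  validate_config(cfg)
  cfg
}

modify_defaults <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  stopifnot(is.list(user))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  fail <- function(field, why)
    stop(sprintf("invalid configuration: `%s` %s", field, why), call. = FALSE)
  if (!is.finite(cfg$n_participants) || cfg$n_participants < 1L)
    fail("n_participants", "must be >= 1")
  if (!is.finite(cfg$observation_days) || cfg$observation_days < 1L)
    fail("observation_days", "must be >= 1")
  if (cfg$device_split < 0 || cfg$device_split > 1)
    fail("device_split", "must lie in [0, 1]")
  si <- cfg$survey_interval_days
  if (length(si) != 2L || si[1] <= 0L || si[1] > si[2])
    fail("survey_interval_days", "must satisfy 0 < lo <= hi")
  for (nm in names(cfg$instruments)) {
    ins <- cfg$instruments[[nm]]
    sds <- c(ins$b0_sd, ins$b1_sd, ins$resid_sd)
    if (any(!is.finite(sds)) || any(sds < 0))
      fail(paste0("instruments$", nm), "has a negative or non-finite SD")
    if (abs(ins$b_corr) > 1)
      fail(paste0("instruments$", nm, "$b_corr"), "must lie in [-1, 1]")
  }
  for (blk in c("activity", "steps")) {
    sds <- unlist(cfg[[blk]][c("b0_sd", "b1_sd", "daily_sd")])
    if (any(!is.finite(sds)) || any(sds < 0))
      fail(blk, "has a negative or non-finite SD")
  }
  if (cfg$latent_coupling < 0 || cfg$latent_coupling > 1)
    fail("latent_coupling", "must lie in [0, 1]")
  if (cfg$missingness$charge_gap_prob < 0 || cfg$missingness$charge_gap_prob > 1)
    fail("missingness$charge_gap_prob", "must lie in [0, 1]")
  invisible(cfg)
}

# Deterministic, participant-keyed seed so adding a participant never
# perturbs the streams of the others. Products stay below 2^53, results
# below 2^31.
participant_seed <- function(master_seed, participant_index) {
  as.integer((as.numeric(master_seed) %% 2147483629 * 48271 +
                as.numeric(participant_index) * 40503) %% 2147483629) + 1L
}
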