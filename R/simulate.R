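# Synthetic cohort generator. Emulates a 6-month remote ALS study: each
# participant wears either an activity-count device ("actigraph": minute AC
# with wear/missing flags) or a step-count device ("modus": minute step sums,
# no epoch wear flag), and answers self-entry surveys (ALSFRS-RSE, ROADS)
# every 2-4 weeks, with staff-administered ALSFRS-R at months 0/3/6.
#
# A per-participant latent severity process (standard-normal intercept and
# slope loadings z0, z1) feeds both the survey and the activity random
# effects with loading `latent_coupling`, so activity volume and functional
# scores decline together, as observed in ALS cohorts.

#' Circadian weight profile over the 1440 minutes of a day
#'
#' Unimodal sin^2 bump across the waking window, with a small uniform share
#' (`night_mass`) outside it; weights sum to 1.
#'
#' @param wake_start,wake_end waking window in hours (0-24)
#' @param night_mass share of total mass spent outside the window
#' @return numeric vector of length 1440 summing to 1
#' @export
circadian_weights <- function(wake_start = 6, wake_end = 22,
                              night_mass = 0.02) {
  h <- (0:1439 + 0.5) / 60
  w <- numeric(1440)
  inside <- h >= wake_start & h < wake_end
  w[inside] <- sin(pi * (h[inside] - wake_start) / (wake_end - wake_start))^2
  if (sum(w) > 0) w <- w / sum(w) * (1 - night_mass)
  n_out <- sum(!inside)
  if (n_out > 0) w[!inside] <- night_mass / n_out
  w
}

# Bivariate random effect (b0, b1): a coupled share loads on the shared
# latent (z0, z1), the idiosyncratic share carries the configured
# intercept-slope correlation.
draw_random_effects <- function(z0, z1, b0_sd, b1_sd, b_corr, coupling) {
  e0 <- stats::rnorm(1)
  e1 <- stats::rnorm(1)
  e1 <- b_corr * e0 + sqrt(max(0, 1 - b_corr^2)) * e1
  w <- coupling
  c(b0 = b0_sd * (w * z0 + sqrt(1 - w^2) * e0),
    b1 = b1_sd * (w * z1 + sqrt(1 - w^2) * e1))
}

#' Generate one participant profile
#'
#' Draws the latent severity loadings and every instrument's and the activity
#' model's random intercept/slope for one participant, using that
#' participant's own RNG substream.
#'
#' @param config a [cohort_config()]
#' @param participant_index 1-based index
#' @return list of class `participant_profile`
#' @export
generate_profile <- function(config, participant_index) {
  n_acti <- round(config$n_participants * config$device_split)
  device <- if (participant_index <= n_acti) "actigraph" else "modus"
  set.seed(participant_seed(config$master_seed, 2L * participant_index))
  z0 <- stats::rnorm(1); z1 <- stats::rnorm(1)
  w <- config$latent_coupling

  # ALSFRS-R and ALSFRS-RSE measure the same construct: shared effects
  ia <- config$instruments$alsfrs_r
  alsfrs <- draw_random_effects(z0, z1, ia$b0_sd, ia$b1_sd, ia$b_corr, w)
  ir <- config$instruments$roads
  roads <- draw_random_effects(z0, z1, ir$b0_sd, ir$b1_sd, ir$b_corr, w)

  if (device == "actigraph") {
    am <- config$activity
    act <- draw_random_effects(z0, z1, am$b0_sd, am$b1_sd, am$b_corr, w)
  } else {
    sm <- config$steps
    act <- draw_random_effects(z0, z1, sm$b0_sd, sm$b1_sd, sm$b_corr, w)
  }
  structure(list(
    participant_id = sprintf("P%03d", participant_index),
    participant_index = participant_index,
    device = device,
    z0 = z0, z1 = z1,
    alsfrs_b0 = unname(alsfrs["b0"]), alsfrs_b1 = unname(alsfrs["b1"]),
    roads_b0 = unname(roads["b0"]), roads_b1 = unname(roads["b1"]),
    activity_b0 = unname(act["b0"]), activity_b1 = unname(act["b1"])
  ), class = "participant_profile")
}

#' Generate one participant-day minute grid
#'
#' Draws a single day of minute-level device data from the ambient RNG
#' stream. For the actigraph arm the day's latent total activity count is
#' the participant's linear trajectory plus daily noise, spread over minutes
#' by the circadian profile with multiplicative gamma noise (mean-preserving,
#' non-negative); non-wear and charging gaps are then overlaid. For the modus
#' arm each minute is a stepping minute with circadian probability and
#' stepping minutes carry a shifted negative-binomial cadence.
#'
#' @param profile a [generate_profile()] result
#' @param day_index 0-based day within the observation period
#' @param config a [cohort_config()]
#' @return list of class `minute_day` with `value` (length 1440; NA where
#'   missing), `wear` (logical, actigraph only; NULL for modus), `missing`
#'   (logical length 1440)
#' @export
generate_minute_day <- function(profile, day_index, config) {
  stopifnot(day_index >= 0, day_index < config$observation_days)
  t_m <- day_index / DAYS_PER_MONTH
  mis <- config$missingness
  if (profile$device == "actigraph") {
    am <- config$activity
    mu_day <- am$tac_baseline + profile$activity_b0 +
      (am$tac_slope_month + profile$activity_b1) * t_m
    tac <- max(0, mu_day + if (am$daily_sd > 0) stats::rnorm(1, 0, am$daily_sd) else 0)
    wgt <- circadian_weights(am$wake_start, am$wake_end, am$night_mass)
    mu <- tac * wgt
    k <- am$minute_shape
    value <- if (is.finite(k) && k > 0) {
      stats::rgamma(1440, shape = k, scale = pmax(mu, 1e-12) / k)
    } else mu
    wear <- rep(TRUE, 1440)
    missing <- rep(FALSE, 1440)
    # full-day device-off
    if (stats::runif(1) < mis$offday_prob_actigraph) {
      wear[] <- FALSE
      value[] <- 0
    } else {
      # charging gap: data not recorded at all
      if (stats::runif(1) < mis$charge_gap_prob && mis$charge_gap_minutes > 0) {
        len <- min(mis$charge_gap_minutes, 1440L)
        s <- sample.int(1440L - len + 1L, 1L)
        missing[s:(s + len - 1L)] <- TRUE
        wear[s:(s + len - 1L)] <- FALSE
      }
      # short non-wear blocks: device on a table records ~no movement
      n_blocks <- stats::rpois(1, mis$nonwear_rate)
      for (b in seq_len(n_blocks)) {
        len <- min(1L + stats::rgeom(1, 1 / max(1, mis$nonwear_minutes)), 1440L)
        s <- sample.int(1440L - len + 1L, 1L)
        wear[s:(s + len - 1L)] <- FALSE
        value[s:(s + len - 1L)] <- 0
      }
    }
    value[missing] <- NA_real_
    structure(list(value = value, wear = wear, missing = missing,
                   device = "actigraph"), class = "minute_day")
  } else {
    sm <- config$steps
    mu_day <- sm$steps_baseline + profile$activity_b0 +
      (sm$steps_slope_month + profile$activity_b1) * t_m
    s_day <- max(0, mu_day + if (sm$daily_sd > 0) stats::rnorm(1, 0, sm$daily_sd) else 0)
    wgt <- circadian_weights(sm$wake_start, sm$wake_end, sm$night_mass)
    # expected stepping minutes scaled so E[daily steps] = s_day
    q <- pmin(1, wgt * s_day / sm$mean_cadence)
    value <- numeric(1440)
    if (stats::runif(1) >= mis$offday_prob_modus && s_day > 0) {
      stepping <- stats::runif(1440) < q
      n_step <- sum(stepping)
      if (n_step > 0) {
        value[stepping] <- 1 + stats::rnbinom(n_step, size = sm$cadence_size,
                                              mu = max(sm$mean_cadence - 1, 0))
      }
    }
    structure(list(value = value, wear = NULL,
                   missing = rep(FALSE, 1440), device = "modus"),
              class = "minute_day")
  }
}

#' Generate all wearable days for one participant
#'
#' Minute grids for the whole observation period as 1440-by-days matrices,
#' drawn from the participant's wearable RNG substream (independent of the
#' survey substream and of every other participant).
#'
#' @param profile a [generate_profile()] result
#' @param config a [cohort_config()]
#' @return a `wearable_participant` record
#' @export
generate_participant_wearable <- function(profile, config) {
  D <- config$observation_days
  set.seed(participant_seed(config$master_seed,
                            2L * profile$participant_index + 1L))
  value <- matrix(NA_real_, 1440, D)
  missing <- matrix(FALSE, 1440, D)
  wear <- if (profile$device == "actigraph") matrix(TRUE, 1440, D) else NULL
  for (d in seq_len(D)) {
    day <- generate_minute_day(profile, d - 1L, config)
    value[, d] <- day$value
    missing[, d] <- day$missing
    if (!is.null(wear)) wear[, d] <- day$wear
  }
  structure(list(
    participant_id = profile$participant_id,
    device = profile$device,
    dates = config$start_date + 0:(D - 1L),
    value = value, wear = wear, missing = missing
  ), class = "wearable_participant")
}

#' Generate one participant's survey trajectory
#'
#' Scores follow baseline + monthly slope plus the participant's random
#' intercept and slope, with instrument residual noise, then (optionally)
#' integer rounding and clipping to the instrument's admissible range. The
#' self-entry ALSFRS shares the staff random effects and adds the configured
#' self-report offset via its derived baseline.
#'
#' @param profile a [generate_profile()] result
#' @param schedule data.frame with columns `day` (0-based) and `instrument`
#' @param config a [cohort_config()]
#' @return data.table of survey observations
#' @export
generate_survey_trajectory <- function(profile, schedule, config) {
  stopifnot(nrow(schedule) > 0,
            all(schedule$day >= 0 & schedule$day < config$observation_days))
  t_m <- schedule$day / DAYS_PER_MONTH
  score <- numeric(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    ins <- config$instruments[[schedule$instrument[i]]]
    b0 <- if (schedule$instrument[i] == "roads") profile$roads_b0 else profile$alsfrs_b0
    b1 <- if (schedule$instrument[i] == "roads") profile$roads_b1 else profile$alsfrs_b1
    y <- ins$baseline + b0 + (ins$slope_month + b1) * t_m[i] +
      if (ins$resid_sd > 0) stats::rnorm(1, 0, ins$resid_sd) else 0
    if (config$round_scores) y <- round(y)
    score[i] <- min(max(y, ins$range[1]), ins$range[2])
  }
  data.table::data.table(
    participant_id = profile$participant_id,
    date = config$start_date + schedule$day,
    day = as.integer(schedule$day),
    t_months = t_m,
    instrument = schedule$instrument,
    nominal_month = schedule$nominal_month,
    score = score
  )
}

# Survey event days: baseline at day 0, then uniform 2-4 week intervals
# (self-entry instruments each event); staff ALSFRS-R at months 0/3/6.
survey_schedule <- function(config) {
  D <- config$observation_days
  lo <- config$survey_interval_days[1]; hi <- config$survey_interval_days[2]
  days <- 0L
  repeat {
    nxt <- days[length(days)] + sample(lo:hi, 1L)
    if (nxt > D - 1L) break
    days <- c(days, nxt)
  }
  self <- data.frame(
    day = rep(days, each = 2L),
    instrument = rep(c("alsfrs_rse", "roads"), length(days)),
    nominal_month = NA_real_, stringsAsFactors = FALSE)
  staff_days <- pmin(round(c(0, 3, 6) * DAYS_PER_MONTH), D - 1L)
  staff <- data.frame(day = unique(staff_days),
                      instrument = "alsfrs_r",
                      nominal_month = c(0, 3, 6)[!duplicated(staff_days)],
                      stringsAsFactors = FALSE)
  rbind(self, staff)
}

#' Generate a synthetic cohort
#'
#' Top-level generator: profiles, minute-level wearable streams, surveys and
#' a truth record (population parameters plus every participant's realized
#' random effects). Deterministic given the configuration's `master_seed`;
#' each participant draws from an own substream, so adding participants never
#' perturbs existing ones.
#'
#' @param config a [cohort_config()]
#' @param streams which data streams to generate; dropping `"wearable"`
#'   skips the (much larger) minute-level simulation, leaving surveys and
#'   profiles untouched
#' @return list of class `als_cohort` with elements `config`, `profiles`
#'   (data.table), `wearable` (list of `wearable_participant`, possibly
#'   empty), `surveys` (data.table) and `truth`
#' @export
generate_cohort <- function(config,
                            streams = c("wearable", "surveys")) {
  validate_config(config)
  streams <- match.arg(streams, several.ok = TRUE)
  n <- config$n_participants
  profiles <- lapply(seq_len(n), function(i) generate_profile(config, i))

  surveys <- NULL
  if ("surveys" %in% streams) {
    surveys <- data.table::rbindlist(lapply(profiles, function(p) {
      # schedule + residuals live in the participant's profile/survey stream
      set.seed(participant_seed(config$master_seed,
                                2L * p$participant_index) + 7L)
      generate_survey_trajectory(p, survey_schedule(config), config)
    }))
    data.table::setorder(surveys, participant_id, day, instrument)
  }

  wearable <- list()
  if ("wearable" %in% streams) {
    wearable <- lapply(profiles, generate_participant_wearable, config = config)
    names(wearable) <- vapply(wearable, `[[`, "", "participant_id")
  }

  prof_dt <- data.table::rbindlist(lapply(profiles, function(p)
    data.table::as.data.table(unclass(p)[c(
      "participant_id", "device", "z0", "z1",
      "alsfrs_b0", "alsfrs_b1", "roads_b0", "roads_b1",
      "activity_b0", "activity_b1")])))

  truth <- list(
    population = list(
      alsfrs_r = config$instruments$alsfrs_r[c("baseline", "slope_month")],
      alsfrs_rse = config$instruments$alsfrs_rse[c("baseline", "slope_month")],
      roads = config$instruments$roads[c("baseline", "slope_month")],
      self_report_offset = config$self_report_offset,
      tac = config$activity[c("tac_baseline", "tac_slope_month")],
      steps = config$steps[c("steps_baseline", "steps_slope_month")]
    ),
    random_effects = prof_dt
  )

  structure(list(config = config, profiles = prof_dt,
                 profile_objects = profiles,
                 wearable = wearable, surveys = surveys, truth = truth),
            class = "als_cohort")
}

#' @export
print.als_cohort <- function(x, ...) {
  cat(sprintf("ALS synthetic cohort: %d participants, %d days, seed %d\n",
              x$config$n_participants, x$config$observation_days,
              x$config$master_seed))
  if (length(x$wearable))
    cat(sprintf("  wearable: %d participants (%d actigraph, %d modus)\n",
                length(x$wearable),
                sum(x$profiles$device == "actigraph"),
                sum(x$profiles$device == "modus")))
  if (!is.null(x$surveys))
    cat(sprintf("  surveys: %d observations over %d instruments\n",
                nrow(x$surveys), length(unique(x$surveys$instrument))))
  invisible(x)
}
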