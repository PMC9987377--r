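# Daily physical-activity measures.
#
# Actigraph investigator-derived measures (IDMs), computed on imputed days:
# total activity counts (TAC, 24-h AC sum), log(TAC + 1), total log AC
# (24-h sum of log(AC + 1)), minutes active (AC strictly > threshold,
# default 1853) and sedentary, and the fragmentation transition
# probabilities ASTP (P(next minute sedentary | minute active)) and SATP
# (P(next minute active | minute sedentary)).
#
# Modus step measures: daily total steps; mean/median/95th-percentile
# cadence over stepping minutes (>= 1 step); percent time in the
# 1-15 / 16-40 / 41+ steps-per-minute bands (denominator = minutes within
# valid hours); maximum consecutive cadence over 60/20/5/1-minute windows;
# and the peak performance index (mean of the day's 30 largest minute-level
# step counts).

#' Total activity counts (24-hour AC sum)
#' @param value numeric minute AC vector (imputed: no NA)
#' @return sum of minute values
#' @export
total_activity_counts <- function(value) sum(value)

#' Log total activity counts: ln(TAC + 1)
#' @inheritParams total_activity_counts
#' @export
log_total_activity_counts <- function(value) log(sum(value) + 1)

#' Total log activity counts: sum over minutes of ln(AC + 1)
#' @inheritParams total_activity_counts
#' @export
total_log_activity_counts <- function(value) sum(log(value + 1))

#' Minutes spent active and sedentary
#'
#' A minute is active iff its AC strictly exceeds `threshold` (a minute at
#' exactly the threshold is sedentary); the two counts partition the day.
#'
#' @inheritParams total_activity_counts
#' @param threshold activity-count cut (default 1853)
#' @return named vector `c(active = , sedentary = )`
#' @export
active_sedentary_minutes <- function(value, threshold = 1853) {
  active <- sum(value > threshold)
  c(active = active, sedentary = length(value) - active)
}

#' Active/sedentary transition probabilities (fragmentation)
#'
#' Minutes are labelled active/sedentary by the threshold. ASTP = number of
#' active-to-sedentary adjacent transitions divided by the number of active
#' minutes excluding the day's final minute; SATP symmetrically. A zero
#' denominator yields NA (undefined), never 0. Transitions are counted
#' within the day only.
#'
#' @inheritParams active_sedentary_minutes
#' @return named vector `c(astp = , satp = )`, possibly NA
#' @export
transition_probabilities <- function(value, threshold = 1853) {
  a <- value > threshold
  n <- length(a)
  if (n < 2L) return(c(astp = NA_real_, satp = NA_real_))
  cur <- a[-n]; nxt <- a[-1L]
  n_active <- sum(cur); n_sed <- sum(!cur)
  c(astp = if (n_active > 0) sum(cur & !nxt) / n_active else NA_real_,
    satp = if (n_sed > 0) sum(!cur & nxt) / n_sed else NA_real_)
}

#' Daily total steps
#' @param value numeric minute step-sum vector
#' @export
modus_daily_steps <- function(value) sum(value, na.rm = TRUE)

#' Cadence statistics over stepping minutes
#'
#' Mean, median and 95th percentile of steps/minute over minutes with at
#' least one step recorded (zero-step minutes carry no cadence information).
#' The 95th percentile uses linear interpolation between order statistics
#' (R quantile type 7). All three are NA on a day without stepping minutes.
#'
#' @inheritParams modus_daily_steps
#' @return named vector `c(mean = , median = , p95 = )`
#' @export
cadence_statistics <- function(value) {
  s <- value[!is.na(value) & value >= 1]
  if (!length(s)) return(c(mean = NA_real_, median = NA_real_, p95 = NA_real_))
  c(mean = mean(s), median = stats::median(s),
    p95 = unname(stats::quantile(s, 0.95, type = 7)))
}

#' Percent time in low/medium/high step bands
#'
#' Bands are inclusive integer ranges of steps/minute: low 1-15, medium
#' 16-40, high 41+. Numerator = minutes inside valid hours whose step count
#' falls in the band; denominator = all minutes inside valid hours (the
#' step device has no wear flag, so an all-day denominator would conflate
#' non-wear with inactivity). All NA when the day has no valid hours.
#'
#' @inheritParams modus_daily_steps
#' @param valid_hour_flags 24 logicals marking the day's valid clock hours;
#'   default recomputed from the step grid
#' @param bands integer band edges `c(low_lo, low_hi, med_hi)`
#' @return named vector `c(low = , medium = , high = )` in percent
#' @export
percent_time_bands <- function(value, valid_hour_flags = NULL,
                               bands = c(low_lo = 1L, low_hi = 15L,
                                         med_hi = 40L)) {
  assert_grid(value, "step grid")
  if (is.null(valid_hour_flags))
    valid_hour_flags <- modus_valid_hours(value)$valid_hour_flags
  in_valid <- rep(valid_hour_flags, each = 60L)
  denom <- sum(in_valid)
  if (denom == 0)
    return(c(low = NA_real_, medium = NA_real_, high = NA_real_))
  v <- value[in_valid]
  c(low = 100 * sum(v >= bands[1] & v <= bands[2]) / denom,
    medium = 100 * sum(v > bands[2] & v <= bands[3]) / denom,
    high = 100 * sum(v > bands[3]) / denom)
}

#' Maximum consecutive cadence
#'
#' Maximum over all contiguous windows of `window` minutes of the window's
#' mean steps/minute. Requires at least one full window; shorter days
#' yield NA.
#'
#' @inheritParams modus_daily_steps
#' @param window window length in minutes (60, 20, 5 or 1 in the standard
#'   summaries)
#' @export
max_consecutive_cadence <- function(value, window) {
  n <- length(value)
  if (window < 1L || window > n) return(NA_real_)
  cs <- cumsum(c(0, value))
  max(cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

#' Peak performance index
#'
#' Mean cadence of the day's most intensive, non-contiguous 30 minutes,
#' i.e. the mean of the 30 largest minute-level step counts.
#'
#' @inheritParams modus_daily_steps
#' @param top number of minutes averaged (default 30)
#' @export
peak_performance_index <- function(value, top = 30L) {
  if (length(value) < top)
    stop(sprintf("peak performance index needs >= %d minutes", top),
         call. = FALSE)
  mean(sort(value, decreasing = TRUE)[seq_len(top)])
}

#' Names of the daily measures per device
#' @export
ACTIGRAPH_MEASURES <- c("tac", "log_tac", "total_log_ac",
                        "active_min", "sedentary_min", "astp", "satp")

#' @rdname ACTIGRAPH_MEASURES
#' @export
MODUS_MEASURES <- c("total_steps", "cadence_mean", "cadence_median",
                    "cadence_p95", "pct_low", "pct_medium", "pct_high",
                    "max_cadence_60", "max_cadence_20", "max_cadence_5",
                    "max_cadence_1", "ppi")

# Daily measures for one participant record (valid days; actigraph imputed).
participant_daily_measures <- function(rec, active_threshold = 1853,
                                       bands = c(low_lo = 1L, low_hi = 15L,
                                                 med_hi = 40L)) {
  D <- ncol(rec$value)
  if (D == 0L)
    return(data.table::data.table(participant_id = character(),
                                  date = as.Date(character()),
                                  device = character(), measure = character(),
                                  value = numeric()))
  v <- rec$value
  if (rec$device == "actigraph") {
    if (anyNA(v))
      stop(sprintf("participant %s: actigraph days must be imputed before measure derivation",
                   rec$participant_id), call. = FALSE)
    tac <- colSums(v)
    a <- v > active_threshold
    active <- colSums(a)
    cur <- a[-1440L, , drop = FALSE]; nxt <- a[-1L, , drop = FALSE]
    n_active <- colSums(cur); n_sed <- 1439L - n_active
    astp <- ifelse(n_active > 0, colSums(cur & !nxt) / n_active, NA_real_)
    satp <- ifelse(n_sed > 0, colSums(!cur & nxt) / n_sed, NA_real_)
    vals <- rbind(tac = tac,
                  log_tac = log(tac + 1),
                  total_log_ac = colSums(log(v + 1)),
                  active_min = active,
                  sedentary_min = 1440 - active,
                  astp = astp, satp = satp)
  } else {
    hour_ok <- matrix(colSums(matrix(v, nrow = 60L)) >= 1, nrow = 24L)
    vals <- vapply(seq_len(D), function(d) {
      x <- v[, d]
      cs <- cadence_statistics(x)
      pb <- percent_time_bands(x, hour_ok[, d], bands)
      c(total_steps = sum(x),
        cadence_mean = unname(cs["mean"]),
        cadence_median = unname(cs["median"]),
        cadence_p95 = unname(cs["p95"]),
        pct_low = unname(pb["low"]),
        pct_medium = unname(pb["medium"]),
        pct_high = unname(pb["high"]),
        max_cadence_60 = max_consecutive_cadence(x, 60L),
        max_cadence_20 = max_consecutive_cadence(x, 20L),
        max_cadence_5 = max_consecutive_cadence(x, 5L),
        max_cadence_1 = max_consecutive_cadence(x, 1L),
        ppi = peak_performance_index(x))
    }, numeric(12L))
  }
  data.table::data.table(
    participant_id = rec$participant_id,
    date = rep(rec$dates, each = nrow(vals)),
    device = rec$device,
    measure = rep(rownames(vals), D),
    value = as.numeric(vals)
  )
}

#' Derive all daily measures for a wearable set
#'
#' Long-format table, one row per participant-day-measure: the 7 actigraph
#' IDMs for actigraph participants, the 12 step/cadence measures for modus
#' participants. Input must be validity-filtered, with actigraph records
#' imputed.
#'
#' @param wearable list of `wearable_participant` records
#' @param active_threshold AC cut for the active/sedentary split
#' @param bands step-band edges as in [percent_time_bands()]
#' @return data.table with columns participant_id, date, device, measure,
#'   value
#' @export
derive_all <- function(wearable, active_threshold = 1853,
                       bands = c(low_lo = 1L, low_hi = 15L, med_hi = 40L)) {
  if (length(wearable) == 0)
    return(data.table::data.table(participant_id = character(),
                                  date = as.Date(character()),
                                  device = character(), measure = character(),
                                  value = numeric()))
  data.table::rbindlist(lapply(wearable, participant_daily_measures,
                               active_threshold = active_threshold,
                               bands = bands))
}
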