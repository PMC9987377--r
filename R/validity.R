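# Wear-compliance classification. An hour is clock-aligned (minutes
# 60h..60h+59). Actigraph: a valid hour has all 60 minutes non-missing and
# wear-flagged. Modus: a valid hour has at least one step logged. A valid
# day has >= 8 valid hours (not necessarily consecutive). Only valid days
# enter any downstream wearable computation.

VALID_HOURS_PER_DAY <- 8L

assert_grid <- function(x, what = "minute grid") {
  if (length(x) != 1440L)
    stop(sprintf("%s must have exactly 1440 slots, got %d", what, length(x)),
         call. = FALSE)
  invisible(x)
}

#' Valid hours of one actigraph day
#'
#' @param value numeric length-1440 minute AC (NA where missing); only its
#'   length and NA pattern matter here
#' @param wear logical length-1440 wear flag
#' @param missing logical length-1440 missing flag
#' @return list with `valid_hour_flags` (24 logicals), `valid_hour_count`,
#'   `is_valid_day`
#' @export
actigraph_valid_hours <- function(value, wear, missing) {
  assert_grid(wear, "wear flags"); assert_grid(missing, "missing flags")
  ok <- wear & !missing
  flags <- colSums(matrix(ok, nrow = 60L)) == 60L
  list(valid_hour_flags = flags,
       valid_hour_count = sum(flags),
       is_valid_day = sum(flags) >= VALID_HOURS_PER_DAY)
}

#' Valid hours of one modus day
#'
#' @param value numeric length-1440 minute step sums
#' @return as [actigraph_valid_hours()]
#' @export
modus_valid_hours <- function(value) {
  assert_grid(value, "step grid")
  flags <- colSums(matrix(value, nrow = 60L), na.rm = TRUE) >= 1
  list(valid_hour_flags = flags,
       valid_hour_count = sum(flags),
       is_valid_day = sum(flags) >= VALID_HOURS_PER_DAY)
}

# Per-participant day validity, vectorized over the day columns.
participant_day_validity <- function(rec) {
  if (rec$device == "actigraph") {
    ok <- rec$wear & !rec$missing
    dim(ok) <- c(60L, 24L * ncol(rec$value))
    hour_ok <- colSums(ok) == 60L
  } else {
    v <- rec$value
    v[is.na(v)] <- 0
    dim(v) <- c(60L, 24L * ncol(rec$value))
    hour_ok <- colSums(v) >= 1
  }
  hour_ok <- matrix(hour_ok, nrow = 24L)
  valid_hours <- colSums(hour_ok)
  data.table::data.table(
    participant_id = rec$participant_id,
    date = rec$dates,
    device = rec$device,
    valid_hours = as.integer(valid_hours),
    is_valid_day = valid_hours >= VALID_HOURS_PER_DAY
  )
}

#' Classify and filter valid days across a wearable set
#'
#' @param wearable list of `wearable_participant` records (one device type
#'   per participant)
#' @return list with `wearable` (the same records restricted to their valid
#'   day columns) and `validity` (data.table covering every input day)
#' @export
filter_valid_days <- function(wearable) {
  if (length(wearable) == 0)
    return(list(wearable = list(),
                validity = data.table::data.table(
                  participant_id = character(), date = as.Date(character()),
                  device = character(), valid_hours = integer(),
                  is_valid_day = logical())))
  ids <- vapply(wearable, `[[`, "", "participant_id")
  if (anyDuplicated(ids))
    stop("mixed or duplicated device records for participant(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  validity <- data.table::rbindlist(lapply(wearable, participant_day_validity))
  filtered <- lapply(wearable, function(rec) {
    v <- participant_day_validity(rec)
    keep <- which(v$is_valid_day)
    rec$dates <- rec$dates[keep]
    rec$value <- rec$value[, keep, drop = FALSE]
    rec$missing <- rec$missing[, keep, drop = FALSE]
    if (!is.null(rec$wear)) rec$wear <- rec$wear[, keep, drop = FALSE]
    rec
  })
  names(filtered) <- ids
  list(wearable = filtered, validity = validity)
}

med_range <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("--")
  sprintf("%.4g [%.4g, %.4g]", stats::median(x), min(x), max(x))
}

#' Compliance summary by device group
#'
#' Per device group and combined: median `[min, max]` across participants of
#' complete ALSFRS-RSE submissions, ROADS submissions, days in the
#' observation period (inclusive first-to-last day with any device data),
#' valid days, and the average number of valid hours on a valid day.
#'
#' @param validity data.table from [filter_valid_days()]
#' @param surveys survey observations (complete submissions only)
#' @return data.table, one row per statistic, columns actigraph/modus/combined
#' @export
compliance_summary <- function(validity, surveys) {
  stopifnot(nrow(validity) > 0, nrow(surveys) > 0)
  validity <- data.table::as.data.table(validity)
  surveys <- data.table::as.data.table(surveys)
  per <- validity[, .(
    device = device[1],
    days_in_observation = as.integer(max(date) - min(date)) + 1L,
    valid_days = sum(is_valid_day),
    avg_valid_hours = if (any(is_valid_day))
      mean(valid_hours[is_valid_day]) else NA_real_
  ), by = participant_id]
  counts <- surveys[instrument %in% c("alsfrs_rse", "roads"),
                    .N, by = .(participant_id, instrument)]
  counts <- data.table::dcast(counts, participant_id ~ instrument,
                              value.var = "N", fill = 0L)
  for (col in c("alsfrs_rse", "roads"))
    if (!col %in% names(counts)) counts[[col]] <- 0L
  per <- merge(per, counts, by = "participant_id", all.x = TRUE)
  for (col in c("alsfrs_rse", "roads"))
    per[[col]][is.na(per[[col]])] <- 0L

  cell <- function(dev, col) {
    rows <- if (dev == "combined") per else per[per$device == dev, ]
    med_range(rows[[col]])
  }
  stats_ <- c(alsfrs_rse = "ALSFRS-RSE submissions",
              roads = "ROADS submissions",
              days_in_observation = "Days in observation period",
              valid_days = "Valid days in observation period",
              avg_valid_hours = "Average valid hours on a valid day")
  data.table::data.table(
    statistic = unname(stats_),
    actigraph = vapply(names(stats_), cell, "", dev = "actigraph"),
    modus = vapply(names(stats_), cell, "", dev = "modus"),
    combined = vapply(names(stats_), cell, "", dev = "combined")
  )
}
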