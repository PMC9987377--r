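# CSV dialects. Long minute-level table: participant_id, date (ISO-8601),
# minute_of_day (0-1439), value, wear, missing (and imputed once filled);
# survey and daily-measure tables as written by their modules. Missing
# values are empty fields; round-trips are identity.

#' Write a wearable set as a long minute-level CSV
#'
#' @param wearable list of `wearable_participant` records
#' @param path output file
#' @export
write_minute_csv <- function(wearable, path) {
  dt <- data.table::rbindlist(lapply(wearable, function(rec) {
    D <- ncol(rec$value)
    data.table::data.table(
      participant_id = rec$participant_id,
      date = format(rep(rec$dates, each = 1440L), "%Y-%m-%d"),
      minute_of_day = rep(0:1439, D),
      value = as.numeric(rec$value),
      wear = if (is.null(rec$wear)) NA else as.logical(rec$wear),
      missing = as.logical(rec$missing),
      imputed = if (is.null(rec$imputed)) NA else as.logical(rec$imputed),
      device = rec$device)
  }))
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}

#' Read a long minute-level CSV back into a wearable set
#'
#' @param path file written by [write_minute_csv()]
#' @return list of `wearable_participant` records
#' @export
read_minute_csv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  dt <- data.table::fread(path, na.strings = "")
  need <- c("participant_id", "date", "minute_of_day", "value",
            "wear", "missing", "device")
  if (!all(need %in% names(dt)))
    stop("malformed minute CSV: missing column(s) ",
         paste(setdiff(need, names(dt)), collapse = ", "), call. = FALSE)
  dates <- as.Date(as.character(dt$date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop(sprintf("malformed date at data row %d: '%s'", bad, dt$date[bad]),
         call. = FALSE)
  }
  dt$date <- dates
  recs <- lapply(split(dt, dt$participant_id), function(p) {
    data.table::setorder(p, date, minute_of_day)
    udates <- unique(p$date)
    D <- length(udates)
    if (nrow(p) != 1440L * D)
      stop(sprintf("participant %s: day(s) without exactly 1440 slots",
                   p$participant_id[1]), call. = FALSE)
    rec <- list(
      participant_id = p$participant_id[1],
      device = p$device[1],
      dates = udates,
      value = matrix(p$value, 1440L, D),
      wear = if (all(is.na(p$wear))) NULL else matrix(p$wear, 1440L, D),
      missing = matrix(p$missing, 1440L, D))
    if ("imputed" %in% names(p) && !all(is.na(p$imputed)))
      rec$imputed <- matrix(p$imputed, 1440L, D)
    structure(rec, class = "wearable_participant")
  })
  recs[order(names(recs))]
}

#' Write / read a survey table
#' @param surveys survey data.table
#' @param path file path
#' @export
write_survey_csv <- function(surveys, path) {
  out <- data.table::copy(data.table::as.data.table(surveys))
  out$date <- format(out$date, "%Y-%m-%d")
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  dt <- data.table::fread(path, na.strings = "")
  need <- c("participant_id", "date", "instrument", "score")
  if (!all(need %in% names(dt)))
    stop("malformed survey CSV: missing column(s) ",
         paste(setdiff(need, names(dt)), collapse = ", "), call. = FALSE)
  dates <- as.Date(as.character(dt$date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop(sprintf("malformed date at data row %d: '%s'", bad, dt$date[bad]),
         call. = FALSE)
  }
  dt$date <- dates
  dt
}

#' Write a generic results table (dates ISO, missing as empty)
#' @param x data.frame/data.table
#' @param path file path
#' @export
write_table_csv <- function(x, path) {
  x <- data.table::copy(data.table::as.data.table(x))
  for (col in names(x)) if (inherits(x[[col]], "Date"))
    x[[col]] <- format(x[[col]], "%Y-%m-%d")
  data.table::fwrite(x, path, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  dt <- data.table::fread(path, na.strings = "")
  if ("date" %in% names(dt)) dt$date <- as.Date(as.character(dt$date))
  dt
}
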