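# Minute-level imputation for investigator-derived daily measures (IDMs).
# A minute lacking an observed worn AC (missing, or non-wear) is filled with
# the mean of that minute-of-day's observed worn values across the
# participant's valid days, so every imputed day spans 1440 analyzable
# minutes. Applied to actigraph AC streams only; the step device has no
# epoch wear flag and is summarized without imputation.

#' Impute one participant's missing minute-level activity counts
#'
#' Donor pool for minute-of-day m = that participant's valid days where
#' minute m is non-missing and wear-flagged. Observed worn values pass
#' through unchanged. A minute-of-day with zero donors across all valid days
#' is filled with 0 (with a warning): the day must still yield 1440
#' analyzable minutes.
#'
#' @param rec a `wearable_participant` (actigraph, valid days only)
#' @return the record with `value` fully observed, plus an `imputed`
#'   logical matrix marking filled slots
#' @export
impute_participant <- function(rec) {
  stopifnot(inherits(rec, "wearable_participant"))
  if (rec$device != "actigraph")
    stop("imputation applies to actigraph activity-count streams only",
         call. = FALSE)
  if (ncol(rec$value) < 1L)
    stop("participant has no valid days to impute from", call. = FALSE)
  if (!is.null(rec$imputed)) return(rec)  # idempotent

  donor <- rec$wear & !rec$missing
  v <- rec$value
  v[!donor] <- 0
  n_donor <- rowSums(donor)
  minute_mean <- rowSums(v) / pmax(n_donor, 1L)
  if (any(n_donor == 0L)) {
    warning(sprintf(
      "participant %s: %d minute-of-day slot(s) have no donor on any valid day; filled with 0",
      rec$participant_id, sum(n_donor == 0L)), call. = FALSE)
    minute_mean[n_donor == 0L] <- 0
  }
  fill <- !donor
  out <- rec$value
  out[fill] <- minute_mean[row(out)[fill]]
  rec$value <- out
  rec$imputed <- fill
  rec
}

#' Impute every actigraph participant in a filtered wearable set
#'
#' @param wearable list of validity-filtered `wearable_participant` records
#' @return the list with actigraph records imputed (modus records untouched)
#' @export
impute_wearable <- function(wearable) {
  lapply(wearable, function(rec) {
    if (rec$device == "actigraph" && ncol(rec$value) >= 1L)
      impute_participant(rec)
    else rec
  })
}
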