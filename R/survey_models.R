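# Survey trajectory models. Six LMMs: per-instrument trajectories
# (ALSFRS-RSE, ROADS, ALSFRS-R), a combined ALSFRS model with a self-entry
# indicator and its interaction with time, and device-group comparison
# models; plus the matched Pearson correlation between staff and self-entry
# ALSFRS at each staff administration.

#' Apply the analysis-sample filter
#'
#' Keeps participants with at least two fully completed ALSFRS-RSE and at
#' least two fully completed ROADS submissions.
#'
#' @param surveys survey observations
#' @return filtered data.table
#' @export
analysis_sample <- function(surveys) {
  surveys <- data.table::as.data.table(surveys)
  counts <- surveys[instrument %in% c("alsfrs_rse", "roads"),
                    .N, by = .(participant_id, instrument)]
  wide <- data.table::dcast(counts, participant_id ~ instrument,
                            value.var = "N", fill = 0L)
  for (col in c("alsfrs_rse", "roads"))
    if (!col %in% names(wide)) wide[[col]] <- 0L
  keep <- wide$participant_id[wide$alsfrs_rse >= 2L & wide$roads >= 2L]
  surveys[participant_id %in% keep]
}

#' Per-instrument survey trajectory models (models 1-3)
#'
#' One LMM per instrument: score ~ time (months) with participant random
#' intercept and slope; intercept = population baseline, time coefficient =
#' monthly rate of change.
#'
#' @param surveys survey observations (the analysis-sample filter is
#'   applied internally)
#' @return named list of `als_lmm` fits (`alsfrs_rse`, `roads`, `alsfrs_r`)
#' @export
fit_trajectory_models <- function(surveys) {
  surveys <- analysis_sample(surveys)
  fits <- lapply(c(alsfrs_rse = "alsfrs_rse", roads = "roads",
                   alsfrs_r = "alsfrs_r"), function(ins) {
    d <- surveys[surveys$instrument == ins, ]
    fit_lmm(d, outcome = "score", fixed = "t_months")
  })
  fits
}

#' Combined staff/self-entry ALSFRS model (model 4)
#'
#' Stacks ALSFRS-R and ALSFRS-RSE observations with an indicator for the
#' self-entry outcome and its interaction with time; the indicator estimates
#' the self-report baseline offset, the interaction the slope difference.
#'
#' @inheritParams fit_trajectory_models
#' @return an `als_lmm`
#' @export
fit_combined_scale_model <- function(surveys) {
  surveys <- analysis_sample(surveys)
  d <- surveys[surveys$instrument %in% c("alsfrs_r", "alsfrs_rse"), ]
  if (length(unique(d$instrument)) < 2L)
    stop("combined scale model needs both ALSFRS variants", call. = FALSE)
  d$self_entry <- as.integer(d$instrument == "alsfrs_rse")
  fit_lmm(d, outcome = "score",
          fixed = c("t_months", "self_entry", "self_entry:t_months"))
}

#' Device-group survey comparison models (models 5-6)
#'
#' For ALSFRS-RSE and ROADS separately: score ~ time + modus indicator +
#' indicator x time, with participant random intercept and slope. The
#' indicator estimates the group baseline difference, the interaction the
#' slope difference.
#'
#' @inheritParams fit_trajectory_models
#' @param devices data.frame with columns `participant_id`, `device`
#' @return named list of `als_lmm` fits (`alsfrs_rse`, `roads`)
#' @export
fit_device_group_models <- function(surveys, devices) {
  surveys <- analysis_sample(surveys)
  devices <- as.data.frame(devices)[, c("participant_id", "device")]
  d <- merge(surveys, devices, by = "participant_id")
  if (any(is.na(d$device)))
    stop("every participant needs a device label", call. = FALSE)
  if (length(unique(d$device)) < 2L)
    stop("device comparison needs both device groups", call. = FALSE)
  d$modus <- as.integer(d$device == "modus")
  lapply(c(alsfrs_rse = "alsfrs_rse", roads = "roads"), function(ins) {
    fit_lmm(d[d$instrument == ins, ],
            outcome = "score",
            fixed = c("t_months", "modus", "modus:t_months"))
  })
}

#' Matched Pearson correlation between staff and self-entry ALSFRS
#'
#' For each staff ALSFRS-R administration (nominal months 0/3/6) and
#' participant, selects the ALSFRS-RSE with the smallest absolute date
#' difference within `window` days (ties broken toward the earlier survey)
#' and computes the Pearson correlation over the matched pairs at each
#' timepoint. A timepoint with fewer than 3 matched pairs yields NA with
#' a warning.
#'
#' @param surveys survey observations containing both `alsfrs_r` rows (with
#'   `nominal_month`) and `alsfrs_rse` rows
#' @param window maximum |date difference| in days (default 28)
#' @return data.table: nominal_month, n_pairs, r
#' @export
matched_pearson <- function(surveys, window = 28) {
  surveys <- data.table::as.data.table(surveys)
  staff <- surveys[instrument == "alsfrs_r" & !is.na(nominal_month)]
  rse <- surveys[instrument == "alsfrs_rse"]
  if (nrow(staff) == 0 || nrow(rse) == 0)
    stop("need both staff and self-entry ALSFRS observations", call. = FALSE)

  pairs <- lapply(seq_len(nrow(staff)), function(i) {
    cand <- rse[participant_id == staff$participant_id[i]]
    if (nrow(cand) == 0) return(NULL)
    dd <- as.numeric(cand$date - staff$date[i])
    ok <- abs(dd) <= window
    if (!any(ok)) return(NULL)
    cand <- cand[ok]; dd <- dd[ok]
    # minimum |offset|; equidistant before/after -> earlier survey
    ord <- order(abs(dd), dd)
    data.table::data.table(
      participant_id = staff$participant_id[i],
      nominal_month = staff$nominal_month[i],
      staff_score = staff$score[i],
      rse_score = cand$score[ord[1]])
  })
  pairs <- data.table::rbindlist(pairs)
  months <- sort(unique(staff$nominal_month))
  out <- data.table::rbindlist(lapply(months, function(mn) {
    p <- pairs[pairs$nominal_month == mn, ]
    r <- if (nrow(p) >= 3L) stats::cor(p$staff_score, p$rse_score) else {
      warning(sprintf("timepoint month %s: only %d matched pair(s); correlation undefined",
                      mn, nrow(p)), call. = FALSE)
      NA_real_
    }
    data.table::data.table(nominal_month = mn, n_pairs = nrow(p), r = r)
  }))
  out
}
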