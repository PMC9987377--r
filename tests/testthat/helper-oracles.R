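# Independent brute-force oracles: plain loops and sorts, sharing no code
# with the implementation they check.

oracle_sum <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s
}

# transition probabilities from an active/sedentary label sequence
oracle_transitions <- function(active) {
  n <- length(active)
  a2s <- 0; s2a <- 0; n_active <- 0; n_sed <- 0
  for (i in seq_len(n - 1)) {
    if (active[i]) {
      n_active <- n_active + 1
      if (!active[i + 1]) a2s <- a2s + 1
    } else {
      n_sed <- n_sed + 1
      if (active[i + 1]) s2a <- s2a + 1
    }
  }
  c(astp = if (n_active > 0) a2s / n_active else NA_real_,
    satp = if (n_sed > 0) s2a / n_sed else NA_real_)
}

oracle_max_window_mean <- function(x, w) {
  n <- length(x)
  if (w > n) return(NA_real_)
  best <- -Inf
  for (s in 1:(n - w + 1)) {
    m <- mean(x[s:(s + w - 1)])
    if (m > best) best <- m
  }
  best
}

oracle_top_k_mean <- function(x, k) mean(sort(x, decreasing = TRUE)[1:k])

oracle_band_counts <- function(x, keep) {
  low <- 0; med <- 0; high <- 0; denom <- 0
  for (i in seq_along(x)) {
    if (!keep[i]) next
    denom <- denom + 1
    if (x[i] >= 1 && x[i] <= 15) low <- low + 1
    else if (x[i] >= 16 && x[i] <= 40) med <- med + 1
    else if (x[i] >= 41) high <- high + 1
  }
  c(low = low, medium = med, high = high, denom = denom)
}

oracle_quantile_p95 <- function(x) {
  # type-7 linear interpolation, written out from the definition
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * 0.95 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# --- fixture builders -------------------------------------------------------

# a wearable_participant from per-day value/wear/missing vectors
make_record <- function(values, wear = NULL, missing = NULL,
                        device = "actigraph", id = "P001",
                        start = as.Date("2021-01-01")) {
  value <- do.call(cbind, values)
  D <- ncol(value)
  if (is.null(missing)) missing <- matrix(FALSE, 1440, D)
  else missing <- do.call(cbind, missing)
  if (device == "actigraph") {
    if (is.null(wear)) wear <- matrix(TRUE, 1440, D)
    else wear <- do.call(cbind, wear)
  } else wear <- NULL
  structure(list(participant_id = id, device = device,
                 dates = start + 0:(D - 1), value = value,
                 wear = wear, missing = missing),
            class = "wearable_participant")
}

# small quiet config for pipeline-level tests
small_config <- function(seed = 101, n = 6, days = 40, ...) {
  cohort_config(n_participants = n, observation_days = days,
                master_seed = seed, ...)
}

# noise-free configuration: exact linear trajectories everywhere;
# override blocks are merged on top of the zero-noise settings
noiseless_config <- function(seed = 7, n = 6, days = 120,
                             instruments = NULL, activity = NULL,
                             steps = NULL, missingness = NULL, ...) {
  merge2 <- function(base, extra) {
    for (nm in names(extra)) {
      if (is.list(base[[nm]]) && is.list(extra[[nm]]))
        base[[nm]] <- merge2(base[[nm]], extra[[nm]])
      else base[[nm]] <- extra[[nm]]
    }
    base
  }
  zero <- list(b0_sd = 0, b1_sd = 0, resid_sd = 0)
  cohort_config(
    n_participants = n, observation_days = days, master_seed = seed,
    instruments = merge2(list(alsfrs_r = zero, alsfrs_rse = zero,
                              roads = zero), instruments),
    activity = merge2(list(b0_sd = 0, b1_sd = 0, daily_sd = 0,
                           minute_shape = Inf), activity),
    steps = merge2(list(b0_sd = 0, b1_sd = 0, daily_sd = 0), steps),
    missingness = merge2(list(charge_gap_prob = 0, nonwear_rate = 0,
                              offday_prob_actigraph = 0,
                              offday_prob_modus = 0), missingness),
    latent_coupling = 0, round_scores = FALSE, ...)
}

# actigraph-arm-only wearable generation (per-participant RNG substreams
# make this identical to the corresponding arm of the full cohort)
actigraph_arm <- function(config) {
  n_acti <- round(config$n_participants * config$device_split)
  recs <- lapply(seq_len(n_acti), function(i)
    generate_participant_wearable(generate_profile(config, i), config))
  names(recs) <- vapply(recs, `[[`, "", "participant_id")
  recs
}

# daily TAC table with participant-anchored time, from raw records
tac_table <- function(wearable) {
  flt <- filter_valid_days(wearable)
  imp <- impute_wearable(flt$wearable)
  daily <- derive_all(imp)
  d <- daily[daily$measure == "tac" & !is.na(daily$value), ]
  d[, t_months := as.numeric(date - min(date)) / DAYS_PER_MONTH,
    by = participant_id]
  d
}
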