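# Daily physical-activity measures against closed forms and brute-force
# oracles.

test_that("total activity counts and log transforms match closed forms", {
  expect_equal(total_activity_counts(numeric(1440)), 0)
  expect_equal(total_activity_counts(rep(100, 1440)), 144000)
  x <- 0:1439
  expect_equal(total_activity_counts(x), oracle_sum(x))
  expect_equal(total_activity_counts(x), 1439 * 1440 / 2)

  expect_equal(log_total_activity_counts(numeric(1440)), 0)
  expect_equal(total_log_activity_counts(numeric(1440)), 0)
  one <- numeric(1440); one[500] <- exp(1) - 1
  expect_equal(log_total_activity_counts(one), 1)
  expect_equal(total_log_activity_counts(one), 1)
  expect_equal(log_total_activity_counts(x), log(sum(x) + 1))
  expect_lte(total_log_activity_counts(x), 1440 * log(max(x) + 1))
})

test_that("active/sedentary split uses a strict threshold and partitions the day", {
  expect_equal(active_sedentary_minutes(rep(1853, 1440)),
               c(active = 0, sedentary = 1440))
  x <- numeric(1440); x[1:30] <- 2000
  expect_equal(active_sedentary_minutes(x), c(active = 30, sedentary = 1410))
  set.seed(5)
  for (i in 1:20) {
    g <- rgamma(1440, 1, scale = 1500)
    expect_equal(sum(active_sedentary_minutes(g)), 1440)
  }
})

test_that("transition probabilities match brute-force counting", {
  # toy sequence A,A,S,A,S
  toy <- c(2000, 2000, 0, 2000, 0)
  tp <- transition_probabilities(toy)
  expect_equal(unname(tp["astp"]), 2 / 3)
  expect_equal(unname(tp["satp"]), 1)

  # all-active: ASTP 0, SATP undefined
  tp2 <- transition_probabilities(rep(5000, 1440))
  expect_equal(unname(tp2["astp"]), 0)
  expect_true(is.na(tp2["satp"]))

  # strict alternation: both 1
  alt <- rep(c(5000, 0), 720)
  tp3 <- transition_probabilities(alt)
  expect_equal(unname(tp3), c(1, 1))
})

test_that("cadence statistics are computed over stepping minutes", {
  x <- numeric(1440); x[c(100, 200, 300)] <- c(10, 20, 30)
  cs <- cadence_statistics(x)
  expect_equal(unname(cs["mean"]), 20)
  expect_equal(unname(cs["median"]), 20)
  y <- numeric(1440); y[7] <- 7
  expect_equal(unname(cadence_statistics(y)), c(7, 7, 7))
  expect_true(all(is.na(cadence_statistics(numeric(1440)))))
  # p95 matches the sort-based type-7 oracle
  set.seed(11)
  steps <- sample(1:60, 100, replace = TRUE)
  z <- numeric(1440); z[sample.int(1440, 100)] <- steps
  expect_equal(unname(cadence_statistics(z)["p95"]), oracle_quantile_p95(steps))
})

test_that("percent-time bands use inclusive edges and the valid-hour denominator", {
  # every minute of 8 valid hours carries 10 steps
  x <- numeric(1440); x[1:(8 * 60)] <- 10
  pb <- percent_time_bands(x)
  expect_equal(unname(pb), c(100, 0, 0))

  # 15 is low, 16 is medium
  x2 <- numeric(1440); x2[1] <- 15; x2[2] <- 16; x2[3:60] <- 1
  pb2 <- percent_time_bands(x2)  # one valid hour only
  expect_equal(unname(pb2["low"]), 100 * 59 / 60)
  expect_equal(unname(pb2["medium"]), 100 * 1 / 60)

  # crafted 480-valid-minute day with 48 low-band minutes
  x3 <- numeric(1440)
  x3[seq(1, 480, by = 10)] <- 5            # 48 low minutes in hours 0-7
  x3[seq(60, 480, by = 60)] <- 50          # keep all 8 hours valid
  v <- modus_valid_hours(x3)
  expect_equal(v$valid_hour_count, 8L)
  pb3 <- percent_time_bands(x3)
  expect_equal(unname(pb3["low"]), 10)
  expect_true(all(is.na(percent_time_bands(numeric(1440)))))
})

test_that("max consecutive cadence equals the sliding-window oracle", {
  x <- numeric(1440); x[100:104] <- 60
  expect_equal(max_consecutive_cadence(x, 5), 60)
  expect_equal(max_consecutive_cadence(x, 1), max(x))
  set.seed(21)
  for (i in 1:10) {
    g <- rpois(180, 2) * rbinom(180, 1, 0.3)
    for (w in c(60, 20, 5, 1))
      expect_equal(max_consecutive_cadence(g, w), oracle_max_window_mean(g, w))
  }
  expect_true(is.na(max_consecutive_cadence(numeric(30), 60)))
})

test_that("peak performance index is the mean of the 30 largest minutes", {
  x <- numeric(1440); x[1:30] <- 60
  expect_equal(peak_performance_index(x), 60)
  y <- numeric(1440); y[1] <- 100; y[2:30] <- 50
  expect_equal(peak_performance_index(y), (100 + 29 * 50) / 30)
  expect_equal(peak_performance_index(y), oracle_top_k_mean(y, 30))
  expect_equal(peak_performance_index(numeric(1440)), 0)
  expect_error(peak_performance_index(numeric(10)), ">= 30")
})

test_that("derive_all emits one row per participant-day-measure", {
  cfg <- small_config(seed = 61, n = 4, days = 8)
  co <- generate_cohort(cfg)
  flt <- filter_valid_days(co$wearable)
  imp <- impute_wearable(flt$wearable)
  daily <- derive_all(imp)
  v <- flt$validity[flt$validity$is_valid_day, ]
  n_acti_days <- sum(v$device == "actigraph")
  n_modus_days <- sum(v$device == "modus")
  expect_equal(nrow(daily), n_acti_days * 7 + n_modus_days * 12)
  expect_setequal(unique(daily$measure[daily$device == "actigraph"]),
                  ACTIGRAPH_MEASURES)
  expect_setequal(unique(daily$measure[daily$device == "modus"]),
                  MODUS_MEASURES)
  expect_equal(nrow(derive_all(list())), 0L)

  # IDM identity and ranges on the derived table
  wide <- data.table::dcast(daily[daily$device == "actigraph"],
                            participant_id + date ~ measure)
  expect_true(all(wide$active_min + wide$sedentary_min == 1440))
  tp <- daily[daily$measure %in% c("astp", "satp") & !is.na(daily$value), ]
  expect_true(all(tp$value >= 0 & tp$value <= 1))
})

test_that("modus measure orderings hold: Max-1 >= Max-5 >= Max-20 >= Max-60 >= daily mean", {
  cfg <- small_config(seed = 62, n = 4, days = 10)
  co <- generate_cohort(cfg)
  flt <- filter_valid_days(co$wearable)
  modus <- flt$wearable[vapply(flt$wearable, `[[`, "", "device") == "modus"]
  modus <- modus[vapply(modus, function(r) ncol(r$value) > 0, TRUE)]
  for (rec in modus) {
    for (d in seq_len(ncol(rec$value))) {
      x <- rec$value[, d]
      m <- vapply(c(1, 5, 20, 60), function(w) max_consecutive_cadence(x, w),
                  numeric(1))
      expect_true(all(diff(m) <= 1e-12))
      expect_gte(peak_performance_index(x), mean(x))
    }
    # band percentages sum to at most 100
    daily <- derive_all(list(rec))
    pb <- data.table::dcast(daily[daily$measure %in%
                                    c("pct_low", "pct_medium", "pct_high")],
                            date ~ measure)
    expect_true(all(pb$pct_low + pb$pct_medium + pb$pct_high <= 100 + 1e-9))
  }
})
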