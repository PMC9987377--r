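# Survey trajectory models, the combined staff/self-entry model, device
# comparisons, and the matched Pearson correlation.

test_that("noiseless cohort recovers the configured slopes exactly", {
  cfg <- noiseless_config(n = 6, days = 170)
  co <- generate_cohort(cfg, streams = "surveys")
  fits <- fit_trajectory_models(co$surveys)
  for (ins in names(fits)) {
    est <- fits[[ins]]$fixed
    expect_equal(est$estimate[est$term == "(Intercept)"],
                 cfg$instruments[[ins]]$baseline, tolerance = 1e-6)
    expect_equal(est$estimate[est$term == "t_months"],
                 cfg$instruments[[ins]]$slope_month, tolerance = 1e-6)
  }
})

test_that("participants with fewer than two complete submissions are excluded", {
  cfg <- small_config(seed = 14, n = 5, days = 100)
  co <- generate_cohort(cfg, streams = "surveys")
  s <- co$surveys
  # strip P001 down to a single ROADS submission
  drop <- s$participant_id == "P001" &
    (s$instrument == "roads" & duplicated(s$instrument == "roads" & s$participant_id == "P001"))
  s1 <- s[!(s$participant_id == "P001" & s$instrument == "roads" & s$day > 0), ]
  filtered <- analysis_sample(s1)
  expect_false("P001" %in% filtered$participant_id)
  expect_true("P002" %in% filtered$participant_id)
})

test_that("combined model indicator equals the baseline difference in the noiseless case", {
  cfg <- noiseless_config(n = 6, days = 170)
  co <- generate_cohort(cfg, streams = "surveys")
  comb <- fit_combined_scale_model(co$surveys)
  est <- comb$fixed
  fits <- fit_trajectory_models(co$surveys)
  m1 <- fits$alsfrs_rse$fixed; m3 <- fits$alsfrs_r$fixed
  expect_equal(est$estimate[est$term == "self_entry"],
               m1$estimate[m1$term == "(Intercept)"] -
                 m3$estimate[m3$term == "(Intercept)"],
               tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "self_entry"],
               cfg$self_report_offset, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "t_months:self_entry" |
                              est$term == "self_entry:t_months"],
               cfg$instruments$alsfrs_rse$slope_month -
                 cfg$instruments$alsfrs_r$slope_month, tolerance = 1e-6)
  # a single instrument is a precondition error
  expect_error(fit_combined_scale_model(
    co$surveys[co$surveys$instrument != "alsfrs_r", ]), "both")
})

test_that("device-group models center on zero when groups share parameters", {
  cfg <- cohort_config(n_participants = 60, observation_days = 180,
                       master_seed = 19)
  co <- generate_cohort(cfg, streams = "surveys")
  fits <- fit_device_group_models(co$surveys, co$profiles)
  for (f in fits) {
    est <- as.data.frame(f$fixed)
    for (tt in c("modus", "t_months:modus")) {
      row <- est[est$term == tt, ]
      expect_equal(nrow(row), 1L)
      expect_true(row$ci_lo <= 0 && 0 <= row$ci_hi)
    }
  }
  one_dev <- co$profiles
  one_dev$device <- "modus"
  expect_error(fit_device_group_models(co$surveys, one_dev), "both device")
})

test_that("matched correlation is 1 when self-entry mirrors staff scores", {
  dates <- as.Date("2021-01-01") + c(0, 91, 180)
  staff <- data.table::rbindlist(lapply(1:6, function(i)
    data.table::data.table(participant_id = sprintf("P%02d", i),
                           date = dates, instrument = "alsfrs_r",
                           nominal_month = c(0, 3, 6),
                           score = c(40, 35, 30) - i)))
  rse <- data.table::copy(staff)
  rse$instrument <- "alsfrs_rse"
  rse$date <- rse$date + 5
  rse$nominal_month <- NA_real_
  out <- matched_pearson(rbind(staff, rse))
  expect_equal(out$r, c(1, 1, 1))
  expect_equal(out$n_pairs, c(6L, 6L, 6L))
})

test_that("the 28-day window excludes distant self-entries and ties break earlier", {
  staff <- data.table::data.table(
    participant_id = c("P01", "P02", "P03"),
    date = as.Date("2021-06-01"), instrument = "alsfrs_r",
    nominal_month = 0, score = c(30, 35, 40))
  rse <- data.table::data.table(
    participant_id = c("P01", "P02", "P02", "P03"),
    date = as.Date("2021-06-01") + c(40, -10, 10, 3),  # P01 outside window
    instrument = "alsfrs_rse", nominal_month = NA_real_,
    score = c(99, 1, 2, 41))
  expect_warning(out <- matched_pearson(rbind(staff, rse)), "2 matched")
  expect_equal(out$n_pairs, 2L)
  expect_true(is.na(out$r))
  # P02's equidistant pair resolved toward the earlier survey (score 1)
  s <- rbind(staff, rse)
  s2 <- rbind(s, data.table::data.table(
    participant_id = "P04", date = as.Date("2021-06-01"),
    instrument = c("alsfrs_r", "alsfrs_rse"), nominal_month = c(0, NA),
    score = c(20, 21)))
  out2 <- matched_pearson(s2)
  expect_equal(out2$n_pairs, 3L)
  pairs_scores <- c(1, 41, 21)  # earlier tie for P02
  expect_equal(out2$r, cor(c(35, 40, 20), pairs_scores))
})

test_that("default-cohort staff/self correlation is high at every timepoint", {
  cfg <- cohort_config(master_seed = 23)
  co <- generate_cohort(cfg, streams = "surveys")
  out <- matched_pearson(co$surveys)
  expect_equal(out$nominal_month, c(0, 3, 6))
  expect_true(all(out$r >= 0.85))
})
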