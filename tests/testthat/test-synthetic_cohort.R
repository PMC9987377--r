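# Synthetic cohort generator: structure, determinism, noiseless exactness,
# and moment agreement with the configured population parameters.

test_that("default cohort has the study's size and device split", {
  cfg <- cohort_config(master_seed = 1)
  co <- generate_cohort(cfg, streams = "surveys")
  expect_equal(nrow(co$profiles), 40L)
  expect_equal(sum(co$profiles$device == "actigraph"), 20L)
  expect_equal(sum(co$profiles$device == "modus"), 20L)
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_config(seed = 33, n = 4, days = 10)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a$surveys, NULL), serialize(b$surveys, NULL))
  expect_identical(serialize(a$wearable, NULL), serialize(b$wearable, NULL))
})

test_that("participant substreams are independent of cohort size", {
  cfg5 <- small_config(seed = 12, n = 5, days = 8)
  cfg6 <- small_config(seed = 12, n = 6, days = 8)
  co5 <- generate_cohort(cfg5)
  co6 <- generate_cohort(cfg6)
  expect_identical(co5$wearable[["P002"]], co6$wearable[["P002"]])
  expect_identical(co5$surveys[co5$surveys$participant_id == "P003", ],
                   co6$surveys[co6$surveys$participant_id == "P003", ])
})

test_that("noiseless survey trajectories are exactly baseline + slope * months", {
  cfg <- noiseless_config(n = 4, days = 150)
  co <- generate_cohort(cfg, streams = "surveys")
  s <- co$surveys
  for (ins in c("alsfrs_r", "alsfrs_rse", "roads")) {
    p <- cfg$instruments[[ins]]
    rows <- s[s$instrument == ins, ]
    expect_equal(rows$score, p$baseline + p$slope_month * rows$t_months,
                 tolerance = 1e-12)
  }
  # self-report offset applies to the self-entry ALSFRS only
  expect_equal(cfg$instruments$alsfrs_rse$baseline,
               cfg$instruments$alsfrs_r$baseline + cfg$self_report_offset)
  expect_equal(cfg$instruments$roads$baseline, 84.9)
})

test_that("scores are clipped to the instrument's admissible range", {
  cfg <- noiseless_config(n = 2, days = 150,
    instruments = list(roads = list(baseline = 5, slope_month = -30,
                                    b0_sd = 0, b1_sd = 0, resid_sd = 0)))
  co <- generate_cohort(cfg, streams = "surveys")
  r <- co$surveys[co$surveys$instrument == "roads", ]
  expect_true(any(r$score == 0))       # trajectory goes far below zero
  expect_true(all(r$score >= 0))
})

test_that("survey schedule issues both self instruments per event and staff at months 0/3/6", {
  cfg <- small_config(seed = 2, n = 3, days = 180)
  co <- generate_cohort(cfg, streams = "surveys")
  s <- co$surveys[co$surveys$participant_id == "P001", ]
  self <- s[s$instrument %in% c("alsfrs_rse", "roads"), ]
  per_day <- table(self$day, self$instrument)
  expect_true(all(per_day == 1))       # both instruments at every event
  gaps <- diff(sort(unique(self$day)))
  expect_true(all(gaps >= 14 & gaps <= 28))
  staff <- s[s$instrument == "alsfrs_r", ]
  expect_equal(sort(staff$nominal_month), c(0, 3, 6))
  expect_equal(sort(staff$day), c(0L, 91L, 179L))
})

test_that("flat activity model yields identical daily totals", {
  cfg <- noiseless_config(n = 2, days = 6,
                          activity = list(tac_slope_month = 0))
  rec <- generate_participant_wearable(generate_profile(cfg, 1), cfg)
  tac <- colSums(rec$value)
  expect_equal(max(tac) - min(tac), 0, tolerance = 1e-6)
  expect_equal(tac[1], cfg$activity$tac_baseline, tolerance = 1e-6)
})

test_that("a forced daily charging gap produces exactly 240 missing minutes", {
  cfg <- noiseless_config(n = 2, days = 5,
    missingness = list(charge_gap_prob = 1, charge_gap_minutes = 240,
                       nonwear_rate = 0, offday_prob_actigraph = 0))
  rec <- generate_participant_wearable(generate_profile(cfg, 1), cfg)
  expect_equal(unname(colSums(rec$missing)), rep(240, 5))
  expect_true(all(is.na(rec$value[rec$missing])))
})

test_that("empirical mean daily TAC matches the configured mean (Monte-Carlo)", {
  cfg <- noiseless_config(seed = 91, n = 2, days = 1000,
                          activity = list(tac_slope_month = 0, daily_sd = 2e5,
                                          minute_shape = 1))
  rec <- generate_participant_wearable(generate_profile(cfg, 1), cfg)
  tac <- colSums(rec$value)
  se <- sd(tac) / sqrt(length(tac))
  expect_lt(abs(mean(tac) - cfg$activity$tac_baseline), 3 * se)
  expect_true(all(rec$value >= 0))
})

test_that("large-cohort survey moments agree with configured baselines and slopes", {
  cfg <- cohort_config(n_participants = 500, observation_days = 180,
                       master_seed = 404)
  co <- generate_cohort(cfg, streams = "surveys")
  for (ins in c("alsfrs_rse", "roads")) {
    rows <- co$surveys[co$surveys$instrument == ins, ]
    ols <- t(vapply(split(rows, rows$participant_id), function(d)
      coef(lm(score ~ t_months, data = d)), numeric(2)))
    p <- cfg$instruments[[ins]]
    expect_lt(abs(mean(ols[, 1]) - p$baseline),
              3 * sd(ols[, 1]) / sqrt(nrow(ols)))
    expect_lt(abs(mean(ols[, 2]) - p$slope_month),
              3 * sd(ols[, 2]) / sqrt(nrow(ols)))
  }
})

test_that("latent coupling induces positive activity-survey slope correlation", {
  cfg <- cohort_config(n_participants = 500, master_seed = 77)
  co <- generate_cohort(cfg, streams = "surveys")
  # within a device arm (random-effect scales differ between arms)
  pr <- co$profiles[co$profiles$device == "actigraph", ]
  expect_gt(cor(pr$activity_b1, pr$alsfrs_b1), 0.2)
  expect_gt(cor(pr$activity_b1, pr$roads_b1), 0.2)
  # and vanishes without coupling
  cfg0 <- cohort_config(n_participants = 500, master_seed = 77,
                        latent_coupling = 0)
  pr0 <- generate_cohort(cfg0, streams = "surveys")$profiles
  pr0 <- pr0[pr0$device == "actigraph", ]
  expect_lt(abs(cor(pr0$activity_b1, pr0$alsfrs_b1)), 0.15)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(survey_interval_days = c(20, 10)),
               "survey_interval_days")
  expect_error(cohort_config(latent_coupling = 2), "latent_coupling")
  expect_error(cohort_config(
    instruments = list(roads = list(b0_sd = -1))), "roads")
})
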