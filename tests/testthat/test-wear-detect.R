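test_that("first difference is elementwise and rejects short series", {
  expect_equal(first_difference(c(22, 25, 31)), c(3, 6))
  expect_equal(first_difference(rep(21.5, 10)), rep(0, 9))
  expect_error(first_difference(22), "at least 2")
})

test_that("flat and slowly drifting traces produce no events", {
  expect_equal(nrow(detect_events(temp_series(rep(22, 144)))), 0)

  # diurnal sinusoid, amplitude 2 degC over 24 h: max per-sample change is
  # 2 * 2*pi/1440 * 10 ~ 0.087 degC, far below theta; bound it analytically
  mins <- (0:143) * 10
  sinu <- 22 + 2 * sin(2 * pi * mins / 1440)
  expect_lt(max(abs(diff(sinu))), 0.1)
  expect_equal(nrow(detect_events(temp_series(sinu))), 0)

  # linear drift of 0.1 degC per sample stays below any default threshold
  drift <- 20 + 0.1 * (0:143)
  expect_equal(nrow(detect_events(temp_series(drift))), 0)
})

test_that("a donning spike triggers a DON at the first sample of the run", {
  cfg <- degenerate_config(n_days = 1, bout = 70)
  t0 <- as.POSIXct("2024-01-01 10:00:00", tz = "UTC")
  sched <- tibble::tibble(don = t0, doff = t0 + 70 * 60, minutes = 70)
  trace <- simulate_temperature(sched, cfg, seed = 1)
  # first warming step: (32 - 22) * (1 - e^{-10/15}) = 4.866 >= 1.5
  expect_gt((32 - 22) * (1 - exp(-10 / 15)), detect_config()$theta_on)
  ev <- detect_events(trace[, c("timestamp", "temp_c")])
  expect_equal(ev$type[1], "don")
  expect_equal(ev$time[1], t0)
})

test_that("event pairing follows the alternating state machine", {
  cfg <- detect_config()
  tm <- function(x) as.POSIXct(paste0("2024-01-01 ", x), tz = "UTC")
  rs <- tm("00:00:00")
  re <- tm("23:50:00")

  ev <- tibble::tibble(time = tm(c("10:00:00", "11:10:00")),
                       type = c("don", "doff"))
  iv <- pair_events(ev, rs, re, cfg)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$minutes, 70)

  # a second DON while worn is ignored
  ev2 <- tibble::tibble(time = tm(c("10:00:00", "10:20:00", "11:00:00")),
                        type = c("don", "don", "doff"))
  iv2 <- pair_events(ev2, rs, re, cfg)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$minutes, 60)

  # a leading DOFF closes a bout open at the record start
  ev3 <- tibble::tibble(time = tm("09:00:00"), type = "doff")
  iv3 <- pair_events(ev3, rs, re, cfg)
  expect_equal(nrow(iv3), 1)
  expect_equal(iv3$don, rs)
  expect_equal(iv3$minutes, 540)

  # a DON left open closes at the record end
  ev4 <- tibble::tibble(time = tm("22:00:00"), type = "don")
  iv4 <- pair_events(ev4, rs, re, cfg)
  expect_equal(iv4$doff, re)

  # sub-min_bout bouts are dropped; near-adjacent bouts merge
  ev5 <- tibble::tibble(
    time = tm(c("10:00:00", "10:05:00", "12:00:00", "13:00:00",
                "13:10:00", "14:00:00")),
    type = c("don", "doff", "don", "doff", "don", "doff")
  )
  iv5 <- pair_events(ev5, rs, re, cfg)
  expect_equal(nrow(iv5), 1)  # 5-min bout dropped, 10-min gap merged
  expect_equal(iv5$don, tm("12:00:00"))
  expect_equal(iv5$doff, tm("14:00:00"))
})

test_that("noise-free detection recovers a single bout within one sample per edge", {
  cfg <- degenerate_config(n_days = 2, bout = 70, seed = 4)
  sched <- simulate_wear_schedule(cfg, 1)
  trace <- simulate_temperature(sched, cfg, seed = 4)
  iv <- detect_wear(trace[, c("timestamp", "temp_c")])
  expect_equal(nrow(iv), nrow(sched))
  expect_true(all(abs(iv$minutes - sched$minutes) <= 20))
})

test_that("detection is invariant to a constant temperature offset", {
  cfg <- sim_config(n_participants = 1, n_days = 7, sensor_noise_sd = 0,
                    confounder_rate = 0, seed = 31)
  trace <- simulate_temperature(simulate_wear_schedule(cfg, 1), cfg, seed = 31)
  base <- detect_wear(trace[, c("timestamp", "temp_c")])
  shifted <- trace[, c("timestamp", "temp_c")]
  shifted$temp_c <- shifted$temp_c + 7.3
  expect_equal(detect_wear(shifted), base)
})

test_that("raising theta_on never increases the number of DON events", {
  cfg <- sim_config(n_participants = 1, n_days = 7, seed = 8)
  trace <- simulate_temperature(simulate_wear_schedule(cfg, 1), cfg, seed = 8)
  series <- trace[, c("timestamp", "temp_c")]
  thetas <- c(0.5, 1, 1.5, 2.5, 4)
  n_don <- vapply(thetas, function(th) {
    ev <- detect_events(series, detect_config(theta_on = th))
    sum(ev$type == "don")
  }, numeric(1))
  expect_true(all(diff(n_don) <= 0))
})

test_that("detected intervals are sorted, non-overlapping and >= min_bout", {
  cfg <- sim_config(n_participants = 3, n_days = 14, seed = 17)
  cohort <- simulate_cohort(cfg)
  iv <- detect_wear(cohort$sensor)
  for (pid in unique(iv$participant_id)) {
    p <- iv[iv$participant_id == pid, ]
    expect_true(all(p$minutes >= detect_config()$min_bout))
    if (nrow(p) > 1) {
      expect_true(all(as.numeric(p$don[-1]) >=
                        as.numeric(p$doff[-nrow(p)])))
    }
  }
})

test_that("sampling gaps split the record instead of creating phantom bouts", {
  cfg <- degenerate_config(n_days = 2, p_wear_day = 0)
  trace <- simulate_temperature(simulate_wear_schedule(cfg, 1), cfg, seed = 2)
  series <- trace[, c("timestamp", "temp_c")]
  # drop 3 hours of samples; the cold restart must not register wear
  series <- series[-(100:117), ]
  expect_equal(nrow(detect_wear(series)), 0)
})

test_that("the plateau check rejects brief spikes but keeps sustained wear", {
  cfg <- detect_config(plateau_check = TRUE)
  # one-sample spike: +5 degC then straight back down
  spike <- temp_series(c(rep(22, 20), 27, rep(22, 20)))
  expect_equal(nrow(detect_wear(spike, cfg)), 0)

  # genuine wear plateau survives the check
  scfg <- degenerate_config(n_days = 1, bout = 70)
  t0 <- as.POSIXct("2024-01-01 12:00:00", tz = "UTC")
  sched <- tibble::tibble(don = t0, doff = t0 + 70 * 60, minutes = 70)
  trace <- simulate_temperature(sched, scfg, seed = 3)
  iv <- detect_wear(trace[, c("timestamp", "temp_c")], cfg)
  expect_equal(nrow(iv), 1)
})
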