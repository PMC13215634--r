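test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(p_wear_day = 1.2), "p_wear_day")
  expect_error(sim_config(sampling_interval = 7), "sampling_interval")
  expect_error(sim_config(tau_on = 0), "tau_on")
  expect_error(sim_config(t_skin = 20, t_ambient_mean = 22), "t_skin")
  expect_error(sim_config(n_days = 0), "n_days")
})

test_that("wear schedule honours degenerate probabilities and durations", {
  cfg0 <- degenerate_config(n_days = 10, p_wear_day = 0)
  expect_equal(nrow(simulate_wear_schedule(cfg0, 1)), 0)

  cfg1 <- degenerate_config(n_days = 10, bout = 70)
  sched <- simulate_wear_schedule(cfg1, 1)
  expect_equal(nrow(sched), 10)
  expect_true(all(sched$minutes == 70))
  expect_equal(length(unique(as.Date(sched$don))), 10)
})

test_that("wear-day fraction matches the configured Bernoulli rate", {
  cfg <- sim_config(n_participants = 1, n_days = 1000,
                    subject_pwear_sdlogit = 0, seed = 2024)
  sched <- simulate_wear_schedule(cfg, 1)
  frac <- length(unique(as.Date(sched$don))) / 1000
  expect_lt(abs(frac - 0.7), 0.03)
})

test_that("schedules are sorted, non-overlapping and inside the window", {
  for (s in 1:5) {
    cfg <- sim_config(n_participants = 1, n_days = 42, seed = s)
    sched <- simulate_wear_schedule(cfg, 1)
    expect_true(all(diff(as.numeric(sched$don)) > 0))
    expect_true(all(as.numeric(sched$doff[-nrow(sched)]) <=
                      as.numeric(sched$don[-1])))
    expect_true(all(sched$don >= as.POSIXct(paste(cfg$start_date), tz = "UTC")))
    expect_true(all(sched$doff <= as.POSIXct(paste(cfg$start_date + 42), tz = "UTC")))
    expect_true(all(sched$minutes >= cfg$sampling_interval))
  }
})

test_that("an empty schedule with no noise or diurnal cycle gives a flat trace", {
  cfg <- degenerate_config(n_days = 1, p_wear_day = 0)
  trace <- simulate_temperature(simulate_wear_schedule(cfg, 1), cfg, seed = 1)
  expect_equal(nrow(trace), 144)
  expect_true(all(trace$temp_c == cfg$t_ambient_mean))
  expect_true(all(!trace$worn))
})

test_that("noise-free trace matches the closed-form Newtonian relaxation", {
  cfg <- degenerate_config(n_days = 1, bout = 70)
  sched <- simulate_wear_schedule(cfg, 1)
  trace <- simulate_temperature(sched, cfg, seed = 1)

  # independent oracle: closed-form exponential relaxation, recomputed here
  a_on <- exp(-10 / cfg$tau_on)
  a_off <- exp(-10 / cfg$tau_off)
  oracle <- numeric(nrow(trace))
  oracle[1] <- cfg$t_ambient_mean
  for (k in 1:(nrow(trace) - 1)) {
    tgt <- if (trace$worn[k]) cfg$t_skin else cfg$t_ambient_mean
    a <- if (trace$worn[k]) a_on else a_off
    oracle[k + 1] <- tgt + (oracle[k] - tgt) * a
  }
  expect_true(all(abs(trace$temp_c - oracle) <= cfg$quantization / 2 + 1e-9))

  # spot-check the first warming step: T(t0 + 10) = T(t0) + dT (1 - e^{-10/tau})
  k0 <- which(trace$worn)[1]
  step <- (cfg$t_skin - oracle[k0]) * (1 - exp(-10 / cfg$tau_on))
  expect_lt(abs(trace$temp_c[k0 + 1] - (oracle[k0] + step)),
            cfg$quantization / 2 + 1e-9)
})

test_that("a 70-minute sample-aligned bout covers exactly 7 samples", {
  cfg <- degenerate_config(n_days = 1, bout = 70)
  t0 <- as.POSIXct(paste(cfg$start_date), tz = "UTC") + 600 * 60
  sched <- tibble::tibble(don = t0, doff = t0 + 70 * 60, minutes = 70)
  trace <- simulate_temperature(sched, cfg, seed = 1)
  expect_equal(sum(trace$worn), 7)
})

test_that("mask minutes agree with interval durations within one sample per transition", {
  for (s in 1:4) {
    cfg <- sim_config(n_participants = 1, n_days = 14, seed = s)
    sched <- simulate_wear_schedule(cfg, 1)
    trace <- simulate_temperature(sched, cfg, seed = s + 100)
    mask_min <- sum(trace$worn) * cfg$sampling_interval
    true_min <- sum(sched$minutes)
    expect_lte(abs(mask_min - true_min),
               cfg$sampling_interval * 2 * nrow(sched))
  }
})

test_that("self-report is the identity in the unbiased degenerate case", {
  cfg <- degenerate_config(n_days = 5)
  truth <- daily_minutes(simulate_wear_schedule(cfg, 1), cfg$start_date,
                         cfg$start_date + 4)
  log <- simulate_self_report(truth, cfg, seed = 9, participant_index = 2)
  expect_equal(nrow(log), 5)
  expect_equal(log$minutes, truth$minutes)
})

test_that("reported minutes round half away from zero to the rounding unit", {
  cfg <- degenerate_config(n_days = 1, report_rounding = 15)
  truth <- tibble::tibble(date = cfg$start_date, minutes = 70)
  log <- simulate_self_report(truth, cfg, seed = 1, participant_index = 2)
  # oracle: 70 / 15 = 4.67 -> 5 -> 75 under half-away-from-zero
  expect_equal(log$minutes, 75)
})

test_that("phantom days make every no-wear entry positive when forced", {
  cfg <- degenerate_config(n_days = 20, p_wear_day = 0, p_phantom_day = 1)
  truth <- tibble::tibble(date = seq(cfg$start_date, by = "day",
                                     length.out = 20),
                          minutes = rep(0, 20))
  log <- simulate_self_report(truth, cfg, seed = 5, participant_index = 2)
  expect_equal(nrow(log), 20)
  expect_true(all(log$minutes > 0))
})

test_that("with no missing-log probability the log has one entry per day", {
  cfg <- sim_config(n_participants = 3, n_days = 42, p_missing_log = 0,
                    p_missing_log_hi = 0, seed = 77)
  cohort <- simulate_cohort(cfg)
  counts <- table(cohort$selfreport$participant_id)
  expect_true(all(counts == 42))
})

test_that("cohorts are seed-reproducible and participant substreams independent", {
  cfg <- sim_config(n_participants = 3, n_days = 7, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sensor, b$sensor)
  expect_identical(a$selfreport, b$selfreport)
  expect_identical(a$truth, b$truth)

  # different seed -> different trace
  c2 <- simulate_cohort(sim_config(n_participants = 3, n_days = 7,
                                   seed = 124))
  expect_false(identical(a$sensor$temp_c, c2$sensor$temp_c))

  # growing the cohort leaves earlier participants untouched
  big <- simulate_cohort(sim_config(n_participants = 5, n_days = 7,
                                    seed = 123))
  expect_identical(a$sensor,
                   big$sensor[big$sensor$participant_id %in%
                                c("P01", "P02", "P03"), ])
})

test_that("cohort dimensions follow n_days and the sampling interval", {
  cfg <- sim_config(n_participants = 2, n_days = 42, seed = 5)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$sensor), 2 * 42 * 144)
})
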