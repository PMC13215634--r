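# Synthetic cohort generator: wear schedules, brace temperature traces under
# first-order (Newtonian) thermal relaxation, and biased daily self-report
# logs, all with full ground truth.

#' Simulate one participant's wear schedule
#'
#' Draws, day by day, whether the brace is worn (Bernoulli) and, on wear days,
#' a single bout whose duration comes from a normal distribution truncated
#' below at the sampling interval and rounded to whole minutes. Between-
#' participant heterogeneity enters through a log-normal multiplier on the
#' bout-duration mean and a logit-normal shift on the wear-day probability,
#' both drawn once per participant from a substream of the master seed, so a
#' participant's schedule is invariant to cohort size.
#'
#' @param config A [sim_config()].
#' @param participant_index 1-based participant index (selects the RNG
#'   substream).
#' @return A tibble of wear bouts with columns `don`, `doff` (POSIXct) and
#'   `minutes`, sorted and non-overlapping. Bouts are truncated at 23:59
#'   unless `config$allow_midnight_span` is TRUE.
#' @export
simulate_wear_schedule <- function(config, participant_index) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::local_seed(substream_seed(config$seed, participant_index, 1L))

  # participant-level random effects (drawn even when their SD is 0 so the
  # stream layout is stable across configurations)
  z_mu <- rnorm(1)
  z_p <- rnorm(1)
  mu_i <- config$bout_minutes_mean * exp(config$subject_bout_sdlog * z_mu)
  p_i <- plogis(qlogis(config$p_wear_day) + config$subject_pwear_sdlogit * z_p)

  wear <- runif(config$n_days) < p_i
  days <- which(wear)
  if (length(days) == 0) {
    return(tibble::tibble(
      don = as.POSIXct(character(), tz = wear_tz()),
      doff = as.POSIXct(character(), tz = wear_tz()),
      minutes = numeric()
    ))
  }
  dur <- round_half_away(
    rtnorm_min(length(days), mu_i, config$bout_minutes_sd,
               config$sampling_interval)
  )
  start <- pmin(
    floor(runif(length(days), config$bout_start_earliest,
                config$bout_start_latest + 1)),
    config$bout_start_latest
  )
  don_min <- (days - 1) * 1440 + start
  doff_min <- don_min + dur
  if (!config$allow_midnight_span) {
    doff_min <- pmin(doff_min, (days - 1) * 1440 + 1439)
  } else {
    if (length(days) > 1) {
      # a bout spilling past midnight must not overlap the next day's bout
      doff_min[-length(days)] <- pmin(doff_min[-length(days)], don_min[-1])
    }
    # and the last bout stays inside the observation window
    doff_min[length(days)] <- min(doff_min[length(days)],
                                  config$n_days * 1440)
  }
  keep <- doff_min - don_min >= config$sampling_interval
  don_min <- don_min[keep]
  doff_min <- doff_min[keep]
  t0 <- day_start(config$start_date)
  tibble::tibble(
    don = t0 + don_min * 60,
    doff = t0 + doff_min * 60,
    minutes = doff_min - don_min
  )
}

# Ambient temperature (degC) at `rel_min` minutes since the window start:
# diurnal sinusoid peaking at 15:00.
ambient_at <- function(rel_min, config) {
  mod <- rel_min %% 1440
  config$t_ambient_mean +
    config$ambient_diurnal_amp * sin(2 * pi * (mod - 540) / 1440)
}

#' Simulate the sensor temperature trace for one schedule
#'
#' Integrates first-order Newtonian relaxation at the sensor sampling
#' interval: while the brace is worn the temperature relaxes toward the skin
#' temperature with time constant `tau_on`; off the body it relaxes toward
#' the (diurnal) ambient with `tau_off`. Transient ambient confounder events
#' (hot car, air-conditioned room) add a temporary ambient step. Gaussian
#' sensor noise is added and values are quantized to the sensor precision.
#'
#' The ground-truth wear mask uses the half-open convention: a sample at time
#' t is "worn" iff `don <= t < doff` for some bout, and the relaxation target
#' over `(t_k, t_{k+1}]` is determined by the state at `t_k`.
#'
#' @param schedule Tibble of bouts as from [simulate_wear_schedule()]
#'   (columns `don`, `doff`), sorted and non-overlapping.
#' @param config A [sim_config()].
#' @param seed RNG seed for noise and confounder draws.
#' @return A tibble with `timestamp`, `temp_c` (quantized), and the truth
#'   mask `worn`.
#' @export
simulate_temperature <- function(schedule, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(schedule) > 1) {
    d <- as.numeric(schedule$don[-1]) - as.numeric(schedule$doff[-nrow(schedule)])
    if (any(d < 0)) stop("schedule bouts must be sorted and non-overlapping")
  }
  si <- config$sampling_interval
  n <- config$n_days * 1440 / si
  rel_min <- (seq_len(n) - 1) * si
  t0 <- day_start(config$start_date)
  timestamps <- t0 + rel_min * 60
  ts_num <- as.numeric(timestamps)

  # truth mask: sample covered by a bout under the [don, doff) convention
  worn <- rep(FALSE, n)
  if (nrow(schedule) > 0) {
    idx <- findInterval(ts_num, as.numeric(schedule$don))
    hit <- idx >= 1
    worn[hit] <- ts_num[hit] < as.numeric(schedule$doff)[idx[hit]]
  }

  ambient <- ambient_at(rel_min, config)

  withr::local_seed(seed)
  # confounder events: transient ambient steps, by default only while the
  # brace is off (a hot car during wear is physically confounded with wear)
  n_ev <- rpois(1, config$confounder_rate * config$n_days)
  offset <- rep(0, n)
  if (n_ev > 0 && config$confounder_amp > 0 && config$confounder_duration > 0) {
    starts <- runif(n_ev, 0, config$n_days * 1440)
    for (s in starts) {
      in_ev <- rel_min >= s & rel_min < s + config$confounder_duration
      if (!config$confounders_during_wear && any(worn[in_ev])) next
      offset[in_ev] <- offset[in_ev] + config$confounder_amp
    }
  }
  noise <- rnorm(n, 0, config$sensor_noise_sd)

  a_on <- exp(-si / config$tau_on)
  a_off <- exp(-si / config$tau_off)
  temp <- numeric(n)
  temp[1] <- ambient[1] + offset[1]
  tgt_off <- ambient + offset
  for (k in seq_len(n - 1)) {
    if (worn[k]) {
      temp[k + 1] <- config$t_skin + (temp[k] - config$t_skin) * a_on
    } else {
      temp[k + 1] <- tgt_off[k] + (temp[k] - tgt_off[k]) * a_off
    }
  }

  tibble::tibble(
    timestamp = timestamps,
    temp_c = quantize(temp + noise, config$quantization),
    worn = worn
  )
}

#' Simulate a biased daily self-report log
#'
#' For each true wear day the reported value is
#' `round_to(rounding, max(0, gain * true + Normal(0, noise_sd)))`; a true
#' no-wear day is reported as worn ("phantom day") with probability
#' `p_phantom_day`, with minutes drawn from the bout distribution; each day's
#' entry is missing entirely with the participant's missing-log probability.
#' Rounding is half-away-from-zero. This bias model can produce both
#' under-reporting of average daily minutes and over-reporting of the number
#' of days worn, the two signatures seen when self-report is compared with an
#' objective sensor.
#'
#' @param truth_daily Tibble with columns `date`, `minutes`: one
#'   participant's true daily wear minutes.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param participant_index Used only to pick the missing-log rate (the
#'   designated high-missingness participant uses `p_missing_log_hi`).
#' @return Tibble with `date`, `minutes`; days with a missing log entry are
#'   absent from the tibble.
#' @export
simulate_self_report <- function(truth_daily, config, seed,
                                 participant_index = 0L) {
  stopifnot(inherits(config, "sim_config"),
            all(c("date", "minutes") %in% names(truth_daily)))
  p_miss <- if (participant_index == config$hi_missing_participant) {
    config$p_missing_log_hi
  } else {
    config$p_missing_log
  }
  n <- nrow(truth_daily)
  withr::local_seed(seed)
  u_miss <- runif(n)
  noise <- rnorm(n, 0, config$report_noise_sd)
  u_phantom <- runif(n)
  phantom <- round_half_away(
    rtnorm_min(n, config$bout_minutes_mean, config$bout_minutes_sd,
               config$sampling_interval)
  )

  true <- truth_daily$minutes
  r_unit <- config$report_rounding
  reported <- ifelse(
    true > 0,
    r_unit * round_half_away(
      pmax(0, config$report_gain * true + noise) / r_unit
    ),
    ifelse(u_phantom < config$p_phantom_day,
           r_unit * round_half_away(phantom / r_unit),
           0)
  )
  reported <- pmin(reported, 1440)
  tibble::tibble(date = truth_daily$date, minutes = reported)[u_miss >= p_miss, ]
}

#' Simulate a full cohort with ground truth
#'
#' Runs [simulate_wear_schedule()], [simulate_temperature()] and
#' [simulate_self_report()] for every participant, each on its own RNG
#' substream derived from `config$seed`, so the bundle is deterministic given
#' the config and participant k's data do not change when `n_participants`
#' changes.
#'
#' @param config A [sim_config()].
#' @return A list of class `"wear_cohort"` with elements `config`, `sensor`
#'   (tibble: participant_id, timestamp, temp_c), `selfreport` (tibble:
#'   participant_id, date, minutes; missing entries absent), and `truth`
#'   (list with `intervals`, `daily`, `mask` tibbles).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 2, n_days = 3,
#'                                      seed = 7))
#' head(cohort$sensor)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  window_end <- config$start_date + config$n_days - 1

  sensor <- vector("list", config$n_participants)
  report <- vector("list", config$n_participants)
  intervals <- vector("list", config$n_participants)
  daily <- vector("list", config$n_participants)
  mask <- vector("list", config$n_participants)

  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    sched <- simulate_wear_schedule(config, i)
    trace <- simulate_temperature(sched, config,
                                  substream_seed(config$seed, i, 2L))
    truth_daily <- daily_minutes(sched, config$start_date, window_end)
    log <- simulate_self_report(truth_daily, config,
                                substream_seed(config$seed, i, 3L), i)

    sensor[[i]] <- tibble::tibble(participant_id = pid,
                                  timestamp = trace$timestamp,
                                  temp_c = trace$temp_c)
    mask[[i]] <- tibble::tibble(participant_id = pid,
                                timestamp = trace$timestamp,
                                worn = trace$worn)
    intervals[[i]] <- tibble::tibble(participant_id = pid,
                                     don = sched$don, doff = sched$doff,
                                     minutes = sched$minutes)
    daily[[i]] <- tibble::tibble(participant_id = pid,
                                 date = truth_daily$date,
                                 minutes = truth_daily$minutes)
    report[[i]] <- tibble::tibble(participant_id = pid,
                                  date = log$date, minutes = log$minutes)
  }

  structure(
    list(
      config = config,
      sensor = dplyr::bind_rows(sensor),
      selfreport = dplyr::bind_rows(report),
      truth = list(
        intervals = dplyr::bind_rows(intervals),
        daily = dplyr::bind_rows(daily),
        mask = dplyr::bind_rows(mask)
      )
    ),
    class = "wear_cohort"
  )
}
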