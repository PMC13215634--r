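# Shared fixtures, all generated in code.

# Homogeneous, fully deterministic wear behaviour: every day one bout of
# exactly `bout` minutes, no noise anywhere.
degenerate_config <- function(n_days = 3, bout = 70, seed = 1, ...) {
  defaults <- list(
    n_participants = 1, n_days = n_days, seed = seed,
    p_wear_day = 1, bout_minutes_mean = bout, bout_minutes_sd = 0,
    subject_bout_sdlog = 0, subject_pwear_sdlogit = 0,
    sensor_noise_sd = 0, ambient_diurnal_amp = 0, confounder_rate = 0,
    report_gain = 1, report_noise_sd = 0, report_rounding = 1,
    p_phantom_day = 0, p_missing_log = 0, p_missing_log_hi = 0
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Daily series tibble builder for agreement/sensitivity tests.
daily_tbl <- function(values_by_participant,
                      start = as.Date("2024-01-01")) {
  dplyr::bind_rows(lapply(names(values_by_participant), function(pid) {
    v <- values_by_participant[[pid]]
    tibble::tibble(participant_id = pid,
                   date = seq(start, by = "day", length.out = length(v)),
                   minutes = v)
  }))
}

# Minimal single-day temperature series at 10-min sampling from a numeric
# vector of temperatures.
temp_series <- function(temps, start = "2024-01-01 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(timestamp = t0 + (seq_along(temps) - 1) * 600,
                 temp_c = temps)
}
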