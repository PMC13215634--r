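#' Configuration for the synthetic wear-time cohort generator
#'
#' Bundles every knob of the synthetic cohort: study window, sensor physics,
#' wear behaviour, environmental confounders, and the self-report bias model.
#' Defaults emulate a 6-week brace trial: temperature logged every 10 minutes
#' at 0.1 degC precision, participants advised to wear the brace at least an
#' hour a day (bout mean 70 min), day-level self-report with over-reporting of
#' days worn and noisy minute recall, and a small number of missing log
#' entries concentrated in a single participant.
#'
#' @param n_participants Number of participants in the cohort.
#' @param n_days Length of the observation window in days (default 42, i.e.
#'   6 weeks).
#' @param sampling_interval Sensor sampling interval in minutes; must divide
#'   1440.
#' @param t_skin Skin-contact equilibrium temperature in degC while the brace
#'   is worn.
#' @param t_ambient_mean Mean ambient temperature in degC.
#' @param ambient_diurnal_amp Amplitude in degC of the sinusoidal diurnal
#'   ambient cycle (peak mid-afternoon).
#' @param tau_on Warming time constant in minutes (relaxation toward
#'   `t_skin` on donning).
#' @param tau_off Cooling time constant in minutes (relaxation toward ambient
#'   on doffing).
#' @param sensor_noise_sd Gaussian sensor noise SD in degC, applied before
#'   quantization.
#' @param quantization Sensor quantization step in degC (0.1 matches a
#'   +/- 0.1 degC device).
#' @param p_wear_day Probability that a day has at least one wear bout.
#' @param bout_minutes_mean,bout_minutes_sd Mean/SD in minutes of the
#'   truncated-normal bout duration (truncated below at `sampling_interval`).
#' @param confounder_rate Expected ambient confounder events per day (hot
#'   car, air-conditioned room, ...).
#' @param confounder_amp Ambient step in degC added during a confounder
#'   event.
#' @param confounder_duration Confounder event duration in minutes.
#' @param confounders_during_wear Allow confounder events to overlap wear
#'   bouts (default FALSE: off-wear only, which isolates false-positive
#'   testing).
#' @param report_gain Multiplicative recall bias on true daily minutes.
#' @param report_noise_sd SD in minutes of additive recall noise.
#' @param report_rounding Rounding unit in minutes for reported values
#'   (round half away from zero).
#' @param p_phantom_day Probability a true no-wear day is reported as worn.
#' @param p_missing_log Baseline probability a day's log entry is absent.
#' @param p_missing_log_hi Missing-log probability for the designated
#'   high-missingness participant (real cohorts concentrate missing logs in
#'   one or two people).
#' @param hi_missing_participant Index of the high-missingness participant
#'   (0 disables the elevated rate).
#' @param subject_bout_sdlog Between-participant SD on the log scale of the
#'   bout-duration mean (log-normal multiplier; 0 = homogeneous cohort).
#' @param subject_pwear_sdlogit Between-participant SD on the logit scale of
#'   `p_wear_day` (0 = homogeneous cohort).
#' @param bout_start_earliest,bout_start_latest Earliest/latest bout start,
#'   minutes after midnight.
#' @param allow_midnight_span Allow bouts to cross midnight (default FALSE:
#'   truncated at 23:59).
#' @param start_date First calendar day of the window.
#' @param seed Master RNG seed; every participant draws from named substreams
#'   derived from it, so earlier participants are unchanged when the cohort
#'   grows.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, n_days = 7, seed = 42)
#' cfg$p_wear_day
sim_config <- function(n_participants = 10,
                       n_days = 42,
                       sampling_interval = 10,
                       t_skin = 32.0,
                       t_ambient_mean = 22.0,
                       ambient_diurnal_amp = 2.0,
                       tau_on = 15,
                       tau_off = 20,
                       sensor_noise_sd = 0.2,
                       quantization = 0.1,
                       p_wear_day = 0.7,
                       bout_minutes_mean = 70,
                       bout_minutes_sd = 30,
                       confounder_rate = 0.1,
                       confounder_amp = 8.0,
                       confounder_duration = 40,
                       confounders_during_wear = FALSE,
                       report_gain = 1.0,
                       report_noise_sd = 20,
                       report_rounding = 15,
                       p_phantom_day = 0.15,
                       p_missing_log = 0.005,
                       p_missing_log_hi = 0.31,
                       hi_missing_participant = 1,
                       subject_bout_sdlog = 0.35,
                       subject_pwear_sdlogit = 0.8,
                       bout_start_earliest = 480,
                       bout_start_latest = 1260,
                       allow_midnight_span = FALSE,
                       start_date = as.Date("2024-01-01"),
                       seed = 1) {
  cfg <- list(
    n_participants = n_participants, n_days = n_days,
    sampling_interval = sampling_interval,
    t_skin = t_skin, t_ambient_mean = t_ambient_mean,
    ambient_diurnal_amp = ambient_diurnal_amp,
    tau_on = tau_on, tau_off = tau_off,
    sensor_noise_sd = sensor_noise_sd, quantization = quantization,
    p_wear_day = p_wear_day,
    bout_minutes_mean = bout_minutes_mean, bout_minutes_sd = bout_minutes_sd,
    confounder_rate = confounder_rate, confounder_amp = confounder_amp,
    confounder_duration = confounder_duration,
    confounders_during_wear = confounders_during_wear,
    report_gain = report_gain, report_noise_sd = report_noise_sd,
    report_rounding = report_rounding,
    p_phantom_day = p_phantom_day,
    p_missing_log = p_missing_log, p_missing_log_hi = p_missing_log_hi,
    hi_missing_participant = hi_missing_participant,
    subject_bout_sdlog = subject_bout_sdlog,
    subject_pwear_sdlogit = subject_pwear_sdlogit,
    bout_start_earliest = bout_start_earliest,
    bout_start_latest = bout_start_latest,
    allow_midnight_span = allow_midnight_span,
    start_date = as.Date(start_date),
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid sim_config field `", field, "`: ", why, call. = FALSE)
  }
  num1 <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      bad(field, "must be a single finite number")
    }
    x
  }
  for (f in c("p_wear_day", "p_phantom_day", "p_missing_log",
              "p_missing_log_hi")) {
    x <- num1(f)
    if (x < 0 || x > 1) bad(f, "probability must lie in [0, 1]")
  }
  if (num1("n_participants") < 1) bad("n_participants", "must be >= 1")
  if (num1("n_days") < 1) bad("n_days", "must be >= 1")
  si <- num1("sampling_interval")
  if (si <= 0 || 1440 %% si != 0) {
    bad("sampling_interval", "must be positive and divide 1440")
  }
  if (num1("tau_on") <= 0) bad("tau_on", "must be > 0")
  if (num1("tau_off") <= 0) bad("tau_off", "must be > 0")
  if (num1("t_skin") <= num1("t_ambient_mean")) {
    bad("t_skin", "must exceed t_ambient_mean")
  }
  for (f in c("sensor_noise_sd", "ambient_diurnal_amp", "bout_minutes_sd",
              "confounder_rate", "confounder_amp", "confounder_duration",
              "report_noise_sd", "subject_bout_sdlog",
              "subject_pwear_sdlogit")) {
    if (num1(f) < 0) bad(f, "must be >= 0")
  }
  if (num1("quantization") <= 0) bad("quantization", "must be > 0")
  if (num1("report_gain") < 0) bad("report_gain", "must be >= 0")
  if (num1("report_rounding") < 1) bad("report_rounding", "must be >= 1")
  if (num1("bout_minutes_mean") < cfg$sampling_interval) {
    bad("bout_minutes_mean", "must be >= sampling_interval")
  }
  lo <- num1("bout_start_earliest")
  hi <- num1("bout_start_latest")
  if (lo < 0 || hi > 1439 || lo > hi) {
    bad("bout_start_earliest", "need 0 <= earliest <= latest <= 1439")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_participants, " participants x ", x$n_days,
      " days, sensor every ", x$sampling_interval, " min\n",
      "  physics: skin ", x$t_skin, " degC, ambient ", x$t_ambient_mean,
      " +/- ", x$ambient_diurnal_amp, " degC, tau on/off ",
      x$tau_on, "/", x$tau_off, " min, noise SD ", x$sensor_noise_sd,
      " degC (q = ", x$quantization, ")\n",
      "  behaviour: P(wear day) ", x$p_wear_day, ", bouts ~ ",
      x$bout_minutes_mean, " +/- ", x$bout_minutes_sd, " min\n",
      "  self-report: gain ", x$report_gain, ", noise SD ",
      x$report_noise_sd, " min, rounding ", x$report_rounding,
      " min, P(phantom) ", x$p_phantom_day, "\n", sep = "")
  invisible(x)
}
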