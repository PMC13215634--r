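# CSV/JSON readers and writers and the end-to-end pipeline. CSV dialect:
# comma-separated, UTF-8, mandatory header. Timestamps are naive local time
# in ISO-8601 (single-site study); a `tz` column, if present, is ignored
# with a warning.

#' Read a sensor temperature CSV
#'
#' Expected columns: `participant_id`, `timestamp` (ISO-8601), `temp_c`.
#' Timestamps must be strictly increasing within each participant
#' (duplicates and out-of-order rows are rejected with their line number);
#' sampling gaps larger than twice the modal interval are reported via the
#' `"gaps"` attribute and a message.
#'
#' @param path Path to the CSV file.
#' @return Tibble `participant_id`, `timestamp` (POSIXct), `temp_c`, with a
#'   `"gaps"` attribute listing any sampling gaps.
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("participant_id", "timestamp", "temp_c")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("sensor CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  if ("tz" %in% names(raw)) {
    warning("timezone column present in ", path,
            "; timestamps are treated as naive local time and `tz` is ignored")
  }
  ts <- parse_iso_ts(raw$timestamp)
  temp <- suppressWarnings(as.numeric(raw$temp_c))
  bad <- which(is.na(ts) | is.na(temp))
  if (length(bad) > 0) {
    stop("malformed sensor row(s) at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  }
  out <- tibble::tibble(participant_id = raw$participant_id,
                        timestamp = ts, temp_c = temp)
  gaps <- list()
  for (pid in unique(out$participant_id)) {
    rows <- which(out$participant_id == pid)
    tnum <- as.numeric(out$timestamp[rows])
    d <- diff(tnum)
    dup <- which(d <= 0)
    if (length(dup) > 0) {
      stop("duplicate or non-monotone timestamp for participant ", pid,
           " at line ", rows[dup[1] + 1] + 1, " of ", path)
    }
    interval <- median(d)
    gap_at <- which(d > 2 * interval)
    if (length(gap_at) > 0) {
      gaps[[pid]] <- tibble::tibble(
        participant_id = pid,
        gap_start = out$timestamp[rows[gap_at]],
        gap_minutes = d[gap_at] / 60
      )
    }
  }
  gaps <- dplyr::bind_rows(gaps)
  if (nrow(gaps) > 0) {
    message(nrow(gaps), " sampling gap(s) found in ", path)
  }
  attr(out, "gaps") <- gaps
  out
}

#' Write a sensor temperature CSV
#'
#' @param sensor Tibble `participant_id`, `timestamp`, `temp_c`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(sensor, path) {
  df <- data.frame(
    participant_id = sensor$participant_id,
    timestamp = format(sensor$timestamp, "%Y-%m-%dT%H:%M:%S"),
    temp_c = sprintf("%.1f", sensor$temp_c)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a self-report daily log CSV
#'
#' Expected columns: `participant_id`, `date` (ISO-8601), `minutes`. An
#' absent row is a missing log entry. Minutes must be integers in
#' `[0, 1440]`; duplicate participant-dates are rejected.
#'
#' @param path Path to the CSV file.
#' @param window_start,window_end Optional window bounds; when given, the log
#'   is expanded to a calendar-complete daily series with `NA` for absent
#'   days (see [selfreport_daily()]).
#' @return Tibble `participant_id`, `date`, `minutes`.
#' @export
read_selfreport_csv <- function(path, window_start = NULL,
                                window_end = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("participant_id", "date", "minutes")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("self-report CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  date <- as.Date(raw$date)
  minutes <- suppressWarnings(as.numeric(raw$minutes))
  bad <- which(is.na(date) | is.na(minutes))
  if (length(bad) > 0) {
    stop("malformed self-report row(s) at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  }
  if (any(minutes < 0)) {
    stop("negative minutes at line ",
         which(minutes < 0)[1] + 1, " of ", path)
  }
  if (any(minutes > 1440)) {
    stop("minutes exceed 1440 at line ",
         which(minutes > 1440)[1] + 1, " of ", path)
  }
  key <- paste(raw$participant_id, date)
  if (anyDuplicated(key)) {
    stop("duplicate participant-date at line ",
         which(duplicated(key))[1] + 1, " of ", path)
  }
  log <- tibble::tibble(participant_id = raw$participant_id,
                        date = date, minutes = minutes)
  if (!is.null(window_start) && !is.null(window_end)) {
    return(selfreport_daily(log, window_start, window_end))
  }
  log
}

#' Write a self-report daily log CSV
#'
#' Rows with `NA` minutes (missing log entries) are omitted: absence of a
#' row is how the format encodes a missing entry.
#'
#' @param log Tibble `participant_id`, `date`, `minutes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selfreport_csv <- function(log, path) {
  log <- log[!is.na(log$minutes), ]
  df <- data.frame(participant_id = log$participant_id,
                   date = format(log$date),
                   minutes = log$minutes)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write / read a wear-interval CSV
#'
#' Columns: `participant_id`, `don`, `doff` (ISO-8601), `minutes`.
#'
#' @param intervals Tibble of wear intervals.
#' @param path File path.
#' @return `path` (writer) or the intervals tibble (reader).
#' @export
write_intervals_csv <- function(intervals, path) {
  df <- data.frame(
    participant_id = intervals$participant_id %||%
      rep("P01", nrow(intervals)),
    don = format(intervals$don, "%Y-%m-%dT%H:%M:%S"),
    doff = format(intervals$doff, "%Y-%m-%dT%H:%M:%S"),
    minutes = intervals$minutes
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = "cccd", progress = FALSE)
  don <- parse_iso_ts(raw$don)
  doff <- parse_iso_ts(raw$doff)
  bad <- which(is.na(don) | is.na(doff))
  if (length(bad) > 0) {
    stop("malformed interval row(s) at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  }
  tibble::tibble(participant_id = raw$participant_id,
                 don = don, doff = doff, minutes = raw$minutes)
}

#' Write the ground-truth bundle as JSON
#'
#' @param truth The `truth` element of a [simulate_cohort()] bundle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    intervals = data.frame(
      participant_id = truth$intervals$participant_id,
      don = format(truth$intervals$don, "%Y-%m-%dT%H:%M:%S"),
      doff = format(truth$intervals$doff, "%Y-%m-%dT%H:%M:%S"),
      minutes = truth$intervals$minutes
    ),
    daily = data.frame(
      participant_id = truth$daily$participant_id,
      date = format(truth$daily$date),
      minutes = truth$daily$minutes
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full simulate-detect-aggregate-agree-sensitivity pipeline
#'
#' Simulates a cohort (or uses supplied sensor/self-report tibbles), detects
#' wear, aggregates to daily series, computes agreement at the requested
#' levels, runs the missing-data sensitivity suite, and writes all artifacts
#' plus a reproducibility manifest to `out_dir`. Deterministic for a fixed
#' configuration.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()]; ignored when `sensor` and `selfreport` are
#'   supplied.
#' @param detect A [detect_config()].
#' @param levels Aggregation levels for the agreement analysis.
#' @param n_boot Bootstrap resamples for repeated-level CIs.
#' @param sensor,selfreport Optional pre-loaded data (tibbles as from
#'   [read_sensor_csv()] / [read_selfreport_csv()]); when supplied the
#'   simulation stage is skipped and `window_start`/`window_end` must be
#'   given.
#' @param window_start,window_end Observation window when data are supplied.
#' @return Invisibly, a list with `intervals`, `sensor_daily`,
#'   `selfreport_daily`, `summaries`, `agreement`, `sensitivity`,
#'   `manifest`.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(),
                         detect = detect_config(), levels = WEAR_LEVELS,
                         n_boot = 2000, sensor = NULL, selfreport = NULL,
                         window_start = NULL, window_end = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  simulated <- is.null(sensor)
  if (simulated) {
    cohort <- stage("simulate", simulate_cohort(sim))
    sensor <- cohort$sensor
    selfreport <- cohort$selfreport
    window_start <- sim$start_date
    window_end <- sim$start_date + sim$n_days - 1
    stage("simulate", {
      write_sensor_csv(sensor, file.path(out_dir, "sensor.csv"))
      write_selfreport_csv(selfreport, file.path(out_dir, "selfreport.csv"))
      write_truth_json(cohort$truth, file.path(out_dir, "truth.json"))
    })
  } else if (is.null(window_start) || is.null(window_end)) {
    stop("pipeline stage [input] failed: supply window_start/window_end ",
         "with external data", call. = FALSE)
  }

  intervals <- stage("detect", detect_wear(sensor, detect))
  stage("detect",
        write_intervals_csv(intervals, file.path(out_dir, "intervals.csv")))

  sensor_daily <- stage("aggregate",
                        daily_zero_fill(intervals,
                                        unique(sensor$participant_id),
                                        window_start, window_end))
  selfreport_cal <- stage("aggregate",
                          selfreport_daily(selfreport, window_start,
                                           window_end))
  summaries <- stage("aggregate", {
    s <- summarize_wear(sensor_daily)
    r <- summarize_wear(selfreport_cal)
    s$source <- "sensor"
    r$source <- "selfreport"
    dplyr::bind_rows(s, r)
  })
  stage("aggregate", {
    readr::write_csv(sensor_daily, file.path(out_dir, "daily_sensor.csv"),
                     progress = FALSE)
    readr::write_csv(selfreport_cal,
                     file.path(out_dir, "daily_selfreport.csv"),
                     progress = FALSE)
    readr::write_csv(summaries, file.path(out_dir, "summary.csv"),
                     progress = FALSE)
  })

  agreement <- stage("agree",
                     agreement_table(sensor_daily, selfreport_cal,
                                     levels = levels, n_boot = n_boot,
                                     seed = sim$seed))
  stage("agree", {
    readr::write_csv(agreement, file.path(out_dir, "agreement.csv"),
                     progress = FALSE)
    jsonlite::write_json(agreement, file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  sens <- stage("sensitivity",
                sensitivity_suite(sensor_daily, selfreport_cal,
                                  levels = levels, n_boot = n_boot,
                                  seed = sim$seed))
  stage("sensitivity", {
    jsonlite::write_json(
      list(excluded_ids = sens$excluded_ids,
           scenarios = lapply(sens$scenarios, as.data.frame),
           deltas = as.data.frame(sens$deltas)),
      file.path(out_dir, "sensitivity.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  })

  manifest <- stage("manifest", {
    m <- list(
      package = "bracewear",
      version = as.character(utils::packageVersion("bracewear")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = if (simulated) sim$seed else NA,
      config_hash = rlang::hash(list(sim = unclass(sim),
                                     detect = unclass(detect),
                                     levels = levels, n_boot = n_boot)),
      rows = list(sensor = nrow(sensor),
                  selfreport = nrow(selfreport),
                  intervals = nrow(intervals))
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    m
  })

  invisible(list(intervals = intervals, sensor_daily = sensor_daily,
                 selfreport_daily = selfreport_cal, summaries = summaries,
                 agreement = agreement, sensitivity = sens,
                 manifest = manifest))
}
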