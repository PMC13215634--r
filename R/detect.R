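# Gradient-based wear detection: donning shows as a temperature spike toward
# skin temperature, doffing as a drop back toward ambient. Working on first
# differences (not absolute levels) makes detection insensitive to ambient
# temperature and slow diurnal drift.

#' Configuration for the donning/doffing detector
#'
#' @param theta_on Cumulative rise in degC (over at most `confirm_samples`
#'   consecutive positive differences) that triggers a donning event. The
#'   default 1.5 sits well below the noise-free first warming step of typical
#'   skin/ambient physics (~4.9 degC for a 10 degC contrast with a 15-min
#'   time constant at 10-min sampling) and far above quantized sensor noise.
#' @param theta_off Cumulative fall in degC triggering a doffing event.
#' @param confirm_samples Maximum number of consecutive same-sign differences
#'   over which the cumulative change may accrue.
#' @param min_bout Minimum bout duration in minutes; shorter detected bouts
#'   are dropped.
#' @param merge_gap Bouts separated by no more than this many minutes are
#'   merged.
#' @param plateau_check Optional sanity check: cancel a donning event unless
#'   the temperature holds at least `plateau_delta` degC above the pre-don
#'   level for at least `plateau_samples` consecutive samples within the next
#'   `plateau_window` samples. Helps reject brief thermal transients; it
#'   cannot reject sustained ambient steps comparable to skin contact.
#' @param plateau_delta,plateau_samples,plateau_window Plateau-check
#'   parameters (degC, samples, samples).
#' @return A validated list of class `"detect_config"`.
#' @export
detect_config <- function(theta_on = 1.5, theta_off = 1.5,
                          confirm_samples = 2, min_bout = 10, merge_gap = 10,
                          plateau_check = FALSE, plateau_delta = 3,
                          plateau_samples = 2, plateau_window = 6) {
  stopifnot(theta_on > 0, theta_off > 0, confirm_samples >= 1,
            min_bout >= 0, merge_gap >= 0,
            plateau_delta > 0, plateau_samples >= 1,
            plateau_window >= plateau_samples)
  structure(
    list(theta_on = theta_on, theta_off = theta_off,
         confirm_samples = as.integer(confirm_samples),
         min_bout = min_bout, merge_gap = merge_gap,
         plateau_check = isTRUE(plateau_check),
         plateau_delta = plateau_delta,
         plateau_samples = as.integer(plateau_samples),
         plateau_window = as.integer(plateau_window)),
    class = "detect_config"
  )
}

#' First difference of a temperature series
#'
#' @param temps Numeric temperature vector, or a tibble with a `temp_c`
#'   column.
#' @return Numeric vector of per-sample changes (degC per sample), length
#'   one less than the input.
#' @export
first_difference <- function(temps) {
  if (is.data.frame(temps)) temps <- temps$temp_c
  if (length(temps) < 2) {
    stop("temperature series must have at least 2 samples")
  }
  diff(temps)
}

# Marks indices i (in the difference vector) where a run of <= confirm
# consecutive same-direction differences starting at i accumulates to the
# threshold. `d` is the (possibly sign-flipped) difference vector.
run_trigger <- function(d, theta, confirm) {
  nd <- length(d)
  pos <- d > 0
  s <- d
  allpos <- pos
  hit <- allpos & s >= theta
  k <- 2
  while (k <= confirm && k <= nd) {
    m <- nd - k + 1
    s <- s[seq_len(m)] + d[k:nd]
    allpos <- allpos[seq_len(m)] & pos[k:nd]
    hit[seq_len(m)] <- hit[seq_len(m)] | (allpos & s >= theta)
    k <- k + 1
  }
  which(hit)
}

#' Detect candidate donning and doffing events
#'
#' A donning (DON) event is emitted at the first sample of any run of at most
#' `confirm_samples` consecutive positive differences whose cumulative sum
#' reaches `theta_on`; a doffing (DOFF) event analogously for falls reaching
#' `theta_off`. Zero differences never trigger. Events are candidates only;
#' [pair_events()] applies the alternating state machine.
#'
#' @param series Tibble with `timestamp` and `temp_c` for one participant
#'   (one contiguous segment).
#' @param config A [detect_config()].
#' @return Tibble with `time` (POSIXct) and `type` (`"don"`/`"doff"`),
#'   time-ordered.
#' @export
detect_events <- function(series, config = detect_config()) {
  stopifnot(inherits(config, "detect_config"),
            all(c("timestamp", "temp_c") %in% names(series)))
  temps <- series$temp_c
  d <- first_difference(temps)

  don_i <- run_trigger(d, config$theta_on, config$confirm_samples)
  doff_i <- run_trigger(-d, config$theta_off, config$confirm_samples)

  if (config$plateau_check && length(don_i) > 0) {
    n <- length(temps)
    ok <- vapply(don_i, function(i) {
      win <- seq(i + 1, min(n, i + config$plateau_window))
      above <- temps[win] >= temps[i] + config$plateau_delta
      r <- rle(above)
      any(r$values & r$lengths >= config$plateau_samples)
    }, logical(1))
    # a cancelled donning transient takes its own falling edge with it,
    # otherwise the record-start boundary rule would turn the orphaned DOFF
    # into a phantom bout
    for (i in don_i[!ok]) {
      doff_i <- doff_i[!(doff_i > i & doff_i <= i + config$plateau_window)]
    }
    don_i <- don_i[ok]
  }

  ev <- tibble::tibble(
    time = c(series$timestamp[don_i], series$timestamp[doff_i]),
    type = c(rep("don", length(don_i)), rep("doff", length(doff_i)))
  )
  ev[order(ev$time), ]
}

#' Pair donning/doffing events into wear bouts
#'
#' State machine starting in NOT-WORN: a DON opens a bout and the next DOFF
#' closes it; a DON while worn and a DOFF while not worn are ignored, except
#' that a DOFF as the very first event of the record closes a bout assumed
#' open at the record start. A bout still open at the record end closes at
#' the last timestamp. Bouts shorter than `min_bout` are then dropped, and
#' bouts separated by at most `merge_gap` minutes merged.
#'
#' @param events Tibble with `time`, `type` as from [detect_events()],
#'   time-ordered.
#' @param record_start,record_end POSIXct bounds of the record (segment).
#' @param config A [detect_config()].
#' @return Tibble of wear intervals: `don`, `doff`, `minutes`.
#' @export
pair_events <- function(events, record_start, record_end,
                        config = detect_config()) {
  stopifnot(inherits(config, "detect_config"))
  don <- list()
  doff <- list()
  worn <- FALSE
  open_at <- NULL
  first <- TRUE
  for (j in seq_len(nrow(events))) {
    tm <- events$time[j]
    ty <- events$type[j]
    if (ty == "don") {
      if (!worn) {
        open_at <- tm
        worn <- TRUE
      }
    } else {
      if (worn) {
        don[[length(don) + 1]] <- open_at
        doff[[length(doff) + 1]] <- tm
        worn <- FALSE
      } else if (first) {
        don[[length(don) + 1]] <- record_start
        doff[[length(doff) + 1]] <- tm
      }
    }
    first <- FALSE
  }
  if (worn) {
    don[[length(don) + 1]] <- open_at
    doff[[length(doff) + 1]] <- record_end
  }
  if (length(don) == 0) {
    return(tibble::tibble(
      don = as.POSIXct(character(), tz = wear_tz()),
      doff = as.POSIXct(character(), tz = wear_tz()),
      minutes = numeric()
    ))
  }
  don <- do.call(c, don)
  doff <- do.call(c, doff)
  minutes <- as_minutes(doff, don)

  keep <- minutes >= config$min_bout
  don <- don[keep]
  doff <- doff[keep]
  if (length(don) > 1) {
    merged_don <- don[1]
    merged_doff <- doff[1]
    for (j in 2:length(don)) {
      gap <- as_minutes(don[j], merged_doff[length(merged_doff)])
      if (gap <= config$merge_gap) {
        merged_doff[length(merged_doff)] <- doff[j]
      } else {
        merged_don <- c(merged_don, don[j])
        merged_doff <- c(merged_doff, doff[j])
      }
    }
    don <- merged_don
    doff <- merged_doff
  }
  tibble::tibble(don = don, doff = doff, minutes = as_minutes(doff, don))
}

#' Detect wear intervals from a temperature series
#'
#' Composition of [first_difference()], [detect_events()] and
#' [pair_events()]. Series with sampling gaps larger than twice the sampling
#' interval are split at the gaps and detection runs per contiguous segment,
#' avoiding spurious gradients across logger outages. Accepts a multi-
#' participant tibble (`participant_id` column), in which case detection runs
#' per participant.
#'
#' @param sensor Tibble with `timestamp`, `temp_c` and optionally
#'   `participant_id`.
#' @param config A [detect_config()].
#' @return Tibble of wear intervals (`participant_id` if present, `don`,
#'   `doff`, `minutes`), sorted and non-overlapping.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 1, n_days = 2,
#'                                      sensor_noise_sd = 0, seed = 3))
#' detect_wear(cohort$sensor)
detect_wear <- function(sensor, config = detect_config()) {
  stopifnot(inherits(config, "detect_config"))
  if ("participant_id" %in% names(sensor)) {
    parts <- split(sensor, sensor$participant_id)
    out <- lapply(names(parts), function(pid) {
      iv <- detect_wear_one(parts[[pid]], config)
      if (nrow(iv) > 0) iv$participant_id <- pid
      iv
    })
    res <- dplyr::bind_rows(out)
    if (nrow(res) == 0) {
      return(tibble::tibble(participant_id = character(),
                            don = as.POSIXct(character(), tz = wear_tz()),
                            doff = as.POSIXct(character(), tz = wear_tz()),
                            minutes = numeric()))
    }
    return(dplyr::select(res, "participant_id", "don", "doff", "minutes"))
  }
  detect_wear_one(sensor, config)
}

#' Detected daily wear minutes
#'
#' Runs [detect_wear()] and attributes the detected intervals to calendar
#' days via [daily_minutes()]. Participants whose trace yields no bouts
#' still contribute observed zero days (a sensor zero is a measurement, not
#' missing data).
#'
#' @param sensor Tibble with `participant_id`, `timestamp`, `temp_c`.
#' @param window_start,window_end Observation window (Date).
#' @param config A [detect_config()].
#' @return Tibble `participant_id`, `date`, `minutes`, calendar-complete.
#' @export
detect_daily_minutes <- function(sensor, window_start, window_end,
                                 config = detect_config()) {
  if (!"participant_id" %in% names(sensor)) {
    sensor <- dplyr::mutate(sensor, participant_id = "P01")
  }
  iv <- detect_wear(sensor, config)
  daily_zero_fill(iv, unique(sensor$participant_id), window_start,
                  window_end)
}

# Daily minutes for all listed participants, zero-filling those with no
# detected intervals.
daily_zero_fill <- function(intervals, pids, window_start, window_end) {
  d <- if (nrow(intervals) > 0) {
    daily_minutes(intervals, window_start, window_end)
  } else {
    NULL
  }
  missing_pids <- setdiff(pids, unique(d$participant_id))
  if (length(missing_pids) > 0) {
    zeros <- lapply(missing_pids, function(pid) {
      tibble::tibble(participant_id = pid,
                     date = seq(as.Date(window_start), as.Date(window_end),
                                by = "day"),
                     minutes = 0)
    })
    d <- dplyr::bind_rows(d, dplyr::bind_rows(zeros))
  }
  d[order(d$participant_id, d$date), ]
}

detect_wear_one <- function(series, config) {
  stopifnot(all(c("timestamp", "temp_c") %in% names(series)))
  if (nrow(series) < 2) stop("temperature series must have at least 2 samples")
  ts <- series$timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  step <- diff(as.numeric(ts)) / 60
  interval <- median(step)
  seg_id <- cumsum(c(0, step > 2 * interval))
  segs <- split(seq_len(nrow(series)), seg_id)
  out <- lapply(segs, function(idx) {
    if (length(idx) < 2) return(NULL)
    seg <- series[idx, ]
    ev <- detect_events(seg, config)
    pair_events(ev, seg$timestamp[1], seg$timestamp[nrow(seg)], config)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(don = as.POSIXct(character(), tz = wear_tz()),
                          doff = as.POSIXct(character(), tz = wear_tz()),
                          minutes = numeric()))
  }
  res
}
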