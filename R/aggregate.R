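# Calendar-day aggregation: intervals -> daily minutes -> rolling averages
# and per-participant summaries (the five outcome measures: daily wear,
# 3- and 7-day rolling averages, cumulative total, average daily wear, and
# days worn).

#' Attribute wear intervals to calendar days
#'
#' Each interval's minutes are attributed to calendar days by overlap with
#' the local-day window `[00:00, 24:00)`; an interval crossing midnight is
#' split. Days in the window with no overlapping wear get 0 minutes (an
#' observed zero, never missing).
#'
#' @param intervals Tibble of wear intervals (`don`, `doff`, optionally
#'   `participant_id`), sorted and non-overlapping per participant.
#' @param window_start,window_end First and last calendar day (Date) of the
#'   observation window.
#' @return Tibble with `participant_id` (if supplied), `date`, `minutes`:
#'   one row per day in the window.
#' @export
#' @examples
#' iv <- tibble::tibble(
#'   don = as.POSIXct("2024-01-01 10:00", tz = "UTC"),
#'   doff = as.POSIXct("2024-01-01 11:10", tz = "UTC")
#' )
#' daily_minutes(iv, as.Date("2024-01-01"), as.Date("2024-01-03"))
daily_minutes <- function(intervals, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  stopifnot(window_end >= window_start)
  if ("participant_id" %in% names(intervals)) {
    parts <- split(intervals, intervals$participant_id)
    out <- lapply(names(parts), function(pid) {
      d <- daily_minutes_one(parts[[pid]], window_start, window_end)
      tibble::tibble(participant_id = pid, date = d$date, minutes = d$minutes)
    })
    return(dplyr::bind_rows(out))
  }
  daily_minutes_one(intervals, window_start, window_end)
}

daily_minutes_one <- function(intervals, window_start, window_end) {
  days <- seq(window_start, window_end, by = "day")
  mins <- numeric(length(days))
  w0 <- as.numeric(day_start(window_start))
  w1 <- as.numeric(day_start(window_end + 1))
  for (j in seq_len(nrow(intervals))) {
    don <- as.numeric(intervals$don[j])
    doff <- as.numeric(intervals$doff[j])
    if (doff <= don) stop("interval ", format(intervals$don[j]),
                          " has non-positive duration")
    if (don < w0 || doff > w1) {
      stop("interval starting ", format(intervals$don[j]),
           " lies outside the window ", window_start, "..", window_end)
    }
    d_idx <- floor((don - w0) / 86400) + 1
    d_last <- floor((doff - 1 - w0) / 86400) + 1
    for (k in d_idx:d_last) {
      lo <- w0 + (k - 1) * 86400
      hi <- lo + 86400
      mins[k] <- mins[k] + (min(doff, hi) - max(don, lo)) / 60
    }
  }
  tibble::tibble(date = days, minutes = mins)
}

#' Expand a self-report log to a calendar-complete daily series
#'
#' Days inside the window with no log entry become missing (`NA`), which is
#' distinct from an observed zero ("no wear reported").
#'
#' @param log Tibble with `date`, `minutes` and optionally `participant_id`.
#' @param window_start,window_end Window bounds (Date).
#' @return Tibble with one row per participant-day in the window; `minutes`
#'   is `NA` where the log entry is absent.
#' @export
selfreport_daily <- function(log, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  days <- seq(window_start, window_end, by = "day")
  one <- function(df) {
    if (anyDuplicated(df$date)) {
      stop("duplicate log dates: ", paste(df$date[duplicated(df$date)],
                                          collapse = ", "))
    }
    m <- df$minutes[match(days, df$date)]
    tibble::tibble(date = days, minutes = m)
  }
  if ("participant_id" %in% names(log)) {
    parts <- split(log, log$participant_id)
    out <- lapply(names(parts), function(pid) {
      d <- one(parts[[pid]])
      tibble::tibble(participant_id = pid, date = d$date, minutes = d$minutes)
    })
    return(dplyr::bind_rows(out))
  }
  one(log)
}

#' Trailing rolling average of daily wear minutes
#'
#' Trailing mean over `window_days` consecutive calendar days, labelled by
#' the window's last day. A value is emitted only where every day of the
#' window is present, calendar-contiguous and non-missing.
#'
#' @param daily Tibble with `date`, `minutes` (NA = missing) and optionally
#'   `participant_id`.
#' @param window_days Window length in days (3 and 7 are the standard
#'   choices).
#' @return Tibble with `participant_id` (if supplied), `date`, `minutes`
#'   (the rolling mean), containing only complete windows.
#' @export
rolling_average <- function(daily, window_days) {
  stopifnot(window_days >= 1)
  one <- function(df) {
    df <- df[order(df$date), ]
    days <- seq(min(df$date), max(df$date), by = "day")
    x <- df$minutes[match(days, df$date)]  # calendar gaps become NA
    if (window_days == 1) {
      rolled <- x
    } else {
      rolled <- as.numeric(stats::filter(x, rep(1 / window_days, window_days),
                                         sides = 1))
    }
    keep <- !is.na(rolled)
    tibble::tibble(date = days[keep], minutes = rolled[keep])
  }
  if ("participant_id" %in% names(daily)) {
    parts <- split(daily, daily$participant_id)
    out <- lapply(names(parts), function(pid) {
      d <- one(parts[[pid]])
      if (nrow(d) == 0) return(NULL)
      tibble::tibble(participant_id = pid, date = d$date, minutes = d$minutes)
    })
    return(dplyr::bind_rows(out))
  }
  one(daily)
}

#' Summarize a daily wear series into the aggregated outcome measures
#'
#' Missing days are excluded from every summary: the total is the sum of
#' observed minutes, the average divides by the number of observed days, and
#' days worn counts observed days with non-zero wear.
#'
#' @param daily Tibble with `date`, `minutes` (NA = missing) and optionally
#'   `participant_id`.
#' @return Tibble with one row per participant: `total_minutes`,
#'   `days_observed`, `avg_daily_minutes`, `days_worn`.
#' @export
summarize_wear <- function(daily) {
  one <- function(df, label) {
    obs <- df$minutes[!is.na(df$minutes)]
    if (length(obs) == 0) {
      stop("all days missing for participant ", label)
    }
    tibble::tibble(
      total_minutes = sum(obs),
      days_observed = length(obs),
      avg_daily_minutes = sum(obs) / length(obs),
      days_worn = sum(obs > 0)
    )
  }
  if ("participant_id" %in% names(daily)) {
    parts <- split(daily, daily$participant_id)
    out <- lapply(names(parts), function(pid) {
      s <- one(parts[[pid]], pid)
      tibble::tibble(participant_id = pid, s)
    })
    return(dplyr::bind_rows(out))
  }
  one(daily, "<single>")
}
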