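# Agreement between sensor-measured and self-reported wear: Lin's
# concordance correlation coefficient (CCC) and Bland-Altman 95% limits of
# agreement (LoA), with repeated-measures-aware confidence intervals.
# Difference orientation is selfreport - sensor throughout, so over-reporting
# shows as positive bias.

WEAR_LEVELS <- c("daily", "rolling3", "rolling7", "total", "avg_daily",
                 "days_worn")
REPEATED_LEVELS <- c("daily", "rolling3", "rolling7")

#' Lin's concordance correlation coefficient
#'
#' Moment estimator with population (divisor-n) variances:
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`. Measures how far
#' pairs fall from the identity line, penalizing both poor correlation and
#' location/scale shift.
#'
#' @param x,y Numeric vectors of equal length (>= 2) of paired measurements.
#' @return CCC in `[-1, 1]`.
#' @export
#' @examples
#' lin_ccc(c(1, 2, 3, 4), c(2, 3, 4, 5))
lin_ccc <- function(x, y) {
  n <- length(x)
  if (n < 2 || length(y) != n) {
    stop("x and y must have equal length >= 2")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite and free of missing values")
  }
  mx <- mean(x)
  my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) {
    stop("CCC undefined: both inputs are constant")
  }
  2 * mean((x - mx) * (y - my)) / (vx + vy + (mx - my)^2)
}

#' Fisher z-transform confidence interval for a CCC
#'
#' `tanh(atanh(ccc) +/- z * / sqrt(n_effective - 2))`. Used for aggregated
#' (one value per participant) levels where rows are independent.
#'
#' @param ccc Point estimate in `(-1, 1)`; a degenerate `|ccc| = 1` returns a
#'   point interval with a warning.
#' @param n_effective Number of independent pairs (>= 3).
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
ccc_ci <- function(ccc, n_effective, conf = 0.95) {
  stopifnot(n_effective >= 3, ccc >= -1, ccc <= 1)
  if (abs(ccc) == 1) {
    warning("CCC is exactly ", ccc, "; returning a degenerate point interval")
    return(c(ccc, ccc))
  }
  z <- atanh(ccc)
  se <- 1 / sqrt(n_effective - 2)
  crit <- qnorm(1 - (1 - conf) / 2)
  tanh(c(z - crit * se, z + crit * se))
}

#' Cluster bootstrap confidence interval over participants
#'
#' Resamples participants with replacement, keeping each participant's rows
#' intact, and recomputes the statistic on every resample; the interval is
#' the percentile 2.5/97.5 range. This respects the repeated-measures
#' structure of daily panels (days within a participant are not independent).
#'
#' @param panel Tibble with `participant_id`, `sensor`, `selfreport` columns.
#' @param statistic Function of a panel returning a scalar; default is the
#'   CCC of `sensor` vs `selfreport`.
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed RNG seed.
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
cluster_bootstrap_ci <- function(panel, statistic = NULL, n_boot = 2000,
                                 seed = 1, conf = 0.95) {
  if (is.null(statistic)) {
    statistic <- function(df) lin_ccc(df$sensor, df$selfreport)
  }
  ids <- unique(panel$participant_id)
  if (length(ids) < 2) {
    stop("cluster bootstrap needs >= 2 participants")
  }
  if (n_boot < 200) stop("n_boot must be >= 200")
  idx_by_id <- split(seq_len(nrow(panel)), panel$participant_id)[ids]
  withr::local_seed(seed)
  draws <- matrix(sample.int(length(ids), length(ids) * n_boot,
                             replace = TRUE), nrow = n_boot)
  stats <- vapply(seq_len(n_boot), function(b) {
    rows <- unlist(idx_by_id[draws[b, ]], use.names = FALSE)
    tryCatch(statistic(panel[rows, ]), error = function(e) NA_real_)
  }, numeric(1))
  if (mean(is.na(stats)) > 0.2) {
    stop("statistic undefined on more than 20% of bootstrap resamples")
  }
  alpha <- (1 - conf) / 2
  unname(quantile(stats, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' `bias = mean(diffs)`, `LoA = bias +/- 1.96 * SD(diffs)` with the sample
#' (divisor n-1) standard deviation.
#'
#' @param diffs Numeric vector of paired differences (length >= 2).
#' @return Named numeric `c(bias, lower, upper)`.
#' @export
bland_altman_loa <- function(diffs) {
  if (length(diffs) < 2) stop("need at least 2 differences")
  b <- mean(diffs)
  s <- sd(diffs)
  c(bias = b, lower = b - 1.96 * s, upper = b + 1.96 * s)
}

# Bland-Altman SD corrected for multiple observations per individual: the
# total variance of differences is rebuilt from one-way ANOVA components so
# the between-subject component is not diluted by unequal replication.
loa_sd_rm <- function(diffs, subject) {
  subject <- factor(subject)
  if (nlevels(subject) < 2) return(sd(diffs))
  a <- anova(aov(diffs ~ subject))
  msb <- a$`Mean Sq`[1]
  msw <- a$`Mean Sq`[2]
  ni <- as.numeric(table(subject))
  n_total <- sum(ni)
  n0 <- (n_total - sum(ni^2) / n_total) / (nlevels(subject) - 1)
  sigma_b2 <- max(0, (msb - msw) / n0)
  sqrt(sigma_b2 + msw)
}

# Variance-components CCC (subject random intercept + shared subject:day
# effect, fixed method shift): concordant variance over concordant plus
# discordant variance plus squared method shift.
vc_ccc <- function(panel) {
  long <- tibble::tibble(
    subject = rep(panel$participant_id, 2),
    item = rep(as.character(panel$label), 2),
    method = rep(c("sensor", "selfreport"), each = nrow(panel)),
    value = c(panel$sensor, panel$selfreport)
  )
  fit <- lme4::lmer(
    value ~ method + (1 | subject) + (1 | subject:item),
    data = long,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_subj <- sum(vc$vcov[vc$grp %in% c("subject", "subject:item")])
  v_err <- vc$vcov[vc$grp == "Residual"]
  delta <- lme4::fixef(fit)[2]
  unname((v_subj) / (v_subj + v_err + delta^2))
}

#' Qualitative agreement band for a CCC
#'
#' poor `< 0.5`; moderate `[0.5, 0.75]`; strong `(0.75, 0.9]`; excellent
#' `> 0.9`. Both 0.5 and 0.75 belong to "moderate"; 0.9 to "strong".
#'
#' @param ccc CCC value in `[-1, 1]`.
#' @return One of `"poor"`, `"moderate"`, `"strong"`, `"excellent"`.
#' @export
ccc_band <- function(ccc) {
  if (!is.finite(ccc) || ccc < -1 || ccc > 1) {
    stop("ccc must lie in [-1, 1]")
  }
  if (ccc < 0.5) "poor"
  else if (ccc <= 0.75) "moderate"
  else if (ccc <= 0.9) "strong"
  else "excellent"
}

#' Build the aligned sensor/self-report panel for an aggregation level
#'
#' For repeated levels, pairs are per participant-day (rolling averages are
#' computed per source first); a participant-day enters only if both the
#' sensor day is observed and a log entry exists. For aggregated levels
#' (`total`, `avg_daily`, `days_worn`) there is one pair per participant,
#' each source summarized over its own observed days.
#'
#' @param sensor_daily Calendar-complete daily sensor series
#'   (`participant_id`, `date`, `minutes`).
#' @param selfreport_daily Calendar-complete daily self-report series with
#'   `NA` for missing log entries.
#' @param level One of `"daily"`, `"rolling3"`, `"rolling7"`, `"total"`,
#'   `"avg_daily"`, `"days_worn"`.
#' @return Tibble with `participant_id`, `label`, `sensor`, `selfreport`.
#' @export
align_panel <- function(sensor_daily, selfreport_daily, level) {
  level <- match.arg(level, WEAR_LEVELS)
  if (level %in% REPEATED_LEVELS) {
    s <- sensor_daily
    r <- selfreport_daily
    if (level != "daily") {
      k <- if (level == "rolling3") 3 else 7
      s <- rolling_average(s, k)
      r <- rolling_average(r, k)
    }
    panel <- dplyr::inner_join(
      dplyr::rename(s, sensor = "minutes"),
      dplyr::rename(r, selfreport = "minutes"),
      by = c("participant_id", "date")
    )
    panel <- panel[!is.na(panel$sensor) & !is.na(panel$selfreport), ]
    panel <- tibble::tibble(participant_id = panel$participant_id,
                            label = panel$date,
                            sensor = panel$sensor,
                            selfreport = panel$selfreport)
  } else {
    col <- switch(level, total = "total_minutes",
                  avg_daily = "avg_daily_minutes", days_worn = "days_worn")
    s <- summarize_wear(sensor_daily)
    r <- summarize_wear(selfreport_daily)
    joined <- dplyr::inner_join(s, r, by = "participant_id",
                                suffix = c("_sensor", "_selfreport"))
    panel <- tibble::tibble(
      participant_id = joined$participant_id,
      label = "all",
      sensor = joined[[paste0(col, "_sensor")]],
      selfreport = joined[[paste0(col, "_selfreport")]]
    )
  }
  if (nrow(panel) == 0) {
    stop("no overlapping observed pairs at level '", level,
         "' (participants: ",
         paste(unique(sensor_daily$participant_id), collapse = ", "), ")")
  }
  panel
}

#' Agreement estimate at one aggregation level
#'
#' Builds the aligned panel, computes the CCC (pooled Lin's moment estimator
#' by default; a variance-components subject random-intercept estimator via
#' `estimator = "vc"` for repeated levels), the mean bias and Bland-Altman
#' LoA of `selfreport - sensor`, and a 95% CI: cluster bootstrap over
#' participants for repeated levels, Fisher z-transform (n = participants)
#' for aggregated levels.
#'
#' @inheritParams align_panel
#' @param n_boot Bootstrap resamples for repeated-level CIs.
#' @param seed RNG seed for the bootstrap.
#' @param ci Compute a confidence interval (set FALSE to skip, e.g. in
#'   simulation loops where only the point estimate is needed).
#' @param loa_rm_correction Use the multiple-observations-per-individual
#'   variance correction for repeated-level LoA (default FALSE: naive pooled
#'   SD of all daily differences).
#' @param estimator `"lin"` (pooled moment estimator) or `"vc"`
#'   (variance components, repeated levels only).
#' @return One-row tibble: `level`, `n_pairs`, `n_participants`, `ccc`,
#'   `ccc_lo`, `ccc_hi`, `bias`, `loa_lo`, `loa_hi`, `band`, `estimator`,
#'   `ci_method`, `orientation`.
#' @export
agreement_at_level <- function(sensor_daily, selfreport_daily, level,
                               n_boot = 2000, seed = 1, ci = TRUE,
                               loa_rm_correction = FALSE,
                               estimator = c("lin", "vc")) {
  estimator <- match.arg(estimator)
  level <- match.arg(level, WEAR_LEVELS)
  panel <- align_panel(sensor_daily, selfreport_daily, level)
  repeated <- level %in% REPEATED_LEVELS
  n_part <- length(unique(panel$participant_id))

  use_vc <- estimator == "vc" && repeated
  ccc <- if (use_vc) vc_ccc(panel) else lin_ccc(panel$sensor, panel$selfreport)

  diffs <- panel$selfreport - panel$sensor
  if (loa_rm_correction && repeated) {
    b <- mean(diffs)
    s <- loa_sd_rm(diffs, panel$participant_id)
    loa <- c(bias = b, lower = b - 1.96 * s, upper = b + 1.96 * s)
    loa_method <- "rm_corrected"
  } else {
    loa <- bland_altman_loa(diffs)
    loa_method <- "pooled_sd"
  }

  if (!ci) {
    ci_bounds <- c(NA_real_, NA_real_)
    ci_method <- "none"
  } else if (repeated) {
    stat <- if (use_vc) {
      function(df) vc_ccc(df)
    } else {
      function(df) lin_ccc(df$sensor, df$selfreport)
    }
    ci_bounds <- cluster_bootstrap_ci(panel, stat, n_boot = n_boot,
                                      seed = seed)
    ci_method <- "cluster_bootstrap"
  } else {
    ci_bounds <- ccc_ci(ccc, n_part)
    ci_method <- "fisher_z"
  }

  tibble::tibble(
    level = level,
    n_pairs = nrow(panel),
    n_participants = n_part,
    ccc = ccc,
    ccc_lo = ci_bounds[1],
    ccc_hi = ci_bounds[2],
    bias = unname(loa["bias"]),
    loa_lo = unname(loa["lower"]),
    loa_hi = unname(loa["upper"]),
    band = ccc_band(ccc),
    estimator = if (use_vc) "vc" else "lin_pooled",
    ci_method = ci_method,
    loa_method = loa_method,
    orientation = "selfreport-sensor"
  )
}

#' Agreement estimates across aggregation levels
#'
#' @inheritParams agreement_at_level
#' @param levels Character vector of levels to evaluate (default all six).
#' @return Tibble with one row per level (see [agreement_at_level()]).
#' @export
agreement_table <- function(sensor_daily, selfreport_daily,
                            levels = WEAR_LEVELS, ...) {
  dplyr::bind_rows(lapply(levels, function(lv) {
    agreement_at_level(sensor_daily, selfreport_daily, lv, ...)
  }))
}
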