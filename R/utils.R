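# Internal helpers shared across modules.

# Deterministic per-participant, per-purpose RNG substream seed derived from a
# master seed. Keeps participant draws independent of cohort size and keeps the
# derived seed inside the 32-bit integer range set.seed() accepts.
substream_seed <- function(master_seed, participant_index, stream) {
  s <- (as.double(master_seed) %% 2147483647) * 48271 +
    as.double(participant_index) * 30269 +
    as.double(stream) * 7919
  as.integer(s %% 2147483646) + 1L
}

# round() uses banker's rounding; self-report and quantization use
# round-half-away-from-zero, which is deterministic and matches how people
# round in logs.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Quantize to the nearest multiple of `q` (half away from zero). The result
# is normalized to its decimal representation so that formatted output
# (e.g. one-decimal CSV) parses back to the identical double.
quantize <- function(x, q) {
  stopifnot(q > 0)
  round(q * round_half_away(x / q), 9)
}

# Lenient ISO-8601 timestamp parser ("T" or space separator); returns NA for
# malformed entries instead of erroring.
parse_iso_ts <- function(x) {
  p1 <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = wear_tz()))
  p2 <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = wear_tz()))
  p1[is.na(p1)] <- p2[is.na(p1)]
  p1
}

# Truncated-at-left normal draws; degenerates gracefully when sd == 0.
rtnorm_min <- function(n, mean, sd, lower) {
  if (sd <= 0) {
    return(rep(max(mean, lower), n))
  }
  p_lo <- pnorm(lower, mean, sd)
  p_lo <- min(p_lo, 1 - 1e-12)
  u <- runif(n, p_lo, 1)
  pmax(qnorm(u, mean, sd), lower)
}

# All timestamps in the package are naive local time carried as UTC POSIXct
# (single-site study; no DST arithmetic wanted).
wear_tz <- function() "UTC"

day_start <- function(date) {
  as.POSIXct(paste0(format(date), " 00:00:00"), tz = wear_tz())
}

as_minutes <- function(t1, t0) {
  as.numeric(t1, units = "secs") / 60 - as.numeric(t0, units = "secs") / 60
}

`%||%` <- function(x, y) if (is.null(x)) y else x
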