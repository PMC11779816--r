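# Fixture builders shared across test files. Everything is generated in
# code; no data files.

T0 <- as.POSIXct("2024-01-01 07:00:00", tz = "UTC")

# Activity tibble from a numeric vector (NA = missing bin).
make_activity <- function(values, bin_seconds = 60, start = T0,
                          id = "a1", ...) {
  tibble::tibble(
    animal_id = id,
    time = start + (seq_along(values) - 1) * bin_seconds,
    ali = as.numeric(values),
    ...
  )
}

# Square-wave nocturnal trace: `low` during light (first 12 h of each
# day), `high` during dark, minute bins, starting at lights-on.
make_square_day <- function(days, low = 0, high = 10, bin_seconds = 60,
                            start = T0, onset_h = 12) {
  per_day <- 86400 / bin_seconds
  hour <- (seq_len(per_day) - 1) * bin_seconds / 3600
  day <- ifelse(hour >= onset_h, high, low)
  make_activity(rep(day, days), bin_seconds = bin_seconds, start = start)
}

# A 12:12 schedule aligned with make_square_day.
make_ld_schedule <- function(days, start = T0) {
  schedule_cycle(start, days = days)
}

# Noiseless onset series with given deviations (h) from a target onset,
# one per day starting at `first_day`.
make_onsets <- function(devs, target = 13, first_day = 1L) {
  tibble::tibble(
    animal_id = "a1",
    day = seq_along(devs) + first_day - 1L,
    onset_h = (target + devs) %% 24,
    onset_time = T0 + (seq_along(devs) + first_day - 1L) * 86400,
    contrast = 1
  )
}
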