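#' Re-bin an activity table to a coarser grid
#'
#' Each output bin is the mean of its constituent non-missing input bins;
#' an output bin is `NA` only if every constituent bin is `NA`. For
#' gap-free traces the total (sum times bin width) is conserved.
#'
#' @param activity Activity tibble (any number of animals).
#' @param new_bin_seconds Target bin width; must be an integer multiple of
#'   the current bin width.
#' @return Activity tibble on the coarser grid.
#' @export
rebin <- function(activity, new_bin_seconds) {
  activity <- check_activity(activity)
  activity |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("animal_id", "sex", "genotype")))) |>
    dplyr::group_modify(function(df, key) {
      old <- bin_seconds_of(df)
      if (is.na(old)) old <- new_bin_seconds
      if (new_bin_seconds %% old != 0) {
        abort("`new_bin_seconds` must be an integer multiple of the current bin width")
      }
      k <- new_bin_seconds / old
      grp <- (seq_len(nrow(df)) - 1L) %/% k
      df |>
        dplyr::mutate(.grp = grp) |>
        dplyr::group_by(.data$.grp) |>
        dplyr::summarise(
          time = dplyr::first(.data$time),
          ali = if (all(is.na(.data$ali))) NA_real_ else mean(.data$ali, na.rm = TRUE),
          .groups = "drop"
        ) |>
        dplyr::select(-".grp")
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("animal_id", "time", "ali")
}

#' Centered running average of an activity trace
#'
#' A centred moving mean over the non-missing values within the window,
#' with shrinking edges (edge bins average over the available part of the
#' window, avoiding the phase lag a trailing window would inject into
#' onset estimates). A bin stays `NA` only when its whole window is
#' missing, so short welfare-check gaps are bridged by their neighbours.
#'
#' @param activity Activity tibble.
#' @param window_minutes Full window width in minutes (default 30).
#' @return Smoothed activity tibble on the same grid.
#' @export
running_average <- function(activity, window_minutes = 30) {
  activity <- check_activity(activity)
  activity |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      bs <- bin_seconds_of(df)
      if (is.na(bs)) return(df)
      if (window_minutes * 60 < bs) {
        abort("`window_minutes` must be at least one bin wide")
      }
      half <- floor(window_minutes * 60 / bs / 2)
      n <- nrow(df)
      ok <- !is.na(df$ali)
      cs <- c(0, cumsum(ifelse(ok, df$ali, 0)))
      ck <- c(0, cumsum(ok))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      s <- cs[hi + 1L] - cs[lo]
      k <- ck[hi + 1L] - ck[lo]
      df$ali <- ifelse(k > 0, s / k, NA_real_)
      df
    }) |>
    dplyr::ungroup()
}

#' Zeitgeber time of wall-clock instants
#'
#' ZT0 is lights-on. For instants during constant conditions the last real
#' lights-on before the constant span is projected forward on a 24-h
#' cycle, matching the convention of plotting constant-condition days
#' against the prior light-dark cycle. Light episodes shorter than
#' `min_light_h` (e.g. a 2-h phase-shifting light pulse) are not treated
#' as lights-on events.
#'
#' @param schedule Schedule tibble.
#' @param t POSIXct vector.
#' @param anchor Optional POSIXct lights-on anchor used when the schedule
#'   contains no qualifying light episode (pure DD).
#' @param min_light_h Minimum light-episode duration (hours) to count as a
#'   daily lights-on (default 4).
#' @return Numeric vector of ZT hours in `[0, 24)`.
#' @export
zt_time <- function(schedule, t, anchor = NULL, min_light_h = 4) {
  schedule <- validate_schedule(schedule)
  dur_h <- as.numeric(difftime(schedule$end, schedule$start, units = "hours"))
  ons <- schedule$start[schedule$state == "light" & dur_h >= min_light_h]
  if (length(ons) == 0) {
    if (is.null(anchor)) {
      abort("schedule has no lights-on episode and no `anchor` was supplied")
    }
    ons <- anchor
  }
  ons <- sort(ons)
  idx <- findInterval(as.numeric(t), as.numeric(ons))
  idx[idx == 0] <- 1L # project the first lights-on backwards if needed
  hours_between(t, ons[idx]) %% 24
}

#' Day-boundary anchor for a trace
#'
#' The default day boundary is the governing lights-on at or before the
#' trace start (projected back on a 24-h grid when the trace starts before
#' the first lights-on); with no usable schedule it falls back to the
#' trace start.
#'
#' @param activity Single- or multi-animal activity tibble.
#' @param schedule Optional schedule tibble.
#' @return POSIXct scalar.
#' @export
day_anchor <- function(activity, schedule = NULL) {
  activity <- check_activity(activity)
  t0 <- min(activity$time)
  if (is.null(schedule)) return(t0)
  zt0 <- tryCatch(zt_time(schedule, t0), error = function(e) NULL)
  if (is.null(zt0)) t0 else t0 - zt0 * 3600
}

#' Split a trace into protocol days
#'
#' @param activity Activity tibble.
#' @param schedule Optional schedule used to derive the day anchor
#'   (lights-on); ignored when `anchor` is given.
#' @param day_length_hours Day length (default 24; use the free-running
#'   period for circadian-time plotting).
#' @param anchor Optional POSIXct day-boundary anchor.
#' @return Tibble with `animal_id`, `day` (integer, 0-based from the
#'   anchor), `day_time_h` (hours into the day), `time`, `ali` and a
#'   per-day `partial` flag marking days not fully covered by the trace.
#' @export
split_days <- function(activity, schedule = NULL, day_length_hours = 24,
                       anchor = NULL) {
  activity <- check_activity(activity)
  if (nrow(activity) == 0) abort("empty activity table")
  anchor <- anchor %||% day_anchor(activity, schedule)
  out <- activity |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      bs <- bin_seconds_of(df)
      h <- hours_between(df$time, anchor)
      df$day <- as.integer(floor(h / day_length_hours))
      df$day_time_h <- h - df$day * day_length_hours
      per_day <- day_length_hours * 3600 / bs
      df |>
        dplyr::group_by(.data$day) |>
        dplyr::mutate(partial = dplyr::n() < per_day) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
  dplyr::relocate(out, "animal_id", "day", "day_time_h", "time", "ali")
}

#' Mean daily activity profile
#'
#' Per-bin-of-day mean ALI over all covered days, ignoring missing bins —
#' the waveform underlying the inter-daily stability and relative
#' amplitude (M10/L5) metrics.
#'
#' @param activity Single-animal activity tibble covering at least one
#'   full day.
#' @param bins_per_day Number of profile bins (default 24 = hourly).
#' @param schedule,anchor Day-boundary convention, as in [split_days()].
#' @return Tibble with `bin` (1-based), `hour` (bin start, hours after the
#'   day anchor), `mean_ali`, and `n` (non-missing bins contributing);
#'   attributes `bins_per_day` and `n_days`.
#' @export
daily_profile <- function(activity, bins_per_day = 24, schedule = NULL,
                          anchor = NULL) {
  activity <- one_animal(activity)
  bs <- bin_seconds_of(activity)
  width_s <- 86400 / bins_per_day
  if (width_s %% bs != 0) {
    abort("trace bin width must divide the profile bin width (24 h / bins_per_day)")
  }
  anchor <- anchor %||% day_anchor(activity, schedule)
  if (nrow(activity) * bs < 86400) abort("trace covers less than one full day")
  h <- hours_between(activity$time, anchor) %% 24
  bin <- floor(h / (width_s / 3600)) + 1L
  prof <- tibble::tibble(bin = bin, ali = activity$ali) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_ali = if (all(is.na(.data$ali))) NA_real_ else mean(.data$ali, na.rm = TRUE),
      n = sum(!is.na(.data$ali)),
      .groups = "drop"
    ) |>
    dplyr::right_join(tibble::tibble(bin = seq_len(bins_per_day)), by = "bin") |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(
      hour = (.data$bin - 1) * 24 / bins_per_day,
      n = ifelse(is.na(.data$n), 0L, .data$n)
    ) |>
    dplyr::relocate("bin", "hour", "mean_ali", "n")
  attr(prof, "bins_per_day") <- bins_per_day
  attr(prof, "n_days") <- floor(nrow(activity) * bs / 86400)
  prof
}
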