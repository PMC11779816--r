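#' Read a home-cage activity export
#'
#' Reads a CSV of minute-binned (or coarser) animal locomotion index (ALI)
#' values, one row per animal and time bin, and returns a tidy activity
#' table on a complete, regular time grid. The ALI is the percentage of
#' cage-floor electrodes activated within the bin, so every value must lie
#' in \[0, 100\]; bins absent from the file (e.g. the cage out of the rack
#' for a welfare check) become explicit `NA` rows, never zeros.
#'
#' Two dialects are accepted:
#' \describe{
#'   \item{long (canonical)}{columns `timestamp, animal_id, ali` and
#'     optionally `sex`, `genotype`; this is also the dialect
#'     [write_activity_csv()] writes.}
#'   \item{wide}{a `timestamp` column plus one ALI column per animal,
#'     named by animal id. Read-only.}
#' }
#'
#' @param path Path to the CSV file.
#' @param bin_seconds Width of the time grid in seconds (default 60, the
#'   platform's minimum export bin).
#' @param tz Time zone used to parse timestamps (default `"UTC"`).
#' @return A tibble with columns `animal_id`, `time` (POSIXct), `ali`
#'   (numeric, `NA` = missing bin) and, when present in the file, `sex`
#'   and `genotype`.
#' @export
read_activity_csv <- function(path, bin_seconds = 60, tz = "UTC") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  char_cols <- intersect(c("animal_id", "sex", "genotype"), tolower(hdr))
  spec <- stats::setNames(
    rep(list(readr::col_character()), length(char_cols)),
    hdr[match(char_cols, tolower(hdr))]
  )
  raw <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = do.call(readr::cols, c(list(.default = readr::col_guess()), spec))
  )
  names(raw) <- tolower(names(raw))
  if (!"timestamp" %in% names(raw)) {
    abort("activity CSV must have a `timestamp` column")
  }
  if (!"ali" %in% names(raw) && !"animal_id" %in% names(raw)) {
    # wide dialect: every non-timestamp column is one animal
    raw <- tidyr::pivot_longer(raw, -"timestamp",
                               names_to = "animal_id", values_to = "ali")
  }
  if (!all(c("animal_id", "ali") %in% names(raw))) {
    abort("activity CSV must have `animal_id` and `ali` columns (long dialect) or one column per animal (wide dialect)")
  }
  ts <- parse_timestamp(raw$timestamp, tz)
  bad <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad) > 0) {
    abort(paste0("malformed timestamp at data row ", bad[1], ": '",
                 raw$timestamp[bad[1]], "'"))
  }
  raw$time <- ts
  out_of_range <- which(!is.na(raw$ali) & (raw$ali < 0 | raw$ali > 100))
  if (length(out_of_range) > 0) {
    abort(paste0("ALI out of [0,100] at data row ", out_of_range[1],
                 " (value ", raw$ali[out_of_range[1]], ")"))
  }
  raw$animal_id <- as.character(raw$animal_id)
  if (anyDuplicated(raw[c("animal_id", "time")]) > 0) {
    d <- raw[duplicated(raw[c("animal_id", "time")]), ]
    abort(paste0("duplicate (animal_id, timestamp) pair: ", d$animal_id[1],
                 " @ ", format(d$time[1])))
  }
  meta_cols <- intersect(c("sex", "genotype"), names(raw))
  raw |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(~ fill_grid(.x, bin_seconds, meta_cols)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$animal_id, .data$time)
}

parse_timestamp <- function(x, tz) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = tz)
  for (f in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
              "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out) & !is.na(x))
    if (length(idx) == 0) break
    p <- as.POSIXct(strptime(x[idx], f, tz = tz))
    out[idx[!is.na(p)]] <- p[!is.na(p)]
  }
  out
}

# Expand one animal's rows onto the full regular grid; gaps become NA bins.
fill_grid <- function(df, bin_seconds, meta_cols) {
  grid <- tibble::tibble(
    time = seq(min(df$time), max(df$time), by = bin_seconds)
  )
  out <- dplyr::left_join(grid, df, by = "time")
  for (mc in meta_cols) {
    val <- df[[mc]][!is.na(df[[mc]])]
    out[[mc]] <- if (length(val) > 0) val[1] else NA_character_
  }
  out[c("time", "ali", meta_cols)]
}

#' Write an activity table to CSV
#'
#' Writes the canonical long dialect (`timestamp,animal_id,ali[,sex,genotype]`).
#' Missing bins are written as rows with an empty `ali` field so that a
#' read/write round trip preserves the missing-data mask exactly.
#'
#' @param activity Activity tibble as returned by [read_activity_csv()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  activity <- check_activity(activity)
  out <- dplyr::transmute(
    activity,
    timestamp = format(.data$time, "%Y-%m-%dT%H:%M:%S"),
    animal_id = .data$animal_id,
    ali = .data$ali
  )
  for (mc in intersect(c("sex", "genotype"), names(activity))) {
    out[[mc]] <- activity[[mc]]
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Build a light-dark cycle schedule
#'
#' Expands a compact cycle description ("12:12, lights-on 07:00, for D
#' days") into explicit light/dark episodes.
#'
#' @param lights_on POSIXct instant of the first lights-on.
#' @param days Number of cycles.
#' @param light_h,dark_h Hours of light and dark per cycle (default 12:12).
#' @param lux Photopic lux during the light phase (default 100).
#' @return A schedule tibble with columns `start`, `end`, `state`
#'   (`"light"`/`"dark"`) and `lux`.
#' @export
#' @examples
#' schedule_cycle(as.POSIXct("2024-01-01 07:00", tz = "UTC"), days = 2)
schedule_cycle <- function(lights_on, days, light_h = 12, dark_h = 12, lux = 100) {
  stopifnot(days >= 1, light_h > 0, dark_h > 0)
  day_starts <- lights_on + (seq_len(days) - 1) * (light_h + dark_h) * 3600
  tibble::tibble(
    start = as.POSIXct(rep(day_starts, each = 2)) +
      rep(c(0, light_h * 3600), days),
    end = as.POSIXct(rep(day_starts, each = 2)) +
      rep(c(light_h * 3600, (light_h + dark_h) * 3600), days),
    state = rep(c("light", "dark"), days),
    lux = rep(c(lux, 0), days)
  )
}

#' Build a constant-condition schedule (DD or LL)
#'
#' @param start POSIXct start of the constant condition.
#' @param days Duration in days.
#' @param state `"dark"` (DD) or `"light"` (LL).
#' @param lux Lux while lit (ignored for dark).
#' @return A one-episode schedule tibble.
#' @export
schedule_constant <- function(start, days, state = c("dark", "light"), lux = 100) {
  state <- match.arg(state)
  tibble::tibble(
    start = start,
    end = start + days * 86400,
    state = state,
    lux = if (state == "light") lux else 0
  )
}

#' Read a lighting schedule from CSV or JSON
#'
#' The file must list episodes with fields `start`, `end`, `state`
#' (light/dark) and optionally `lux`. Episodes are validated to be
#' non-overlapping with `end > start`.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @param tz Time zone for timestamp parsing.
#' @return A validated schedule tibble (see [schedule_cycle()]).
#' @export
read_schedule <- function(path, tz = "UTC") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
  }
  names(df) <- tolower(names(df))
  if (!all(c("start", "end", "state") %in% names(df))) {
    abort("schedule file must have columns start, end, state[, lux]")
  }
  df$start <- parse_timestamp(df$start, tz)
  df$end <- parse_timestamp(df$end, tz)
  if (!"lux" %in% names(df)) df$lux <- NA_real_
  validate_schedule(df[c("start", "end", "state", "lux")])
}

#' Validate a lighting schedule
#'
#' @param schedule Schedule tibble (`start`, `end`, `state`, optional `lux`).
#' @return The schedule, sorted by start, with normalised state tokens.
#' @export
validate_schedule <- function(schedule) {
  schedule <- tibble::as_tibble(schedule)
  schedule$state <- tolower(as.character(schedule$state))
  bad_state <- setdiff(unique(schedule$state), c("light", "dark"))
  if (length(bad_state) > 0) {
    abort(paste0("unknown lighting state token: '", bad_state[1], "'"))
  }
  if (any(schedule$end <= schedule$start)) {
    abort("schedule episode with end <= start")
  }
  schedule <- dplyr::arrange(schedule, .data$start)
  if (nrow(schedule) > 1) {
    overlap <- schedule$start[-1] < schedule$end[-nrow(schedule)]
    if (any(overlap)) {
      i <- which(overlap)[1]
      abort(paste0("overlapping schedule episodes at rows ", i, " and ", i + 1))
    }
  }
  if (!"lux" %in% names(schedule)) schedule$lux <- NA_real_
  schedule
}

#' Lighting state at given instants
#'
#' @param schedule Schedule tibble.
#' @param t POSIXct vector.
#' @return Character vector `"light"`/`"dark"`; instants outside every
#'   episode are `"dark"` (unlisted spans are treated as unlit).
#' @export
light_state <- function(schedule, t) {
  schedule <- validate_schedule(schedule)
  st <- rep("dark", length(t))
  for (i in seq_len(nrow(schedule))) {
    if (schedule$state[i] == "light") {
      st[t >= schedule$start[i] & t < schedule$end[i]] <- "light"
    }
  }
  st
}

#' Write a per-animal metrics table
#'
#' One row per animal and protocol phase; undefined metrics are written as
#' empty fields. Re-reading with [readr::read_csv()] reproduces values to
#' full precision.
#'
#' @param metrics Tibble of per-animal metric rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(tibble::as_tibble(metrics), path, na = "")
  invisible(path)
}
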