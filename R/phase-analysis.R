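#' Detect daily activity onsets
#'
#' Step-template onset detector: for every day, the onset is the candidate
#' time `t` (scanned at bin resolution, windows extending into the
#' neighbouring days) maximising
#' `mean(activity in [t, t + w_act)) - mean(activity in [t - w_rest, t))`.
#' The maximal difference is reported as the onset's `contrast`; ties go
#' to the earliest candidate. The score is unchanged by time translation
#' and scales linearly with the activity, so the detected time is
#' invariant under positive rescaling. The trace should be smoothed first
#' (see [running_average()]), matching how actogram onsets are usually
#' computed.
#'
#' @param activity Single-animal (smoothed) activity tibble.
#' @param schedule,anchor Day-boundary convention, as in [split_days()].
#' @param day_length_h Day length used to index days (default 24).
#' @param w_rest_h,w_act_h Rest/active template windows in hours
#'   (default 6 and 6).
#' @return Tibble with `animal_id`, `day` (0-based from the anchor),
#'   `onset_h` (wall-clock hours after the anchor's time of day, in
#'   `[0, 24)`), `onset_time` (POSIXct) and `contrast` (>= 0 for real
#'   onsets; a zero contrast flags an unreliable, e.g. constant, day).
#'   Days with no non-missing data are skipped with a warning.
#' @export
detect_onsets <- function(activity, schedule = NULL, anchor = NULL,
                          day_length_h = 24, w_rest_h = 6, w_act_h = 6) {
  activity <- one_animal(activity)
  anchor <- anchor %||% day_anchor(activity, schedule)
  bs <- bin_seconds_of(activity)
  bin_h <- bs / 3600
  rs <- rolling_sums(activity$ali,
                     n_fwd = round(w_act_h / bin_h),
                     n_back = round(w_rest_h / bin_h))
  score <- rs$mean_fwd - rs$mean_back
  h <- hours_between(activity$time, anchor)
  day <- as.integer(floor(h / day_length_h))
  res <- tibble::tibble(
    day = day, score = score,
    time = activity$time, h = h,
    has_data = !is.na(activity$ali)
  ) |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(df, key) {
      if (!any(df$has_data) || all(is.na(df$score))) {
        warn(paste0("day ", key$day, ": no usable data, onset skipped"))
        return(tibble::tibble())
      }
      i <- which.max(df$score) # which.max takes the first (earliest) tie
      tibble::tibble(
        onset_h = (as.numeric(df$time[i]) %% 86400) / 3600, # wall clock
        onset_time = df$time[i],
        contrast = max(df$score[i], 0)
      )
    }) |>
    dplyr::ungroup()
  res$animal_id <- activity$animal_id[1]
  dplyr::relocate(res, "animal_id", "day", "onset_h", "onset_time", "contrast")
}

#' Phase shift between two onsets (Aschoff type II)
#'
#' Circular difference `onset(day_after) - onset(day_before)` mapped to
#' `(-12, 12]` hours. Positive values are phase *delays* (the onset moved
#' later), matching the direction of an early-night light pulse; note
#' that many phase-response conventions use the opposite sign.
#'
#' When the days after the stimulus are spent in constant darkness, this
#' single-day comparison includes any free-running drift accumulated
#' between the two days; see [phase_shift_regression()] for a
#' drift-compensated estimate.
#'
#' @param onsets Onset tibble from [detect_onsets()], with `day` indexed
#'   relative to the stimulus day (day 0).
#' @param day_before,day_after Days compared (defaults -1 and +4).
#' @return One-row tibble with `shift_h`, `day_before`, `day_after`.
#' @export
phase_shift <- function(onsets, day_before = -1L, day_after = 4L) {
  ob <- onsets$onset_h[onsets$day == day_before]
  oa <- onsets$onset_h[onsets$day == day_after]
  if (length(ob) != 1) abort(paste0("no onset for day ", day_before))
  if (length(oa) != 1) abort(paste0("no onset for day ", day_after))
  tibble::tibble(
    shift_h = circular_diff_h(oa - ob),
    day_before = day_before,
    day_after = day_after
  )
}

#' Drift-compensated phase-shift estimate
#'
#' Fits a line through the post-stimulus onsets (unwrapped on the 24-h
#' circle) over `fit_days` and extrapolates it back to the stimulus day
#' (day 0); the shift is the extrapolated onset minus the pre-stimulus
#' onset, mapped to `(-12, 12]`. The fitted slope estimates the
#' free-running drift per day, so the shift estimate is unconfounded by
#' a free-running period different from 24 h.
#'
#' @param onsets Onset tibble, `day` indexed relative to the stimulus day.
#' @param day_before Pre-stimulus reference day (default -1).
#' @param fit_days Days used for the regression (default 2:9).
#' @return One-row tibble with `shift_h`, `drift_h_per_day`, `n_days`.
#' @export
phase_shift_regression <- function(onsets, day_before = -1L, fit_days = 2:9) {
  ob <- onsets$onset_h[onsets$day == day_before]
  if (length(ob) != 1) abort(paste0("no onset for day ", day_before))
  pts <- onsets[onsets$day %in% fit_days, c("day", "onset_h")]
  if (nrow(pts) < 2) abort("need at least 2 post-stimulus onsets to fit")
  pts <- dplyr::arrange(pts, .data$day)
  # unwrap relative to the pre-stimulus onset so the fit is on a line
  rel <- cumsum(c(circular_diff_h(pts$onset_h[1] - ob),
                  circular_diff_h(diff(pts$onset_h))))
  fit <- lm(rel ~ day, data = tibble::tibble(rel = rel, day = pts$day))
  tibble::tibble(
    shift_h = circular_diff_h(unname(coef(fit)[1])),
    drift_h_per_day = unname(coef(fit)[2]),
    n_days = nrow(pts)
  )
}

#' Days to re-entrain after a shifted light-dark cycle
#'
#' The smallest `d >= 1` such that on days `shift_day + d` through
#' `shift_day + d + stable_days - 1` the circular distance between the
#' activity onset and the new dark onset is at most `tol_h`. For an
#' animal correcting a shift of `S` hours at `rho` hours per day with
#' noiseless onsets this equals `ceiling((S - tol_h) / rho)`.
#'
#' @param onsets Onset tibble from [detect_onsets()].
#' @param target_onset_h New dark-onset time (hours, same clock as
#'   `onset_h`).
#' @param shift_day Day index on which the new cycle began (default 0).
#' @param tol_h Re-entrainment tolerance epsilon (default 0.5 h).
#' @param stable_days Consecutive days required within tolerance
#'   (default 2).
#' @return One-row tibble with `days_to_reentrain` (`NA` when never
#'   reached within the record), `reached`, `tol_h`, `stable_days`.
#' @export
days_to_reentrain <- function(onsets, target_onset_h, shift_day = 0L,
                              tol_h = 0.5, stable_days = 2L) {
  rel <- onsets[onsets$day >= shift_day + 1L, c("day", "onset_h")]
  rel <- dplyr::arrange(rel, .data$day)
  dev <- abs(circular_diff_h(rel$onset_h - target_onset_h))
  names(dev) <- rel$day
  max_d <- if (nrow(rel) > 0) max(rel$day) - shift_day else 0L
  for (d in seq_len(max_d)) {
    need <- shift_day + d + seq_len(stable_days) - 1L
    got <- dev[as.character(need)]
    if (length(got) == length(need) && !anyNA(got) && all(got <= tol_h)) {
      return(tibble::tibble(days_to_reentrain = as.integer(d), reached = TRUE,
                            tol_h = tol_h, stable_days = as.integer(stable_days)))
    }
  }
  tibble::tibble(days_to_reentrain = NA_integer_, reached = FALSE,
                 tol_h = tol_h, stable_days = as.integer(stable_days))
}

#' Build an actogram matrix
#'
#' One row per day; when double-plotted, row `d` concatenates day `d` and
#' day `d + 1` (the final row's right half is filled with `NA`). The
#' matrix is the tested artifact; [autoplot()] renders the conventional
#' raster (darker = more activity).
#'
#' @param activity Single-animal (typically smoothed) activity tibble.
#' @param bins_per_row Bins per day row (default 288 = 5-min bins). The
#'   trace is re-binned if needed.
#' @param double Double-plot (default TRUE).
#' @param schedule,anchor Day-boundary convention, as in [split_days()].
#' @param onsets Optional onset tibble to overlay in the plot.
#' @return Object of class `actogram`: list with `mat` (days x bins),
#'   `bins_per_row`, `double`, `anchor`, `onsets`.
#' @export
build_actogram <- function(activity, bins_per_row = 288, double = TRUE,
                           schedule = NULL, anchor = NULL, onsets = NULL) {
  activity <- one_animal(activity)
  anchor <- anchor %||% day_anchor(activity, schedule)
  target_bs <- 86400 / bins_per_row
  if (bin_seconds_of(activity) != target_bs) {
    activity <- rebin(activity, target_bs)
  }
  sec <- round(as.numeric(difftime(activity$time, anchor, units = "secs")))
  day <- sec %/% 86400L
  bin <- (sec %% 86400L) %/% as.integer(target_bs) + 1L
  keep <- day >= 0
  n_days <- max(day[keep]) + 1L
  mat <- matrix(NA_real_, nrow = n_days, ncol = bins_per_row)
  mat[cbind(day[keep] + 1L, bin[keep])] <- activity$ali[keep]
  if (double) {
    mat <- cbind(mat, rbind(mat[-1, , drop = FALSE],
                            matrix(NA_real_, 1, bins_per_row)))
  }
  structure(
    list(mat = mat, bins_per_row = bins_per_row, double = double,
         anchor = anchor, onsets = onsets,
         animal_id = activity$animal_id[1]),
    class = "actogram"
  )
}

#' @rdname build_actogram
#' @param object An `actogram` object.
#' @param ... Unused.
#' @export
autoplot.actogram <- function(object, ...) {
  m <- object$mat
  df <- tidyr::expand_grid(day = seq_len(nrow(m)), bin = seq_len(ncol(m)))
  df$ali <- m[cbind(df$day, df$bin)]
  df$hour <- (df$bin - 1) / object$bins_per_row * 24
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$day,
                                        fill = .data$ali)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 na.value = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = if (object$double) "time (h, double-plotted)" else "time (h)",
                  y = "day", fill = "ALI",
                  title = object$animal_id)
  if (!is.null(object$onsets)) {
    ons <- dplyr::mutate(object$onsets,
                         hour = hours_between(.data$onset_time, object$anchor) -
                           .data$day * 24)
    p <- p + ggplot2::geom_point(
      data = ons, ggplot2::aes(x = .data$hour, y = .data$day + 1),
      inherit.aes = FALSE, colour = "orange", size = 1
    )
  }
  p
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf("Actogram: %s, %d days x %d bins%s\n", x$animal_id,
              nrow(x$mat), x$bins_per_row,
              if (x$double) " (double-plotted)" else ""))
  invisible(x)
}
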