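#' Run the full circadian screen on a cohort
#'
#' For every animal and protocol phase this computes, on up to
#' `analysis_days` consecutive full days from the phase's first full day:
#' the chi-square periodogram peak (period, max Qp, chi-square excess and
#' the Bonferroni-corrected significance call), inter-daily stability,
#' intra-daily variability, M10/L5/relative amplitude, the activity-bout
#' length distribution, the light-phase activity fraction (entrained
#' phases only) and mean total daily activity. For the jet-lag phase it
#' additionally reports days to re-entrain; for the post-light-pulse
#' phase, the Day -1 vs Day +4 phase shift and its drift-compensated
#' regression estimate. Phases with fewer than `min_days` full days get a
#' row of explicit `NA` markers and a warning, and the run continues.
#'
#' @param activity Cohort activity tibble (minute bins).
#' @param schedule Lighting schedule shared by the cohort.
#' @param protocol [screen_protocol()] object defining phases and days.
#' @param analysis_days Days analysed per phase (default 7, one week).
#' @param min_days Minimum full days for a phase to be analysable
#'   (default 5).
#' @param periodogram_bin_seconds Bin width for the periodogram (default
#'   360 s, giving 0.1-h period resolution on the default grid).
#' @param p_min_h,p_max_h,alpha Periodogram grid and significance level.
#' @param is_iv_bin_seconds Bin width for IS/IV (default 3600 s, the
#'   hourly convention).
#' @param bout_threshold,bout_max_gap Bout definition (ALI threshold and
#'   bridgeable gap in minutes).
#' @param smooth_minutes Running-average window for onset detection.
#' @param w_rest_h,w_act_h Onset template windows.
#' @param reentrain_tol_h,reentrain_stable_days Re-entrainment criterion.
#' @param out_dir Optional output directory: writes `metrics.csv`,
#'   `onsets.csv`, `periodograms.csv`, `summary.json` and per-animal
#'   actogram PNGs.
#' @return Object of class `screen_result`: list with `metrics` (one row
#'   per animal x phase), `onsets`, `periodograms` (curves), `summary`
#'   (cohort mean +/- SEM per phase/genotype/sex) and `params` (every
#'   analysis parameter echoed for provenance).
#' @export
run_screen <- function(activity, schedule, protocol,
                       analysis_days = 7, min_days = 5,
                       periodogram_bin_seconds = 360,
                       p_min_h = 16, p_max_h = 32, alpha = 0.05,
                       is_iv_bin_seconds = 3600,
                       bout_threshold = 0, bout_max_gap = 0L,
                       smooth_minutes = 30, w_rest_h = 6, w_act_h = 6,
                       reentrain_tol_h = 0.5, reentrain_stable_days = 2L,
                       out_dir = NULL) {
  activity <- check_activity(activity)
  if (!"sex" %in% names(activity)) activity$sex <- "unknown"
  if (!"genotype" %in% names(activity)) activity$genotype <- "unknown"
  params <- list(
    analysis_days = analysis_days, min_days = min_days,
    periodogram_bin_seconds = periodogram_bin_seconds,
    p_min_h = p_min_h, p_max_h = p_max_h, alpha = alpha,
    is_iv_bin_seconds = is_iv_bin_seconds,
    bout_threshold = bout_threshold, bout_max_gap = bout_max_gap,
    smooth_minutes = smooth_minutes, w_rest_h = w_rest_h, w_act_h = w_act_h,
    reentrain_tol_h = reentrain_tol_h,
    reentrain_stable_days = reentrain_stable_days
  )
  ids <- unique(activity$animal_id)
  res <- purrr::map(ids, function(id) {
    screen_one(dplyr::filter(activity, .data$animal_id == id),
               schedule, protocol, params)
  })
  metrics <- dplyr::bind_rows(purrr::map(res, "metrics"))
  onsets <- dplyr::bind_rows(purrr::map(res, "onsets"))
  curves <- dplyr::bind_rows(purrr::map(res, "curves"))
  out <- structure(
    list(metrics = metrics, onsets = onsets, periodograms = curves,
         summary = summarize_cohort(metrics), params = params),
    class = "screen_result"
  )
  if (!is.null(out_dir)) write_screen_outputs(out, activity, out_dir)
  out
}

# Analyse one animal across all protocol phases.
screen_one <- function(act, schedule, protocol, pr) {
  id <- act$animal_id[1]
  smoothed <- running_average(act, pr$smooth_minutes)
  days <- protocol$days
  trace_end <- max(act$time) + bin_seconds_of(act)

  rows <- list(); curves <- list(); onset_tbl <- list()
  for (k in seq_len(nrow(protocol$phases))) {
    ph <- protocol$phases[k, ]
    pd <- days[days$phase == ph$phase, ]
    full <- pd$day_len_h == 24 & pd$day_end <= trace_end
    # consecutive full days from the first full day of the phase
    first <- which(full)[1]
    n_full <- 0L
    if (!is.na(first)) {
      run <- cumprod(full[first:nrow(pd)])
      n_full <- sum(run)
    }
    n_use <- min(n_full, pr$analysis_days)
    row <- tibble::tibble(
      animal_id = id, sex = act$sex[1], genotype = act$genotype[1],
      phase = ph$phase, condition = ph$condition, n_days = n_use,
      period_h = NA_real_, max_qp = NA_real_, qp_excess = NA_real_,
      qp_significant = NA, is = NA_real_, iv = NA_real_,
      m10 = NA_real_, l5 = NA_real_, ra = NA_real_,
      light_phase_fraction = NA_real_, total_activity = NA_real_,
      days_to_reentrain = NA_integer_,
      phase_shift_h = NA_real_, phase_shift_reg_h = NA_real_
    )
    bout_cols <- stats::setNames(rep(NA_integer_, 8),
                                 paste0("bout_", c(1:7, "8p")))
    if (n_use < pr$min_days) {
      warn(paste0(id, " / ", ph$phase, ": only ", n_use,
                  " full days, metrics left undefined"))
      rows[[k]] <- dplyr::bind_cols(row, tibble::as_tibble(as.list(bout_cols)))
      next
    }
    w0 <- pd$day_start[first]
    w1 <- w0 + n_use * 86400
    slice <- dplyr::filter(act, .data$time >= w0, .data$time < w1)

    pg <- tryCatch(
      chi_square_periodogram(rebin(slice, pr$periodogram_bin_seconds),
                             p_min_h = pr$p_min_h, p_max_h = pr$p_max_h,
                             alpha = pr$alpha),
      error = function(e) NULL
    )
    if (!is.null(pg)) {
      row$period_h <- pg$peak_period_h
      row$max_qp <- pg$max_qp
      row$qp_excess <- pg$qp_excess
      row$qp_significant <- pg$significant
      curves[[length(curves) + 1]] <-
        dplyr::mutate(pg$curve, animal_id = id, phase = ph$phase)
    }
    hourly <- rebin(slice, pr$is_iv_bin_seconds)
    row$is <- quiet_na(interdaily_stability(hourly))
    row$iv <- quiet_na(intradaily_variability(hourly))
    prof <- daily_profile(slice, bins_per_day = 24, anchor = w0)
    ml <- suppressWarnings(m10_l5(prof))
    row$m10 <- ml$m10; row$l5 <- ml$l5; row$ra <- ml$ra
    if (ph$condition == "LD") {
      row$light_phase_fraction <-
        quiet_na(light_phase_activity(slice, schedule))
    }
    tot <- total_activity(slice, anchor = w0)
    row$total_activity <- mean(tot$total, na.rm = TRUE)
    b <- activity_bouts(slice, pr$bout_threshold, pr$bout_max_gap)
    bout_cols[] <- b$count

    if (ph$phase == "JETLAG_LD") {
      jw0 <- pd$day_start[1]
      jl <- dplyr::filter(smoothed, .data$time >= jw0 - 86400,
                          .data$time < max(pd$day_end))
      ons <- suppressWarnings(
        detect_onsets(jl, anchor = jw0, w_rest_h = pr$w_rest_h,
                      w_act_h = pr$w_act_h)
      )
      target <- (days$lights_on_h[days$phase == "JETLAG_LD"][1] + 12) %% 24
      re <- days_to_reentrain(ons, target_onset_h = target, shift_day = 0L,
                              tol_h = pr$reentrain_tol_h,
                              stable_days = pr$reentrain_stable_days)
      row$days_to_reentrain <- re$days_to_reentrain
      onset_tbl[[length(onset_tbl) + 1]] <-
        dplyr::mutate(ons, context = "jetlag")
    }
    if (ph$phase == "DD_POST_LP" && !is.null(protocol$lp_time)) {
      lp_anchor <- days$day_start[which(!is.na(days$lp_zt))[1]]
      lw <- dplyr::filter(smoothed, .data$time >= lp_anchor - 2 * 86400,
                          .data$time < max(pd$day_end))
      ons <- suppressWarnings(
        detect_onsets(lw, anchor = lp_anchor, w_rest_h = pr$w_rest_h,
                      w_act_h = pr$w_act_h)
      )
      row$phase_shift_h <- tryCatch(
        phase_shift(ons, day_before = -1L, day_after = 4L)$shift_h,
        error = function(e) NA_real_
      )
      row$phase_shift_reg_h <- tryCatch(
        phase_shift_regression(ons, day_before = -1L, fit_days = 2:9)$shift_h,
        error = function(e) NA_real_
      )
      onset_tbl[[length(onset_tbl) + 1]] <-
        dplyr::mutate(ons, context = "light_pulse")
    }
    rows[[k]] <- dplyr::bind_cols(row, tibble::as_tibble(as.list(bout_cols)))
  }
  list(
    metrics = dplyr::bind_rows(rows),
    onsets = dplyr::bind_rows(onset_tbl),
    curves = dplyr::bind_rows(curves)
  )
}

quiet_na <- function(x) suppressWarnings(x)

#' Cohort summary: mean and SEM per group
#'
#' Mean and standard error (sd / sqrt(n), over defined values) of every
#' numeric metric, per phase, genotype and sex, with the contributing `n`
#' reported. Undefined (NA) values are excluded; all-undefined groups are
#' omitted with a warning; a single defined value yields an `NA` SEM.
#'
#' @param metrics Per-animal metrics tibble from [run_screen()].
#' @param by Grouping columns (default phase, genotype, sex).
#' @return Long tibble with `metric`, grouping columns, `mean`, `sem`, `n`.
#' @export
summarize_cohort <- function(metrics, by = c("phase", "genotype", "sex")) {
  by <- intersect(by, names(metrics))
  num <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  num <- setdiff(num, "n_days")
  long <- tidyr::pivot_longer(metrics, dplyr::all_of(num),
                              names_to = "metric", values_to = "value")
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "metric")))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = if (sum(!is.na(.data$value)) > 0) {
        mean(.data$value, na.rm = TRUE)
      } else NA_real_,
      sem = if (sum(!is.na(.data$value)) > 1) {
        sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
      } else NA_real_,
      .groups = "drop"
    )
  empty <- out$n == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " group(s) had no defined values and were omitted"))
    out <- out[!empty, ]
  }
  out
}

write_screen_outputs <- function(res, activity, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics_csv(res$metrics, file.path(out_dir, "metrics.csv"))
  if (nrow(res$onsets) > 0) {
    readr::write_csv(res$onsets, file.path(out_dir, "onsets.csv"))
  }
  if (nrow(res$periodograms) > 0) {
    readr::write_csv(res$periodograms, file.path(out_dir, "periodograms.csv"))
  }
  jsonlite::write_json(
    list(parameters = res$params, cohort_summary = res$summary),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null", POSIXt = "ISO8601"
  )
  for (id in unique(activity$animal_id)) {
    a <- dplyr::filter(activity, .data$animal_id == id)
    acto <- build_actogram(running_average(a, 30))
    ggplot2::ggsave(
      file.path(out_dir, paste0("actogram_", id, ".png")),
      ggplot2::autoplot(acto), width = 7, height = 5, dpi = 120
    )
  }
  invisible(out_dir)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Circadian screen result\n")
  cat(sprintf("  %d animals x %d phases (%d metric rows)\n",
              dplyr::n_distinct(x$metrics$animal_id),
              dplyr::n_distinct(x$metrics$phase), nrow(x$metrics)))
  cat("  metrics: period_h, max_qp, is, iv, ra, light_phase_fraction,",
      "total_activity, bouts,\n           days_to_reentrain, phase_shift_h\n")
  invisible(x)
}
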