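#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period of `P` bins the first `K = floor(N/P)`
#' complete cycles are folded into a `K x P` array with column means
#' `M_h` and grand mean `M`, and
#' \deqn{Q_P = N' K \sum_h (M_h - M)^2 / \sum_i (x_i - M)^2}
#' over the `N' = K P` folded points. Under the white-noise null `Q_P` is
#' approximately chi-square with `P - 1` degrees of freedom, which gives
#' the per-candidate significance line; a noiseless periodic signal
#' reaches the ceiling `Q_P = N'` at its true period. Missing bins are
#' excluded from all means and sums with matching counts.
#'
#' The peak is the candidate maximising `Q_P` minus its significance line.
#' Because the peak is selected across the whole candidate grid, the
#' peak-level significance call (`significant` in [glance()]) uses a
#' Bonferroni-corrected critical value (`alpha / n_candidates`); the
#' nominal per-candidate line is kept in the curve for plotting.
#'
#' @param x Single-animal activity tibble, or a numeric vector of
#'   uniformly binned ALI values (`NA` = missing).
#' @param bin_seconds Bin width in seconds; required when `x` is a bare
#'   vector, inferred otherwise.
#' @param p_min_h,p_max_h Candidate period range in hours (default 16-32).
#' @param step_bins Candidate grid step in bins (default 1, i.e. 0.1 h on
#'   6-min bins).
#' @param alpha Significance level of the chi-square line (default 0.05).
#' @return An object of class `chi_sq_periodogram`: use [tidy()] for the
#'   (period, Qp, significance line) curve and [glance()] for the peak.
#' @export
chi_square_periodogram <- function(x, bin_seconds = NULL,
                                   p_min_h = 16, p_max_h = 32,
                                   step_bins = 1L, alpha = 0.05) {
  if (is.data.frame(x)) {
    x <- one_animal(x)
    bin_seconds <- bin_seconds %||% bin_seconds_of(x)
    x <- x$ali
  }
  if (is.null(bin_seconds)) abort("`bin_seconds` is required for vector input")
  bin_h <- bin_seconds / 3600
  n <- length(x)
  p_bins <- seq(round(p_min_h / bin_h), round(p_max_h / bin_h), by = step_bins)
  p_bins <- p_bins[p_bins >= 2]
  if (length(p_bins) == 0) abort("empty candidate period grid")
  if (floor(n / max(p_bins)) < 3) {
    abort("trace too short: need at least 3 full cycles of the longest candidate period")
  }
  if (sum(!is.na(x)) < 2 || var(x, na.rm = TRUE) == 0) {
    abort("periodogram undefined for constant (zero-variance) input")
  }
  qp <- numeric(length(p_bins))
  for (j in seq_along(p_bins)) {
    qp[j] <- qp_stat(x, p_bins[j])
  }
  df <- p_bins - 1L
  sig <- qchisq(1 - alpha, df)
  excess <- qp - sig
  peak <- which.max(excess)
  n_cand <- length(p_bins)
  structure(
    list(
      curve = tibble::tibble(
        period_h = p_bins * bin_h, qp = qp, df = df, sig_line = sig
      ),
      peak_period_h = p_bins[peak] * bin_h,
      max_qp = qp[peak],
      qp_excess = excess[peak],
      significant = qp[peak] > qchisq(1 - alpha / n_cand, df[peak]),
      alpha = alpha,
      n_candidates = n_cand,
      bin_seconds = bin_seconds,
      n = n
    ),
    class = "chi_sq_periodogram"
  )
}

# Qp for one candidate period of p bins, missing-aware.
qp_stat <- function(x, p) {
  k <- floor(length(x) / p)
  xx <- x[seq_len(k * p)]
  col <- rep(seq_len(p), k)
  ok <- !is.na(xx)
  if (!any(ok)) return(NA_real_)
  m <- mean(xx[ok])
  tot <- sum((xx[ok] - m)^2)
  if (tot == 0) return(NA_real_)
  n_h <- tabulate(col[ok], nbins = p)
  s_h <- vapply(split(xx[ok], col[ok]), sum, numeric(1))
  m_h <- numeric(p)
  m_h[n_h > 0] <- s_h / n_h[n_h > 0]
  n_eff <- sum(ok)
  n_eff * sum(n_h * (m_h - m)^2) / tot
}

#' @export
print.chi_sq_periodogram <- function(x, ...) {
  cat("Chi-square periodogram\n")
  cat(sprintf("  candidates: %d periods in [%.1f, %.1f] h\n",
              x$n_candidates, min(x$curve$period_h), max(x$curve$period_h)))
  cat(sprintf("  peak period: %.2f h   max Qp: %.1f (excess over chi-sq line: %.1f)\n",
              x$peak_period_h, x$max_qp, x$qp_excess))
  cat(sprintf("  peak significant at alpha = %g (Bonferroni over grid): %s\n",
              x$alpha, x$significant))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname chi_square_periodogram
#' @param x A `chi_sq_periodogram` object.
#' @param ... Unused.
#' @export
tidy.chi_sq_periodogram <- function(x, ...) x$curve

#' @rdname chi_square_periodogram
#' @export
glance.chi_sq_periodogram <- function(x, ...) {
  tibble::tibble(
    peak_period_h = x$peak_period_h,
    max_qp = x$max_qp,
    qp_excess = x$qp_excess,
    significant = x$significant,
    alpha = x$alpha,
    n_candidates = x$n_candidates,
    n = x$n
  )
}

#' @rdname chi_square_periodogram
#' @param object A `chi_sq_periodogram` object.
#' @export
autoplot.chi_sq_periodogram <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$period_h)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$qp)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sig_line), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$peak_period_h,
                        colour = "grey50", linetype = "dotted") +
    ggplot2::labs(x = "candidate period (h)", y = expression(Q[p]),
                  title = sprintf("Peak %.1f h, max Qp = %.0f",
                                  object$peak_period_h, object$max_qp))
}

#' Inter-daily stability (IS)
#'
#' Ratio of the variance of the mean daily profile to the total variance:
#' \deqn{IS = \frac{N \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2}}
#' with `p` bins per day. IS is 1 when every day repeats the same pattern
#' exactly and has expectation ~1/D for D days of uncorrelated noise.
#' The analysis span is truncated to whole days; missing bins are dropped
#' with count-consistent normalisation (per-bin means over their own
#' counts, variances over the non-missing points).
#'
#' @param x Single-animal activity tibble or numeric vector of binned
#'   values in day order.
#' @param bins_per_day Bins per day `p` (default 24, the hourly
#'   convention).
#' @return IS in `[0, 1]`, or `NA` (with a warning) when the total
#'   variance is zero.
#' @export
interdaily_stability <- function(x, bins_per_day = 24) {
  x <- metric_values(x)
  d <- floor(length(x) / bins_per_day)
  if (d < 2) abort("need at least 2 full days for IS")
  xx <- x[seq_len(d * bins_per_day)]
  h <- rep(seq_len(bins_per_day), d)
  ok <- !is.na(xx)
  m <- mean(xx[ok])
  tot <- sum((xx[ok] - m)^2) / sum(ok)
  if (tot == 0) {
    warn("zero total variance: IS undefined")
    return(NA_real_)
  }
  n_h <- tabulate(h[ok], nbins = bins_per_day)
  s_h <- rep(NA_real_, bins_per_day)
  s_h[n_h > 0] <- vapply(split(xx[ok], h[ok]), mean, numeric(1))
  between <- sum((s_h[n_h > 0] - m)^2) / sum(n_h > 0)
  between / tot
}

#' Intra-daily variability (IV)
#'
#' Normalised mean squared successive difference,
#' \deqn{IV = \frac{N \sum_{i=2}^{N} (x_i - x_{i-1})^2}{(N-1)\sum_i (x_i - \bar x)^2},}
#' an index of rest-activity fragmentation: ~2 for white noise, small for
#' consolidated rhythms. First differences spanning a missing bin are
#' skipped, with the pair count adjusted to match.
#'
#' @inheritParams interdaily_stability
#' @return IV >= 0, or `NA` (with a warning) for zero-variance input.
#' @export
intradaily_variability <- function(x) {
  x <- metric_values(x)
  ok <- !is.na(x)
  if (sum(ok) < 2) abort("need at least 2 non-missing bins for IV")
  m <- mean(x[ok])
  tot <- sum((x[ok] - m)^2) / sum(ok)
  if (tot == 0) {
    warn("zero total variance: IV undefined")
    return(NA_real_)
  }
  d <- diff(x)
  d <- d[!is.na(d)] # a diff is NA iff either neighbour is missing
  if (length(d) == 0) {
    warn("no valid successive pairs: IV undefined")
    return(NA_real_)
  }
  mssd <- sum(d^2) / length(d)
  mssd / tot
}

#' M10, L5 and relative amplitude (RA)
#'
#' M10 is the maximum over circular 10-h windows of the windowed mean of
#' the daily profile; L5 the minimum over circular 5-h windows;
#' `RA = (M10 - L5) / (M10 + L5)`.
#'
#' @param profile A [daily_profile()] tibble (or any tibble with a
#'   `mean_ali` column on an equally spaced circular day grid).
#' @param active_window_h Width of the most-active window (default 10 h).
#' @param rest_window_h Width of the least-active window (default 5 h).
#' @return One-row tibble with `m10`, `l5`, `ra`; `ra` is `NA` (with a
#'   warning) when `M10 + L5 = 0`.
#' @export
m10_l5 <- function(profile, active_window_h = 10, rest_window_h = 5) {
  v <- profile$mean_ali
  p <- length(v)
  bin_h <- 24 / p
  wa <- active_window_h / bin_h
  wr <- rest_window_h / bin_h
  if (wa != round(wa) || wr != round(wr)) {
    abort("window widths must be whole numbers of profile bins")
  }
  m10 <- max(circular_window_means(v, as.integer(wa)))
  l5 <- min(circular_window_means(v, as.integer(wr)))
  ra <- if (m10 + l5 == 0) {
    warn("all-zero profile: RA undefined")
    NA_real_
  } else {
    (m10 - l5) / (m10 + l5)
  }
  tibble::tibble(m10 = m10, l5 = l5, ra = ra)
}

#' @rdname m10_l5
#' @export
relative_amplitude <- function(profile, active_window_h = 10, rest_window_h = 5) {
  m10_l5(profile, active_window_h, rest_window_h)$ra
}

circular_window_means <- function(v, w) {
  p <- length(v)
  if (w > p) abort("window wider than the day")
  ext <- c(v, v[seq_len(w - 1)])
  vapply(seq_len(p), function(i) mean(ext[i:(i + w - 1)], na.rm = TRUE),
         numeric(1))
}

#' Activity-bout length distribution
#'
#' A bout is a maximal run of bins with ALI above `threshold`;
#' interruptions of at most `max_gap_bins` consecutive at-or-below-
#' threshold bins do not break a run, and bout length counts the
#' interruptions. Missing bins always terminate a bout. Lengths are
#' tallied into eight classes: 1-7 minutes and `8+`.
#'
#' @param x Single-animal minute-binned activity tibble or numeric vector.
#' @param threshold ALI threshold `theta` (default 0: any activity).
#' @param max_gap_bins Bridgeable gap length `g` in bins (default 0).
#' @return Tibble with `bout_class` (`"1"`..`"7"`, `"8+"`) and `count`.
#' @export
activity_bouts <- function(x, threshold = 0, max_gap_bins = 0L) {
  x <- metric_values(x)
  # 2 = active, 1 = inactive, 0 = missing (hard break)
  state <- ifelse(is.na(x), 0L, ifelse(x > threshold, 2L, 1L))
  r <- rle(state)
  lengths <- integer(0)
  cur <- 0L
  pend_gap <- 0L
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    len <- r$lengths[i]
    if (v == 2L) {
      cur <- cur + pend_gap + len
      pend_gap <- 0L
    } else if (v == 1L && cur > 0L && len <= max_gap_bins) {
      pend_gap <- len # bridged only if more activity follows
    } else {
      if (cur > 0L) lengths <- c(lengths, cur)
      cur <- 0L
      pend_gap <- 0L
    }
  }
  if (cur > 0L) lengths <- c(lengths, cur)
  cls <- factor(pmin(lengths, 8L), levels = 1:8,
                labels = c(as.character(1:7), "8+"))
  tibble::tibble(
    bout_class = factor(c(as.character(1:7), "8+"),
                        levels = c(as.character(1:7), "8+")),
    count = as.integer(table(cls))
  )
}

#' Fraction of activity occurring during the light phase
#'
#' Sum of non-missing ALI within light episodes divided by the total
#' non-missing ALI. Undefined (NA, with a warning) under constant
#' darkness or when the animal shows no activity at all.
#'
#' @param activity Single-animal activity tibble.
#' @param schedule Schedule tibble overlapping the trace.
#' @return Fraction in `[0, 1]`, or `NA` when undefined.
#' @export
light_phase_activity <- function(activity, schedule) {
  activity <- one_animal(activity)
  st <- light_state(schedule, activity$time)
  if (!any(st == "light")) {
    warn("no light episodes overlap the trace: light-phase activity undefined")
    return(NA_real_)
  }
  tot <- sum(activity$ali, na.rm = TRUE)
  if (tot == 0) {
    warn("zero total activity: light-phase activity undefined")
    return(NA_real_)
  }
  sum(activity$ali[st == "light"], na.rm = TRUE) / tot
}

#' Total daily activity
#'
#' Per-day sum of non-missing ALI, rescaled by the fraction of bins that
#' are non-missing so that short welfare-check gaps do not deflate the
#' day's total. Only full days (per the day-boundary convention) are
#' summed.
#'
#' @param activity Single-animal activity tibble covering >= 1 full day.
#' @param schedule,anchor Day-boundary convention, as in [split_days()].
#' @return Tibble with `day` and `total` (ALI x bins per day).
#' @export
total_activity <- function(activity, schedule = NULL, anchor = NULL) {
  activity <- one_animal(activity)
  days <- split_days(activity, schedule = schedule, anchor = anchor)
  days |>
    dplyr::filter(!.data$partial) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      total = if (sum(!is.na(.data$ali)) == 0) NA_real_ else {
        sum(.data$ali, na.rm = TRUE) * dplyr::n() / sum(!is.na(.data$ali))
      },
      .groups = "drop"
    )
}

# Accept a tibble or bare numeric vector for the sequence metrics.
metric_values <- function(x) {
  if (is.data.frame(x)) one_animal(x)$ali else as.numeric(x)
}
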