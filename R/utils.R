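#' @importFrom rlang .data abort warn %||%
#' @importFrom stats qchisq sd var rgamma rbinom rnorm runif median coef lm
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Hours between two POSIXct instants.
hours_between <- function(t, origin) {
  as.numeric(difftime(t, origin, units = "hours"))
}

#' Map an hour difference onto the circular interval (-12, 12]
#'
#' Differences between clock times (activity onsets, phase angles) live on a
#' 24-h circle; this maps any real-valued difference to the signed
#' half-circle, with exactly 12 h mapped to +12.
#'
#' @param dh Numeric vector of hour differences.
#' @return Numeric vector in (-12, 12].
#' @export
#' @examples
#' circular_diff_h(c(1.3, -23, 13))
circular_diff_h <- function(dh) {
  d <- dh %% 24
  ifelse(d > 12, d - 24, d)
}

# Validate that `x` is a single-animal activity tibble and return it sorted.
check_activity <- function(x, call = rlang::caller_env()) {
  if (!is.data.frame(x)) {
    abort("`activity` must be a data frame (see `read_activity_csv()`).", call = call)
  }
  need <- c("animal_id", "time", "ali")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("`activity` is missing column(s): ", paste(miss, collapse = ", ")),
          call = call)
  }
  dplyr::arrange(tibble::as_tibble(x), .data$animal_id, .data$time)
}

one_animal <- function(x, call = rlang::caller_env()) {
  x <- check_activity(x, call = call)
  if (dplyr::n_distinct(x$animal_id) != 1) {
    abort("expected a single-animal activity table; use `dplyr::group_split()` or the cohort wrappers for multi-animal input.",
          call = call)
  }
  x
}

# Bin width in seconds, inferred from the (regular) time grid.
bin_seconds_of <- function(x) {
  if (nrow(x) < 2) return(NA_real_)
  d <- as.numeric(difftime(x$time[2], x$time[1], units = "secs"))
  round(d)
}

# Rolling mean over non-missing values, window of `before` bins strictly
# before i and `after` bins from i onward; shrinking at the series edges.
# Returns list(mean_fwd, mean_back) used by the onset template.
rolling_sums <- function(v, n_fwd, n_back) {
  n <- length(v)
  ok <- !is.na(v)
  vv <- ifelse(ok, v, 0)
  cs <- c(0, cumsum(vv))
  ck <- c(0, cumsum(ok))
  idx <- seq_len(n)
  # forward window [i, i + n_fwd - 1]
  hi <- pmin(idx + n_fwd - 1L, n)
  s_f <- cs[hi + 1L] - cs[idx]
  k_f <- ck[hi + 1L] - ck[idx]
  # backward window [i - n_back, i - 1]
  lo <- pmax(idx - n_back, 1L)
  s_b <- cs[idx] - cs[lo]
  k_b <- ck[idx] - ck[lo]
  list(
    mean_fwd = ifelse(k_f > 0, s_f / k_f, NA_real_),
    mean_back = ifelse(k_b > 0, s_b / k_b, NA_real_)
  )
}
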