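test_that("onsets land on the activity step and carry its contrast", {
  act <- running_average(make_square_day(3, low = 0, high = 8), 30)
  ons <- detect_onsets(act)
  expect_equal(nrow(ons), 3)
  # activity starts 12 h after the 07:00 anchor -> 19:00 wall clock
  expect_true(all(abs(ons$onset_h - 19) <= 10 / 60))
  expect_true(all(ons$contrast > 7))
})

test_that("onset detection is translation-equivariant and scale-invariant", {
  base <- make_square_day(3, low = 1, high = 9)
  shift <- base
  shift$time <- shift$time + 1.3 * 3600 # same values 1.3 h later
  o1 <- detect_onsets(running_average(base, 30))
  o2 <- detect_onsets(running_average(shift, 30), anchor = T0 + 1.3 * 3600)
  expect_equal(o2$onset_h, (o1$onset_h + 1.3) %% 24, tolerance = 1e-8)

  scaled <- base
  scaled$ali <- base$ali * 6
  o3 <- detect_onsets(running_average(scaled, 30))
  expect_equal(o3$onset_h, o1$onset_h)
  expect_equal(o3$contrast, o1$contrast * 6)
})

test_that("constant days give zero contrast; empty days are skipped", {
  cst <- make_activity(rep(5, 2 * 1440))
  ons <- detect_onsets(cst)
  expect_equal(ons$contrast, rep(0, 2))

  gappy <- make_activity(c(rep(5, 1440), rep(NA, 1440), rep(5, 1440)))
  expect_warning(ons <- detect_onsets(gappy), "onset skipped")
  expect_equal(nrow(ons), 2)
})

test_that("phase shift is a circular difference with delay positive", {
  ons <- tibble::tibble(day = c(-1, 4), onset_h = c(20, 21.3))
  expect_equal(phase_shift(ons)$shift_h, 1.3)

  wrap <- tibble::tibble(day = c(-1, 4), onset_h = c(23.5, 0.5))
  expect_equal(phase_shift(wrap)$shift_h, 1.0)

  same <- tibble::tibble(day = c(-1, 4), onset_h = c(20, 20))
  expect_equal(phase_shift(same)$shift_h, 0)

  expect_error(phase_shift(same[1, ]), "day 4")

  # antisymmetry under swapping the two days
  set.seed(8)
  for (i in 1:20) {
    o <- tibble::tibble(day = c(-1, 4), onset_h = runif(2, 0, 24))
    d1 <- phase_shift(o)$shift_h
    d2 <- phase_shift(tibble::tibble(day = c(-1, 4), onset_h = rev(o$onset_h)))$shift_h
    expect_equal(circular_diff_h(d1 + d2), 0)
  }
})

test_that("regression shift removes free-running drift from the estimate", {
  # onset_-1 = 13; pulse delays by 1.5 h; drift -0.5 h/day afterwards
  days <- c(-1, 1:9)
  onset <- c(13, 13 + 1.5 + (1:9 - 0) * -0.5)
  ons <- tibble::tibble(day = days, onset_h = onset %% 24)
  fit <- phase_shift_regression(ons)
  expect_equal(fit$shift_h, 1.5, tolerance = 1e-8)
  expect_equal(fit$drift_h_per_day, -0.5, tolerance = 1e-8)
})

test_that("days to re-entrain matches deviation sequences and closed form", {
  expect_equal(days_to_reentrain(make_onsets(c(5, 4, 3, 2, 1, 0, 0, 0)),
                                 13)$days_to_reentrain, 6)
  expect_equal(days_to_reentrain(make_onsets(rep(0, 5)), 13)$days_to_reentrain, 1)

  stuck <- days_to_reentrain(make_onsets(rep(3, 8)), 13)
  expect_true(is.na(stuck$days_to_reentrain))
  expect_false(stuck$reached)

  # noiseless rho h/day advance toward an S-h shift: ceil((S - eps)/rho)
  for (S in c(4, 6, 8)) {
    for (rho in c(0.5, 1, 1.5)) {
      devs <- pmax(S - rho * (1:20), 0)
      got <- days_to_reentrain(make_onsets(devs), 13, tol_h = 0.5)
      expect_equal(got$days_to_reentrain, ceiling((S - 0.5) / rho))
    }
  }
})

test_that("actogram matrix is day-by-bin, double-plotting duplicates day d+1", {
  act <- make_activity(rep(1:288, 3), bin_seconds = 300)
  a <- build_actogram(act, bins_per_row = 288, double = TRUE)
  expect_equal(dim(a$mat), c(3, 576))
  expect_true(all(is.na(a$mat[3, 289:576])))
  expect_equal(a$mat[1, 289:576], a$mat[2, 1:288])

  single <- build_actogram(act, bins_per_row = 288, double = FALSE)
  d <- split_days(act)
  expect_equal(as.vector(t(single$mat)), d$ali)
  # conservation, counting duplicates once
  expect_equal(sum(single$mat, na.rm = TRUE), sum(act$ali))
  expect_s3_class(ggplot2::autoplot(a), "ggplot")
})
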