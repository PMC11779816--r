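test_that("periodogram recovers a noisy period within one grid step", {
  # 23.5-h square gate with gamma noise, 7 days of 6-min bins; the peak
  # of single noisy traces scatters by about one grid step, so the
  # typical (median) error over replicates is what the grid resolves
  pgs <- lapply(1:5, function(s) {
    set.seed(s)
    n <- 7 * 240
    h <- (seq_len(n) - 1) * 0.1
    gate <- (h %% 23.5) >= 11.75
    x <- (1 + 20 * gate) * rgamma(n, 1)
    chi_square_periodogram(x, bin_seconds = 360)
  })
  peaks <- vapply(pgs, function(p) p$peak_period_h, numeric(1))
  expect_lte(median(abs(peaks - 23.5)), 0.1 + 1e-9)
  expect_true(all(vapply(pgs, function(p) p$significant, logical(1))))
  pg <- pgs[[1]]
  expect_equal(pg$max_qp, max(pg$curve$qp[pg$curve$period_h == pg$peak_period_h]))
})

test_that("periodogram errors on constant input and short traces", {
  expect_error(chi_square_periodogram(rep(5, 2000), bin_seconds = 360),
               "constant")
  expect_error(chi_square_periodogram(rnorm(80), bin_seconds = 3600),
               "3 full cycles")
})

test_that("periodogram excludes missing bins with matching counts", {
  # noiseless signal with missing bins still hits the ceiling Qp = N_eff
  x <- rep(c(rep(0, 120), rep(8, 120)), 7)
  x[c(5, 300, 1000)] <- NA
  pg <- chi_square_periodogram(x, bin_seconds = 360,
                               p_min_h = 24, p_max_h = 24)
  expect_equal(pg$max_qp, sum(!is.na(x)))
})

test_that("tidy/glance expose the curve and the peak", {
  x <- rep(c(rep(0, 120), rep(8, 120)), 7)
  pg <- chi_square_periodogram(x, bin_seconds = 360)
  expect_named(tidy(pg), c("period_h", "qp", "df", "sig_line"))
  g <- glance(pg)
  expect_equal(g$peak_period_h, 24)
  expect_s3_class(ggplot2::autoplot(pg), "ggplot")
})

test_that("IS closed forms: identical days, anti-phase days, iid noise", {
  expect_equal(interdaily_stability(c(0, 1, 0, 1), bins_per_day = 2), 1)
  expect_equal(interdaily_stability(c(0, 1, 1, 0), bins_per_day = 2), 0)
  # expectation ~ 1/D for D days of iid noise
  set.seed(4)
  for (d in c(4, 8)) {
    isv <- replicate(150, interdaily_stability(runif(24 * d), 24))
    expect_lt(abs(mean(isv) - 1 / d), 0.035)
  }
  expect_warning(v <- interdaily_stability(rep(3, 48)), "undefined")
  expect_true(is.na(v))
})

test_that("IS and IV are invariant to affine rescaling", {
  set.seed(6)
  x <- runif(24 * 5, 0, 40)
  for (f in list(function(z) 3 * z + 7, function(z) 0.1 * z - 2)) {
    expect_equal(interdaily_stability(f(x)), interdaily_stability(x))
    expect_equal(intradaily_variability(f(x)), intradaily_variability(x))
  }
})

test_that("IV closed forms: alternation, step, gap handling", {
  expect_equal(intradaily_variability(c(0, 1, 0, 1)), 4)
  expect_equal(intradaily_variability(c(0, 0, 1, 1)), 4 / 3)
  # differences across a missing bin are skipped with matching counts
  x <- c(0, 0, NA, 1, 1)
  # valid pairs: (0,0), (1,1) -> mssd 0
  expect_equal(intradaily_variability(x), 0)
})

test_that("M10/L5 and RA closed forms", {
  sq <- daily_profile(make_square_day(2), bins_per_day = 24)
  expect_equal(relative_amplitude(sq), 1) # L5 = 0 in the light phase

  cst <- sq; cst$mean_ali <- rep(7, 24)
  expect_equal(relative_amplitude(cst), 0)

  plateau <- sq; plateau$mean_ali <- c(rep(10, 12), rep(2, 12))
  ml <- m10_l5(plateau)
  expect_equal(ml$m10, 10)
  expect_equal(ml$l5, 2)
  expect_equal(ml$ra, (10 - 2) / (10 + 2))

  zero <- sq; zero$mean_ali <- rep(0, 24)
  expect_warning(ra <- relative_amplitude(zero), "undefined")
  expect_true(is.na(ra))
})

test_that("RA is invariant to positive rescaling of the profile", {
  set.seed(7)
  p <- daily_profile(make_activity(runif(2 * 1440, 0, 30)), 24)
  p2 <- p; p2$mean_ali <- p$mean_ali * 4.5
  expect_equal(relative_amplitude(p2), relative_amplitude(p))
})

test_that("bout scan counts runs, bridges short gaps, respects missing", {
  b <- activity_bouts(c(0, 5, 7, 0, 0, 3, 0))
  expect_equal(sum(b$count), 2)
  expect_equal(b$count[b$bout_class == "2"], 1)
  expect_equal(b$count[b$bout_class == "1"], 1)

  expect_equal(sum(activity_bouts(rep(0, 100))$count), 0)

  b <- activity_bouts(c(5, 0, 5), max_gap_bins = 1)
  expect_equal(b$count[b$bout_class == "3"], 1)
  expect_equal(sum(b$count), 1)

  # missing always breaks a bout, even within the gap allowance
  b <- activity_bouts(c(5, NA, 5), max_gap_bins = 1)
  expect_equal(b$count[b$bout_class == "1"], 2)

  long <- activity_bouts(c(rep(2, 15)))
  expect_equal(long$count[long$bout_class == "8+"], 1)
})

test_that("light-phase activity fraction matches square-wave cases", {
  sch <- make_ld_schedule(2)
  expect_equal(light_phase_activity(make_square_day(2), sch), 0)

  cst <- make_activity(rep(5, 2 * 1440))
  expect_equal(light_phase_activity(cst, sch), 0.5)

  mixed <- make_square_day(2, low = 1, high = 3)
  expect_equal(light_phase_activity(mixed, sch), 12 / 48)

  expect_warning(
    v <- light_phase_activity(cst, schedule_constant(T0, 2, "dark")),
    "undefined"
  )
  expect_true(is.na(v))
})

test_that("total activity rescales welfare-check gaps instead of deflating", {
  cst <- make_activity(rep(2, 1440))
  expect_equal(total_activity(cst)$total, 2880)

  gap <- cst; gap$ali[100:104] <- NA
  expect_equal(total_activity(gap)$total, 2880)

  expect_equal(total_activity(make_activity(rep(0, 1440)))$total, 0)
})
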