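test_that("the default protocol reproduces the screen structure", {
  prot <- screen_protocol()
  expect_equal(prot$phases$phase,
               c("LD_BASELINE", "JETLAG_LD", "DD", "LD_REENTRAIN", "LP",
                 "DD_POST_LP", "LL"))
  expect_equal(sum(prot$phases$days), 62)
  # the 6-h advance shortens exactly one day to 18 h
  expect_equal(sum(prot$days$day_len_h == 18), 1)
  expect_equal(sum(prot$days$day_len_h), 62 * 24 - 6)
  # light pulse sits at ZT14-16 of the LP day
  lp_day <- prot$days[!is.na(prot$days$lp_zt), ]
  expect_equal(as.numeric(difftime(prot$lp_time, lp_day$day_start,
                                   units = "hours")), 14)
  expect_equal(light_state(prot$schedule, prot$lp_time + 3600), "light")
  expect_equal(light_state(prot$schedule, prot$lp_time + 2.5 * 3600), "dark")
})

test_that("same seed gives identical traces; different seeds differ", {
  prot <- ld_dd_protocol(ld_days = 2, dd_days = 2)
  a <- simulate_animal(animal_params(), prot, seed = 9)$activity
  b <- simulate_animal(animal_params(), prot, seed = 9)$activity
  expect_identical(a, b)
  c <- simulate_animal(animal_params(), prot, seed = 10)$activity
  expect_false(identical(a$ali, c$ali))
})

test_that("degenerate parameters give an all-zero trace", {
  prot <- ld_dd_protocol(ld_days = 2, dd_days = 1)
  sim <- simulate_animal(animal_params(amp = 0, baseline = 0), prot, seed = 1,
                         check_time_h = NA)
  expect_true(all(sim$activity$ali == 0))
})

test_that("noiseless entrained activity starts at dark onset with a 24-h peak", {
  p <- animal_params(noise_shape = Inf, zero_inflation = 0)
  sim <- simulate_animal(p, ld_dd_protocol(ld_days = 7, dd_days = 1), seed = 1,
                         check_time_h = NA)
  ld <- dplyr::filter(sim$activity, time < T0 + 7 * 86400)
  ons <- detect_onsets(running_average(ld, 30))
  expect_true(all(abs(ons$onset_h - 19) <= 5 / 60))
  pg <- chi_square_periodogram(rebin(ld, 360))
  expect_equal(pg$peak_period_h, 24)
})

test_that("welfare-check gaps appear as one daily missing window", {
  prot <- ld_dd_protocol(ld_days = 3, dd_days = 0)
  sim <- simulate_animal(animal_params(), prot, seed = 2)
  gaps <- sim$activity |>
    dplyr::filter(is.na(ali)) |>
    dplyr::mutate(d = as.Date(time))
  expect_equal(unname(table(gaps$d)), rep(5L, 3), ignore_attr = TRUE)
  expect_true(all(format(gaps$time, "%H") == "09"))
})

test_that("cohorts are reproducible with per-animal ground truth", {
  prot <- ld_dd_protocol(ld_days = 1, dd_days = 1)
  co <- simulate_cohort(n = 12, protocol = prot, seed = 3)
  expect_equal(dplyr::n_distinct(co$activity$animal_id), 12)
  expect_equal(nrow(co$truth), 12 * 2)
  expect_equal(unique(co$truth$true_period_h[co$truth$phase == "LD_BASELINE"]),
               24)
  co2 <- simulate_cohort(n = 12, protocol = prot, seed = 3)
  expect_identical(co$activity, co2$activity)

  nojit <- simulate_cohort(n = 4, protocol = prot, seed = 3,
                           tau_jitter_sd = 0, amp_jitter_sd = 0)
  expect_equal(unique(nojit$truth$true_period_h[nojit$truth$phase == "DD"]),
               23.5)
})

test_that("arrhythmic animals are dark-active with anticipatory lead in LD", {
  p <- animal_params(arrhythmic = TRUE, mask_light = 0.5, noise_shape = Inf,
                     zero_inflation = 0, arrhythmic_on_prob = 1)
  sim <- simulate_animal(p, ld_dd_protocol(ld_days = 2, dd_days = 1), seed = 1,
                         check_time_h = NA)
  a <- sim$activity
  # anticipation: active (masked) during the hour before dark onset
  lead <- dplyr::filter(a, time >= T0 + 11 * 3600, time < T0 + 12 * 3600)
  expect_true(all(lead$ali > 5))
  # mid light phase: baseline only
  mid <- dplyr::filter(a, time >= T0 + 5 * 3600, time < T0 + 6 * 3600)
  expect_true(all(mid$ali < 1))
  # DD: constant expected activity, no periodic component
  dd <- dplyr::filter(a, time >= T0 + 2 * 86400)
  expect_equal(unique(dd$ali), 21)
})
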