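test_that("phase angles follow the arithmetic rule and its periodicity", {
  cfg <- lunar_config()
  expect_equal(lunar_phase_angle(cfg$epoch, cfg), 0)
  expect_equal(lunar_phase_angle(cfg$epoch + cfg$synodic_period * 86400, cfg),
               0, tolerance = 1e-6)
  half <- cfg$epoch + 14.765 * 86400
  expect_lt(abs(lunar_phase_angle(half, cfg) - 180), 0.01)
  # shifting by one synodic period leaves any date's phase unchanged
  d <- as.POSIXct("1987-03-21 00:00:00", tz = "UTC")
  a1 <- lunar_phase_angle(d, cfg)
  a2 <- lunar_phase_angle(d + cfg$synodic_period * 86400, cfg)
  expect_lt(abs(((a1 - a2 + 180) %% 360) - 180), 0.001)
  expect_error(lunar_config(synodic_period = -1), "synodic_period")
  expect_error(lunar_config(n_bins = 4), "8 bins")
})

test_that("phase bins are 45 degrees wide and centered on the principal phases", {
  expect_equal(as.character(phase_bin(0)), "new")
  expect_equal(as.character(phase_bin(180)), "full")
  expect_equal(as.character(phase_bin(22.4)), "new")
  expect_equal(as.character(phase_bin(22.6)), "waxing_crescent")
  expect_equal(as.character(phase_bin(337.5)), "new")
  expect_equal(as.character(phase_bin(337.4)), "waning_crescent")
  expect_error(phase_bin(360), "\\[0, 360\\)")
  expect_error(phase_bin(-1), "\\[0, 360\\)")
})

test_that("onset counts are conserved and match per-cycle binning", {
  co <- generate_cohort(10, simulation_params(mu = 29, sigma = 3,
                                              n_cycles = 7), seed = 3)
  tab <- count_onsets_by_phase(co)
  expect_equal(attr(tab, "total"), 70)
  expect_equal(sum(tab), 70)
  # brute-force loop over every single onset
  brute <- integer(8)
  for (s in co$series)
    for (d in as.list(onset_dates(s))) {
      b <- as.integer(phase_bin(lunar_phase_angle(d)))
      brute[b] <- brute[b] + 1L
    }
  expect_equal(as.integer(tab), brute)
})

test_that("onsets at multiples of the synodic period all land in the new bin", {
  cfg <- lunar_config()
  epoch_date <- as.Date("2000-01-06")
  starts <- epoch_date + round((0:9) * cfg$synodic_period)
  co <- cohort(lapply(1:10, function(i)
    cycle_series(paste0("w", i), starts[i], 28)))
  tab <- count_onsets_by_phase(co, cfg)
  expect_equal(as.integer(tab), c(10L, rep(0L, 7)))
})

test_that("chi-square uniformity reproduces the published cohort p-values", {
  eu <- chi_square_uniformity(table3_counts(1))
  expect_equal(eu$p_value, 0.0214, tolerance = 0.0005 / 0.0214)
  na <- chi_square_uniformity(table3_counts(2))
  expect_equal(na$p_value, 0.0952, tolerance = 0.0005 / 0.0952)
  flat <- chi_square_uniformity(phase_count_table(rep(1000L, 8)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi_square_uniformity(phase_count_table(rep(0L, 8))),
               "empty")
})

test_that("the grouped Rayleigh test reproduces the published cohort p-values", {
  eu <- rayleigh_grouped(table3_counts(1))
  expect_equal(eu$p_value, 0.0056, tolerance = 0.0005 / 0.0056)
  na <- rayleigh_grouped(table3_counts(2))
  expect_equal(na$p_value, 0.0226, tolerance = 0.0005 / 0.0226)
  flat <- rayleigh_grouped(phase_count_table(rep(1000L, 8)))
  expect_equal(flat$r_bar, 0)
  expect_equal(flat$p_value, 1)
  # all mass in one bin: maximal resultant
  onebin <- rayleigh_grouped(phase_count_table(c(50L, rep(0L, 7))))
  expect_equal(onebin$r_bar, 1)
  expect_equal(onebin$statistic, 50)
})

test_that("chi-square is rotation-invariant; Rayleigh Z rotates its direction only", {
  counts <- as.integer(table3_counts(1))
  rot <- phase_count_table(c(counts[4:8], counts[1:3]))
  orig <- phase_count_table(counts)
  expect_equal(chi_square_uniformity(rot)$statistic,
               chi_square_uniformity(orig)$statistic)
  r1 <- rayleigh_grouped(orig); r2 <- rayleigh_grouped(rot)
  expect_equal(r1$statistic, r2$statistic)
  d <- abs(r2$mean_direction - r1$mean_direction) %% 360
  expect_equal(min(d, 360 - d), 3 * 45, tolerance = 1e-6)
})

test_that("per-woman circular means follow vector-sum arithmetic", {
  # a 4-day 'synodic' config makes consecutive days 90 degrees apart
  cfg <- midnight_config(4)
  base <- as.Date("2000-01-06")
  # single onset one day after the reference: 90 degrees
  one <- cycle_series("a", base + 1, 28)
  expect_equal(circular_mean_per_woman(one, cfg), 90)
  # onsets at 0 and 90 degrees: mean 45
  two <- cycle_series("b", base, c(1, 28))
  expect_equal(circular_mean_per_woman(two, cfg), 45)
  # antipodal onsets (0 and 180 degrees): undefined
  cfg2 <- midnight_config(2)
  anti <- circular_mean_per_woman(cycle_series("c", base, c(1, 28)), cfg2)
  expect_true(is.na(anti))
  expect_true(attr(anti, "undefined"))
})

test_that("the per-woman Rayleigh test uses means and excludes undefined women", {
  base <- as.Date("2000-01-06")
  same <- cohort(lapply(1:20, function(i)
    cycle_series(paste0("w", i), base, 28)))
  r <- rayleigh_per_woman(same)
  expect_equal(r$statistic, 20, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-6)
  # an undefined-mean woman is dropped and counted
  cfg2 <- midnight_config(2)
  mix <- cohort(c(lapply(1:3, function(i)
    cycle_series(paste0("w", i), base, c(2, 2))),
    list(cycle_series("anti", base, c(1, 28)))))
  r2 <- rayleigh_per_woman(mix, cfg2)
  expect_equal(r2$n, 3)
  expect_equal(r2$n_excluded, 1)
  expect_error(rayleigh_per_woman(cohort(list(
    cycle_series("anti", base, c(1, 28)))), cfg2), "fewer than 2")
})

test_that("uniform per-woman mean angles give a null Rayleigh p", {
  co <- generate_cohort(200, simulation_params(mu = 28, sigma = 2,
                                               n_cycles = 3), seed = 12)
  r <- rayleigh_per_woman(co)
  expect_gt(r$p_value, 0.001)
})

test_that("the shift test is seed-reproducible and conserves counts", {
  co <- generate_cohort(30, simulation_params(mu = 29, sigma = 2,
                                              n_cycles = 8), seed = 5)
  s1 <- monte_carlo_shift_test(co, n_iter = 300, seed = 11)
  s2 <- monte_carlo_shift_test(co, n_iter = 300, seed = 11)
  expect_identical(s1$ranks, s2$ranks)
  expect_identical(s1$null_counts, s2$null_counts)
  # every replicate redistributes exactly the observed number of onsets
  expect_true(all(rowSums(s1$null_counts) == attr(s1$observed, "total")))
  expect_true(all(s1$ranks > 0 & s1$ranks < 1))
  expect_warning(monte_carlo_shift_test(co, n_iter = 50, seed = 1),
                 "coarse")
})

test_that("a strongly new-moon-coupled cohort drives the new-moon rank up", {
  p <- simulation_params(mu = 29.5, sigma = 1, n_cycles = 15,
                         lunar_kappa = 2, lunar_mu = 0)
  co <- generate_cohort(200, p, seed = 23)
  st <- monte_carlo_shift_test(co, n_iter = 500, seed = 24)
  expect_gt(st$ranks["new"], 0.975)
  expect_true(st$significant["new"])
})

test_that("circular smoothing conserves mass and tracks the mode", {
  flat <- circular_smooth(phase_count_table(rep(500L, 8)))
  expect_lt(diff(range(flat$density)) / mean(flat$density), 0.01)
  expect_equal(sum(flat$density) * 1, 4000)
  peaked <- phase_count_table(c(10L, 300L, 30L, 10L, 5L, 5L, 5L, 10L))
  sm <- circular_smooth(peaked)
  expect_equal(sum(sm$density), 375)
  mode_angle <- sm$angle[which.max(sm$density)]
  expect_lt(min(abs(mode_angle - 45), 360 - abs(mode_angle - 45)), 45)
})
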