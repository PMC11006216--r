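test_that("offsets are the cumulative deviation from the mean period", {
  a <- build_actogram(cycle_series("w", "2000-01-01", c(28, 30, 26, 28)))
  expect_equal(a$reference_period, 28)
  expect_equal(a$offsets, c(0, 2, 0, 0))
  expect_error(build_actogram(cycle_series("w", "2000-01-01", 28)),
               "at least 2")
})

test_that("the final offset is zero for any series", {
  for (seed in 1:10) {
    s <- generate_series(simulation_params(mu = 28, sigma = 3, ar1 = 0.3,
                                           jump_prob = 0.05,
                                           n_cycles = 20 + seed,
                                           seed = seed))
    a <- build_actogram(s)
    expect_equal(a$offsets[length(a$offsets)], 0, tolerance = 1e-10)
  }
})

test_that("trend + band + residual reconstructs the offsets exactly", {
  s <- generate_series(simulation_params(mu = 28, sigma = 2,
                                         osc_amplitude = 2, osc_period = 6,
                                         n_cycles = 40, seed = 3))
  a <- build_actogram(s)
  expect_equal(a$trend + a$band + a$residual, a$offsets, tolerance = 1e-10)
})

test_that("a constant series gives zero offsets, constant trend, zero band", {
  a <- build_actogram(constant_series(n = 24))
  expect_equal(a$offsets, rep(0, 24))
  expect_equal(a$trend, rep(0, 24), tolerance = 1e-12)
  expect_equal(a$band, rep(0, 24), tolerance = 1e-12)
  expect_equal(nrow(detect_wavelets(a)), 0)
})

test_that("the kernel smoother preserves constants and interior lines", {
  expect_equal(long_trend(rep(4.2, 15)), rep(4.2, 15))
  expect_error(long_trend(rep(0, 11), window = 12), "shorter")
  line <- 0.5 * (1:60) - 3
  sm <- long_trend(line)
  # interior points see an effectively symmetric kernel; residual boundary
  # leakage through the Gaussian tails stays below 1e-3
  expect_lt(max(abs(sm[20:41] - line[20:41])), 1e-3)
  # high-frequency oscillation is attenuated, the slow trend kept
  slow <- 10 * sin(2 * pi * (1:60) / 60)
  fast <- 3 * sin(2 * pi * (1:60) / 4)
  sm2 <- long_trend(slow + fast)
  expect_gt(cor(sm2, slow), 0.95)
})

test_that("the band-pass filter has unit pass-band and attenuated stop-band gain", {
  expect_equal(bandpass_cf(rep(7, 30), 3, 12), rep(0, 30), tolerance = 1e-12)
  expect_error(bandpass_cf(1:30, 12, 3), "min_period")
  expect_error(bandpass_cf(1:30, 1, 12), "min_period")
  i <- 1:60
  in_band <- 2.5 * sin(2 * pi * i / 6)
  out6 <- bandpass_cf(in_band, 3, 12)
  interior <- 10:51
  expect_lt(max(abs(out6[interior] - in_band[interior])), 0.2 * 2.5)
  stop_band <- 2 * cos(pi * i) # alternation: the 2-cycle period floor
  out2 <- bandpass_cf(stop_band, 3, 12)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(out2), 0.25 * rms(stop_band))
})

test_that("the band-pass filter is linear", {
  set.seed(42)
  x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
  expect_equal(bandpass_cf(2 * x - 5 * y, 3, 12),
               2 * bandpass_cf(x, 3, 12) - 5 * bandpass_cf(y, 3, 12),
               tolerance = 1e-10)
})

test_that("wavelets pair opposite-sign runs and respect the duration floor", {
  expect_equal(nrow(detect_wavelets(rep(0, 30))), 0)
  # two full oscillations of period 6 built by hand
  band <- rep(c(1, 2, 1, -1, -2, -1), 2)
  w <- detect_wavelets(band, min_duration = 4)
  expect_equal(w$start_index, c(1L, 7L))
  expect_equal(w$end_index, c(6L, 12L))
  expect_equal(w$duration, c(6L, 6L))
  expect_equal(w$amplitude, c(2, 2))
  # a 3-cycle candidate (2 up, 1 down) is excluded
  expect_equal(nrow(detect_wavelets(c(0, 1, 1, -1, 0, 0), min_duration = 4)),
               0)
  # an unpaired terminal run is dropped
  w2 <- detect_wavelets(c(1, 1, -1, -1, 1, 1, 1), min_duration = 4)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$end_index, 4L)
})

test_that("raising min_duration never yields more wavelets", {
  s <- generate_series(simulation_params(mu = 28, sigma = 2,
                                         osc_amplitude = 3, osc_period = 7,
                                         n_cycles = 50, seed = 13))
  a <- build_actogram(s)
  counts <- vapply(3:8, function(d) nrow(detect_wavelets(a, d)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a noiseless period-6 sinusoid is recovered as 6-cycle wavelets of its amplitude", {
  s <- generate_series(simulation_params(mu = 28, sigma = 0,
                                         osc_amplitude = 3, osc_period = 6,
                                         n_cycles = 60, seed = 7))
  a <- build_actogram(s)
  w <- detect_wavelets(a)
  interior <- w[w$start_index > 6 & w$end_index < 55, ]
  expect_gt(nrow(interior), 4)
  expect_true(all(abs(interior$duration - 6) <= 1))
  expect_true(all(abs(interior$amplitude - 3) <= 0.75))
})

test_that("wavelet contexts partition: jump, fluctuation, stable", {
  # an abrupt +10 d cycle followed by an oscillation -> after_jump
  lengths <- c(rep(28, 10), 38, 31, 30, 29, 26, 25, 26, rep(28, 13))
  a <- build_actogram(cycle_series("j", "2000-01-01", lengths))
  w <- classify_wavelets(detect_wavelets(a), a, jump_threshold = 5)
  expect_gt(nrow(w), 0)
  covers <- w$start_index <= 13 & w$end_index >= 12
  expect_true(any(w$context[covers] == "after_jump"))
  # a pure sinusoid has no jumps and no excess residual -> stable
  s <- generate_series(simulation_params(mu = 28, sigma = 0,
                                         osc_amplitude = 3, osc_period = 6,
                                         n_cycles = 60, seed = 7))
  a2 <- build_actogram(s)
  w2 <- classify_wavelets(detect_wavelets(a2), a2)
  expect_true(all(w2$context == "stable"))
  # every wavelet gets exactly one of the three labels
  s3 <- generate_series(simulation_params(mu = 28, sigma = 3, ar1 = 0.3,
                                          jump_prob = 0.08, n_cycles = 60,
                                          seed = 19))
  a3 <- build_actogram(s3)
  w3 <- classify_wavelets(detect_wavelets(a3), a3)
  expect_true(all(w3$context %in% c("stable", "after_jump",
                                    "with_fluctuations")))
})

test_that("large-amplitude flagging is inclusive at the threshold", {
  w <- data.frame(start_index = 1:3, end_index = 4:6, duration = rep(4L, 3),
                  amplitude = c(2.9, 3.0, 4.1), context = "stable")
  out <- flag_large_amplitude(w)
  expect_equal(out$count, 2)
  expect_equal(out$wavelets$large_amp, c(FALSE, TRUE, TRUE))
  expect_equal(out$count, sum(w$amplitude >= 3)) # brute-force scan
  empty <- flag_large_amplitude(w[0, ])
  expect_equal(empty$count, 0)
})

test_that("the raster export has one row per cycle at the wrapped onset position", {
  lens <- c(rep(28, 10), 38, rep(28, 9))
  s <- cycle_series("w", "2000-01-01", lens)
  a <- build_actogram(s)
  png_file <- tempfile(fileext = ".png")
  grid <- render_actogram(a, file = png_file, width = 56)
  expect_length(grid, 20)
  expect_true(file.exists(png_file))
  col <- unname(vapply(grid, function(r) regexpr("*", r, fixed = TRUE)[1],
                       integer(1)))
  # manual oracle: onset offset of cycle i is sum_{j<i}(len_j - mean),
  # wrapped modulo the reference period and scaled to the grid width
  ref <- mean(lens)
  pos <- cumsum(c(0, lens[-20] - ref)) %% ref
  expect_equal(col,
               unname(pmin(pmax(1, 1 + round(pos / ref * 55)), 56)))
  # the +10 d cycle displaces the next onset right by 38 - ref days
  expect_equal((pos[12] - pos[11]) %% ref, 38 - ref)
  # constant series: all onsets vertically aligned
  grDevices::pdf(tempfile(fileext = ".pdf"))
  on.exit(grDevices::dev.off())
  g2 <- render_actogram(build_actogram(constant_series(n = 8)))
  expect_length(unique(vapply(g2, function(r)
    regexpr("*", r, fixed = TRUE)[1], integer(1))), 1)
})

test_that("cohort wavelet statistics only use series of 18+ cycles", {
  co <- cohort(list(
    generate_series(simulation_params(mu = 28, sigma = 0, osc_amplitude = 3,
                                      osc_period = 6, n_cycles = 30,
                                      seed = 2), woman_id = "long"),
    generate_series(simulation_params(mu = 28, sigma = 0, osc_amplitude = 3,
                                      osc_period = 6, n_cycles = 12,
                                      seed = 3), woman_id = "short")))
  res <- cohort_wavelets(co)
  expect_equal(res$n_women, 1)
  expect_true(all(res$wavelets$woman_id == "long"))
  expect_equal(res$summary$n_wavelets, nrow(res$wavelets))
  expect_equal(res$summary$mean_per_woman, nrow(res$wavelets))
})
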