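test_that("rendered beats are recovered exactly with small timing error", {
  for (s in 1:3) {
    nn <- simulate_rr_series(c(70, 95, 110)[s], 45, 28, duration = 120,
                             seed = s)
    e <- render_ecg(nn, fs = 500)
    r <- detect_r_peaks(e$ecg, 500)
    expect_equal(length(r), length(e$r_times))
    expect_lte(median(abs(r - e$r_times)) * 1000, 10)
    set.seed(s)
    pat <- pmin(pmax(270 + stats::rnorm(length(nn), 0, 3), 50), 600)
    p <- render_pulse(nn, pat, fs = 500)
    f <- detect_pulse_feet(p$pulse, 500)
    expect_equal(length(f), length(p$foot_times))
    expect_lte(median(abs(as.numeric(f) - p$foot_times)) * 1000, 5)
    m <- match_beats(e$r_times, as.numeric(f))
    expect_lte(max(abs(m - pat), na.rm = TRUE), 5)
  }
})

test_that("detection is invariant to uniform gain and handles flat input", {
  nn <- simulate_rr_series(80, 40, 25, duration = 60, seed = 4)
  e <- render_ecg(nn, fs = 500)
  expect_identical(detect_r_peaks(e$ecg, 500),
                   detect_r_peaks(e$ecg * 10, 500))
  expect_identical(detect_r_peaks(e$ecg, 500),
                   detect_r_peaks(e$ecg * 0.1, 500))
  expect_length(detect_r_peaks(rep(0, 2000), 500), 0)
  expect_length(detect_r_peaks(rep(3.7, 2000), 500), 0)
  expect_error(detect_r_peaks(rep(0, 100), 500), "2 s")
  expect_error(detect_r_peaks(rep(0, 5000), 100), "250")
  p <- render_pulse(nn, rep(270, length(nn)), fs = 500)
  expect_equal(as.numeric(detect_pulse_feet(p$pulse * 5, 500)),
               as.numeric(detect_pulse_feet(p$pulse, 500)))
  expect_length(detect_pulse_feet(rep(0, 2000), 500), 0)
})

test_that("detected event times are strictly increasing", {
  nn <- simulate_rr_series(100, 50, 32, duration = 180, seed = 9)
  e <- render_ecg(nn, fs = 500)
  r <- detect_r_peaks(e$ecg, 500)
  expect_true(all(diff(r) > 0))
  p <- render_pulse(nn, rep(250, length(nn)), fs = 500)
  f <- detect_pulse_feet(p$pulse, 500)
  expect_true(all(diff(as.numeric(f)) > 0))
})

test_that("alternative foot fiducials stay within a bounded offset", {
  nn <- rep(800, 30)
  p <- render_pulse(nn, rep(270, 30), fs = 1000)
  f_tan <- as.numeric(detect_pulse_feet(p$pulse, 1000))
  f_slope <- as.numeric(detect_pulse_feet(p$pulse, 1000,
                                          method = "max_slope"))
  f_frac <- as.numeric(detect_pulse_feet(p$pulse, 1000,
                                         method = "fractional_threshold"))
  expect_equal(length(f_slope), length(f_tan))
  expect_lte(max(abs(f_slope - f_tan)) * 1000, 20)
  expect_lte(max(abs(f_frac - f_tan)) * 1000, 20)
})

test_that("beat matching applies lag bounds and ignores input order noise", {
  expect_equal(match_beats(c(1, 2), c(1.27, 2.27)), c(270, 270))
  # lag outside the default bounds leaves the beat unmatched
  expect_true(is.na(match_beats(1, 1.6)))
  expect_true(is.na(match_beats(1, 1.05)))
  # feet belong to the beat preceding them, never to an earlier beat
  expect_equal(match_beats(c(1, 2), c(2.27)), c(NA, 270))
  # sorted inputs produced from shuffled data give identical output
  r <- sort(c(3, 1, 2)); f <- sort(c(3.25, 1.25, 2.25))
  expect_equal(match_beats(r, f), c(250, 250, 250))
  expect_error(match_beats(c(2, 1), c(1.2)), "sorted")
})

test_that("NN cleaning rejects by absolute and relative rules and logs", {
  cl <- clean_nn_intervals(c(800, 810, 250, 805))
  expect_equal(cl$accepted, c(800, 810, 805))
  expect_equal(cl$rejections$index, 3)
  expect_equal(cl$rejections$rule, "absolute_bound")
  # clean series untouched
  clean <- seq(780, 820, length.out = 20)
  expect_equal(clean_nn_intervals(clean)$accepted, clean)
  # one 60% spike rejected by the relative-median rule
  nn <- c(rep(800, 6), 1280, rep(800, 6))
  cl2 <- clean_nn_intervals(nn)
  expect_equal(cl2$rejections$value, 1280)
  expect_equal(cl2$rejections$rule, "relative_median")
  expect_equal(length(cl2$accepted), 12)
})
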