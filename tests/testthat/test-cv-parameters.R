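test_that("HR, SDNN and RMSSD match their defining formulas", {
  expect_equal(compute_hr(rep(1000, 10)), 60)
  expect_equal(compute_hr(rep(600, 5)), 100)
  expect_equal(compute_hr(c(800, 1000)), 60000 / 900)
  expect_equal(compute_sdnn(rep(700, 20)), 0)
  expect_equal(compute_sdnn(c(800, 820, 780, 800)), sqrt(800 / 3))
  expect_equal(compute_rmssd(rep(900, 5)), 0)
  expect_equal(compute_rmssd(c(800, 810, 790)), sqrt((100 + 400) / 2))
  expect_equal(compute_rmssd(c(800, 850)), 50)
})

test_that("degenerate NN inputs are rejected", {
  expect_error(compute_hr(numeric(0)), "empty")
  expect_error(compute_sdnn(1000), "at least 2")
  expect_error(compute_rmssd(1000), "at least 2")
})

test_that("SDNN/RMSSD are translation-invariant and homogeneous", {
  set.seed(42)
  for (i in 1:20) {
    nn <- stats::runif(sample(3:40, 1), 500, 1200)
    expect_equal(compute_sdnn(nn + 250), compute_sdnn(nn))
    expect_equal(compute_rmssd(nn + 250), compute_rmssd(nn))
    expect_equal(compute_sdnn(nn * 2), 2 * compute_sdnn(nn))
    expect_equal(compute_rmssd(nn * 2), 2 * compute_rmssd(nn))
  }
})

test_that("measures agree with direct-formula oracles on random inputs", {
  set.seed(7)
  for (i in 1:1000) {
    nn <- stats::runif(sample(2:30, 1), 300, 2000)
    expect_equal(compute_hr(nn), 60000 / (sum(nn) / length(nn)))
    m <- sum(nn) / length(nn)
    expect_equal(compute_sdnn(nn),
                 sqrt(sum((nn - m)^2) / (length(nn) - 1)))
    d <- nn[-1] - nn[-length(nn)]
    expect_equal(compute_rmssd(nn), sqrt(sum(d^2) / length(d)))
  }
})

test_that("PAT normalization follows the 1 ms/mmHg rule and inverts", {
  expect_equal(normalize_pat(270, 120), 270)
  expect_equal(normalize_pat(260, 130), 270)
  expect_equal(normalize_pat(280, 110), 270)
  # invertibility
  set.seed(1)
  pat <- stats::runif(50, 150, 400)
  sbp <- stats::runif(50, 95, 180)
  norm <- normalize_pat(pat, sbp)
  expect_equal(norm - (sbp - 120), pat)
  expect_error(normalize_pat(270, 300), "bounds")
  expect_error(normalize_pat(-5, 120), "positive")
})

test_that("phase summaries reproduce constructed values and flag thin data", {
  sched <- build_schedule()
  ann <- make_constant_beats(nn_ms = 600, pat_ms = 270)
  m <- summarize_phase(ann, sched[1, ], sbp = 120)
  expect_equal(m$hr, 100)
  expect_equal(m$sdnn, 0)
  expect_equal(m$rmssd, 0)
  expect_equal(m$pat_norm, 270)
  # sbp above reference lengthens normalized PAT
  m2 <- summarize_phase(ann, sched[1, ], sbp = 130)
  expect_equal(m2$pat_norm, 280)
  # too few beats in the window -> flagged missing
  sparse <- make_constant_beats(nn_ms = 30000, duration = 1740)
  msp <- summarize_phase(sparse, sched[1, ], sbp = 120)
  expect_true(is.na(msp$hr) && is.na(msp$sdnn))
})

test_that("cycling HR averages instantaneous rates over cycling phases", {
  sched <- build_schedule()
  ann <- make_constant_beats(nn_ms = 500)
  expect_equal(cycling_hr(ann, sched), 120)
  # hand oracle on six beats across two phases
  r <- c(301, 302, 303, 781, 782, 783)     # in cycling_60w and cycling_90w
  ann2 <- structure(list(r_times = r, nn = rep(1000, 5), nn_times = r[-1],
                         foot_times = numeric(0), pat = rep(NA_real_, 6)),
                    class = "beat_annotations")
  expect_equal(cycling_hr(ann2, sched), 60)
  empty <- structure(list(r_times = numeric(0), nn = numeric(0),
                          nn_times = numeric(0), foot_times = numeric(0),
                          pat = numeric(0)), class = "beat_annotations")
  expect_true(is.na(cycling_hr(empty, sched)))
})
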