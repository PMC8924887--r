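test_that("the RR generator hits its mean-rate and variability targets", {
  nn <- simulate_rr_series(60, 0, 0, duration = 300, seed = 1)
  expect_true(all(nn == nn[1]))
  expect_equal(compute_sdnn(nn), 0)
  expect_true(mean(nn) >= 980 && mean(nn) <= 1020)

  # recovery across seeds at study-like settings
  sdnn_hat <- rmssd_hat <- hr_hat <- numeric(20)
  for (s in 1:20) {
    nn <- simulate_rr_series(98.5, 50, 30, duration = 600, seed = s)
    sdnn_hat[s] <- compute_sdnn(nn)
    rmssd_hat[s] <- compute_rmssd(nn)
    hr_hat[s] <- compute_hr(nn)
  }
  expect_true(all(sdnn_hat >= 45 & sdnn_hat <= 55))
  expect_true(all(abs(rmssd_hat - 30) <= 3))
  expect_true(all(abs(hr_hat - 98.5) / 98.5 <= 0.02))
})

test_that("the RR generator is seed-deterministic and validates inputs", {
  a <- simulate_rr_series(75, 40, 25, duration = 120, seed = 99)
  b <- simulate_rr_series(75, 40, 25, duration = 120, seed = 99)
  expect_identical(a, b)
  expect_error(simulate_rr_series(75, 40, 120, duration = 60, seed = 1),
               "infeasible")
  expect_error(simulate_rr_series(20, 40, 25, duration = 60, seed = 1),
               "mean_hr")
  expect_error(simulate_rr_series(75, 40, 25, duration = 0, seed = 1),
               "duration")
})

test_that("rendered ECG places R-peaks exactly at cumulative NN times", {
  e <- render_ecg(rep(1000, 10), fs = 1000)
  expect_equal(length(e$r_times), 10)
  # local maxima above half the QRS amplitude
  sig <- e$ecg
  pk <- which(diff(sign(diff(sig))) < 0) + 1L
  pk <- pk[sig[pk] > 0.5]
  expect_equal(length(pk), 10)
  expect_equal(diff(pk), rep(1000, 9), tolerance = 1e-8)
  expect_error(render_ecg(numeric(0)), "at least one")
  expect_error(render_ecg(rep(1000, 5), fs = 100), "250")
})

test_that("rendered pulse feet lag R-peaks by exactly the given PAT", {
  nn <- rep(800, 12)
  p <- render_pulse(nn, rep(270, 12), fs = 500)
  expect_equal(p$foot_times - p$r_times, rep(0.27, 12))
  expect_error(render_pulse(nn, rep(270, 11), fs = 500), "length")
  expect_error(render_pulse(nn, rep(700, 12), fs = 500), "\\[50, 600\\]")
})

test_that("reference parameters separate the groups and are deterministic", {
  prof <- data.frame(subject_id = "S01", sex = "F")
  a <- simulate_reference_params(prof, "significant", seed = 5)
  b <- simulate_reference_params(prof, "significant", seed = 5)
  expect_identical(a, b)
  expect_true(all(unlist(a[, -1]) > 0))
  ch_sig <- vapply(1:100, function(s)
    attr(simulate_reference_params(prof, "significant", s), "cmj_change"),
    numeric(1))
  ch_mild <- vapply(1:100, function(s)
    attr(simulate_reference_params(prof, "mild", s), "cmj_change"),
    numeric(1))
  expect_lt(mean(ch_sig), mean(ch_mild))
  expect_error(simulate_reference_params(prof, "extreme", 1), "group")
})

test_that("cohort generation is deterministic and enforces its contract", {
  cfg <- cohort_config(n_subjects = 4, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_error(cohort_config(n_subjects = 3), "n_subjects")
  expect_equal(nrow(a$profiles), 4)
  expect_equal(unname(table(a$profiles$sex)["F"]), 2L)
  # bmi consistency
  expect_true(all(abs(a$profiles$bmi -
                        a$profiles$weight / (a$profiles$height / 100)^2)
                  < 0.1))
  # targets strictly positive; PFS resting HR above RS resting HR
  expect_true(all(a$targets$hr > 0 & a$targets$sdnn > 0 &
                    a$targets$pat > 0))
  rs <- a$targets[a$targets$state == "RS" & a$targets$phase_id == "resting", ]
  pfs <- a$targets[a$targets$state == "PFS" &
                     a$targets$phase_id == "resting", ]
  expect_true(all(pfs$hr > rs$hr))
})

test_that("cohort-level state effects have the configured direction and size", {
  ratios <- matrix(NA_real_, 8, 4,
                   dimnames = list(NULL, c("hr", "sdnn", "rmssd", "pat")))
  for (s in 1:8) {
    coh <- simulate_cohort(cohort_config(n_subjects = 16, seed = 100 + s))
    m <- cohort_measures(coh)
    rs <- m[m$state == "RS" & m$phase_id == "resting", ]
    pf <- m[m$state == "PFS" & m$phase_id == "resting", ]
    ratios[s, ] <- c(mean(pf$hr) / mean(rs$hr),
                     mean(pf$sdnn) / mean(rs$sdnn),
                     mean(pf$rmssd) / mean(rs$rmssd),
                     mean(pf$pat_norm) / mean(rs$pat_norm))
  }
  # direction in every cohort
  expect_true(all(ratios[, "hr"] > 1))
  expect_true(all(ratios[, "sdnn"] < 1))
  expect_true(all(ratios[, "rmssd"] < 1))
  # magnitude near the configured cohort effects on average
  expect_equal(mean(ratios[, "hr"]), 1.095, tolerance = 0.02)
  expect_equal(mean(ratios[, "sdnn"]), 0.788, tolerance = 0.08)
  expect_equal(mean(ratios[, "rmssd"]), 0.707, tolerance = 0.08)
  expect_equal(mean(ratios[, "pat"]), 0.980, tolerance = 0.03)
})

test_that("phase measures recover generator targets within tolerance", {
  coh <- simulate_cohort(cohort_config(n_subjects = 4, seed = 11))
  m <- cohort_measures(coh)
  merged <- merge(m, coh$targets,
                  by = c("subject_id", "state", "phase_id"),
                  suffixes = c("", "_target"))
  expect_true(all(abs(merged$sdnn - merged$sdnn_target) /
                    merged$sdnn_target <= 0.10))
  expect_true(all(abs(merged$pat_norm - merged$pat_norm_target) /
                    merged$pat_norm_target <= 0.05))
})
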