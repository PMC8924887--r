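test_that("signal files survive a write/read round trip with inferred fs", {
  rec <- list(time = seq(0, 4, by = 0.002), ecg = sin(1:2001),
              pulse = cos(1:2001))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(rec, path)
  back <- read_signal_csv(path)
  expect_equal(back$ecg, rec$ecg)
  expect_equal(back$pulse, rec$pulse)
  expect_equal(back$fs, 500)
})

test_that("malformed signal files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time_s = c(0, 0.002, 0.001, 0.003),
                   ecg_mv = 1:4, pulse_au = 1:4)
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_signal_csv(path), "non-monotone")
  utils::write.csv(data.frame(time_s = 1:3, ecg_mv = 1:3), path,
                   row.names = FALSE)
  expect_error(read_signal_csv(path), "pulse_au")
  # NaN run longer than 1 s
  n <- 3000
  df2 <- data.frame(time_s = (0:(n - 1)) / 1000,
                    ecg_mv = c(rep(NA, 1500), stats::rnorm(n - 1500)),
                    pulse_au = stats::rnorm(n))
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_signal_csv(path), "missing ecg_mv")
})

test_that("beat annotations export one row per beat", {
  ann <- make_constant_beats(nn_ms = 1000, duration = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_beats_csv(ann, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), length(ann$r_times))
  expect_equal(df$r_time_s, ann$r_times)
  expect_equal(df$nn_ms[-1], ann$nn)
})

test_that("cohort bundles materialize on disk", {
  coh <- simulate_cohort(cohort_config(n_subjects = 4, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("profiles.csv", "groups.csv", "reference.csv", "bp.csv",
      "ground_truth.json")))))
  bp <- utils::read.csv(file.path(dir, "bp.csv"))
  expect_true(all(c("state", "phase_id", "sbp_mmhg", "dbp_mmhg")
                  %in% names(bp)))
  expect_true(all(bp$dbp_mmhg < bp$sbp_mmhg))
})

test_that("the pipeline runs end to end and is reproducible", {
  cfg <- cohort_config(n_subjects = 6, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, d1)
  r2 <- run_pipeline(cfg, d2)
  for (f in c("config.json", "measures.csv", "features.csv",
              "screening.tsv", "model.json", "groups.csv", "report.md")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_s3_class(r1$fit, "fatigue_classifier")
  # every artifact carries the config hash
  scr <- utils::read.delim(file.path(d1, "screening.tsv"))
  expect_true(all(scr$config_hash == r1$config_hash))
  model <- jsonlite::read_json(file.path(d1, "model.json"))
  expect_equal(model$config_hash, r1$config_hash)
  # stage subsetting stops after the requested artifact
  d3 <- withr::local_tempdir()
  r3 <- run_pipeline(cfg, d3, stages = c("simulate", "measure"))
  expect_true(file.exists(file.path(d3, "measures.csv")))
  expect_false(file.exists(file.path(d3, "features.csv")))
})

test_that("the detection-based pipeline matches truth-based measures", {
  cfg <- cohort_config(n_subjects = 4, seed = 13, fs = 250)
  d <- withr::local_tempdir()
  res <- run_pipeline(cfg, d, detect = TRUE,
                      stages = c("simulate", "measure"))
  truth <- cohort_measures(simulate_cohort(cfg))
  m <- res$measures
  merged <- merge(m, truth, by = c("subject_id", "state", "phase_id"),
                  suffixes = c("_det", "_truth"))
  expect_gt(nrow(merged), 0)
  ok <- is.finite(merged$sdnn_det) & is.finite(merged$sdnn_truth)
  expect_true(all(abs(merged$sdnn_det[ok] - merged$sdnn_truth[ok]) /
                    merged$sdnn_truth[ok] <= 0.10))
  ok2 <- is.finite(merged$pat_norm_det) & is.finite(merged$pat_norm_truth)
  expect_true(all(abs(merged$pat_norm_det[ok2] -
                        merged$pat_norm_truth[ok2]) <= 10))
})
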