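# Shared fixture builders (everything is generated in code at test time).

# Minimal two-state measures table for one subject, from named phase values.
make_measures <- function(sdnn_rs = c(60, 40, 40, 40),
                          sdnn_pfs = c(45, 45, 45, 45),
                          pat_rs = c(270, 255, 250, 260),
                          pat_pfs = c(270, 255, 250, 260),
                          hr_rs = c(60, 70, 70, 70),
                          hr_pfs = c(66, 77, 77, 77),
                          rmssd_rs = c(40, 30, 30, 30),
                          rmssd_pfs = c(30, 22, 22, 22)) {
  ph <- c("resting", "recovery_1", "recovery_2", "recovery_3")
  rbind(
    data.frame(state = "RS", phase_id = ph, hr = hr_rs, sdnn = sdnn_rs,
               rmssd = rmssd_rs, pat_norm = pat_rs,
               stringsAsFactors = FALSE),
    data.frame(state = "PFS", phase_id = ph, hr = hr_pfs, sdnn = sdnn_pfs,
               rmssd = rmssd_pfs, pat_norm = pat_pfs,
               stringsAsFactors = FALSE))
}

# Beat annotations implied by a constant heart rate / PAT over a schedule.
make_constant_beats <- function(nn_ms = 600, pat_ms = 270,
                                duration = 1740) {
  r <- seq(nn_ms / 1000, duration, by = nn_ms / 1000)
  structure(list(r_times = r, nn = rep(nn_ms, length(r) - 1L),
                 nn_times = r[-1L], foot_times = r + pat_ms / 1000,
                 pat = rep(pat_ms, length(r)),
                 rejections = data.frame(), n_skipped_feet = 0L),
            class = "beat_annotations")
}

# Brute-force decision-stump oracle: minimum training errors over every
# threshold and polarity.
stump_brute_force_error <- function(values, labels) {
  labels <- as.character(labels)
  thr <- c(-Inf, sort(unique(values)), Inf)
  best <- length(values)
  for (t in thr) {
    for (hi in c("mild", "significant")) {
      lo <- setdiff(c("mild", "significant"), hi)
      pred <- ifelse(values > t, hi, lo)
      best <- min(best, sum(pred != labels))
      pred2 <- rep(hi, length(values))  # degenerate single-leaf stumps
      best <- min(best, sum(pred2 != labels))
    }
  }
  best
}
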