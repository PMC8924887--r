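#' Configuration for a synthetic two-state cohort
#'
#' Bundles every knob of the synthetic-session generator.  Defaults encode
#' the study conditions the package emulates: a 16-subject cohort (8 female,
#' 8 male), a 29-min cycle-ergometer schedule per state, cohort-level
#' rested-to-fatigued multipliers for the cardiovascular measures
#' (HR +9.5%, SDNN -21.2%, RMSSD -29.3%, normalized PAT -2.0%), and
#' between-subject standard deviations matching the emulated cohort tables
#' (HR 10.9 bpm, SDNN 19.7 ms, RMSSD 18.9 ms, PAT 21.6 ms).
#'
#' The two-group fatigue structure is driven by the countermovement-jump
#' (CMJ) height change: significantly fatigued subjects lose markedly more
#' jump height, their resting SDNN is suppressed more (relative to its
#' recovery values) in the fatigued state, and their fatigued-state recovery
#' PAT dips further below the resting value.  Those two mechanisms are what
#' make the SDNN_DIF_N_AVG and PAT_PFS_N_MIN subparameters informative.
#'
#' @param n_subjects Number of subjects (>= 4; leave-one-out screening needs
#'   both classes in every fold).
#' @param sex_ratio Fraction of female subjects (default 0.5).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param state_effects Named list of cohort-mean multiplicative
#'   fatigued/rested shifts for `hr`, `sdnn`, `rmssd`, `pat`.
#' @param group_structure Named list: `significant_fraction`; per-group CMJ
#'   change means (`cmj_change_mild`, `cmj_change_significant`, percent) and
#'   SD (`cmj_change_sd`); group offsets of the fatigued-state
#'   rest-to-recovery ratio for SDNN and RMSSD (`sdnn_rest_delta`,
#'   `rmssd_rest_delta`) with their between-subject SDs (`sdnn_delta_sd`,
#'   `rmssd_delta_sd`); and fatigued-state recovery-PAT dip multipliers
#'   (`pat_rec_mild`, `pat_rec_significant`) with SD `pat_rec_sd`.
#' @param noise_levels Named list of between-subject SDs for `hr`, `sdnn`,
#'   `rmssd`, `pat` (resting-phase values) plus the within-phase beat-level
#'   PAT jitter `pat_beat_sd` (ms) and the per-phase multiplicative jitter
#'   `phase_jitter`.
#' @param schedule_durations_min Phase durations passed to
#'   [build_schedule()].
#' @param fs Sampling rate used when waveforms are rendered, Hz.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 16,
                          sex_ratio = 0.5,
                          seed = 1,
                          state_effects = list(hr = 1.095, sdnn = 0.788,
                                               rmssd = 0.707, pat = 0.980),
                          group_structure = list(
                            significant_fraction = 0.5,
                            cmj_change_mild = -0.6,
                            cmj_change_significant = -5.6,
                            cmj_change_sd = 1.5,
                            sdnn_rest_delta = 0.18,
                            sdnn_delta_sd = 0.03,
                            rmssd_rest_delta = 0.02,
                            rmssd_delta_sd = 0.06,
                            pat_rec_mild = 0.95,
                            pat_rec_significant = 0.84,
                            pat_rec_sd = 0.02),
                          noise_levels = list(hr = 10.9, sdnn = 19.7,
                                              rmssd = 18.9, pat = 21.6,
                                              pat_beat_sd = 3,
                                              phase_jitter = 0.03),
                          schedule_durations_min = c(5, 3, 5, 3, 5, 3, 5),
                          fs = 1000) {
  if (n_subjects < 4) {
    stop("'n_subjects' must be >= 4: leave-one-out screening needs both ",
         "fatigue classes in every training fold")
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop("'sex_ratio' must be in [0, 1]")
  gf <- group_structure$significant_fraction
  if (is.null(gf) || gf < 0 || gf > 1) {
    stop("group_structure$significant_fraction must be in [0, 1]")
  }
  sds <- unlist(noise_levels)
  if (any(sds < 0)) stop("all noise levels must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), sex_ratio = sex_ratio,
                 seed = as.integer(seed), state_effects = state_effects,
                 group_structure = group_structure,
                 noise_levels = noise_levels,
                 schedule_durations_min = schedule_durations_min,
                 fs = fs),
            class = "cohort_config")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  tries <- 0L
  while (any(bad) && tries < 50L) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
    tries <- tries + 1L
  }
  pmin(pmax(x, lo), hi)
}

# Anthropometric distributions by sex (means/SDs of the emulated cohort)
anthro_defaults <- function(sex) {
  if (sex == "F") {
    list(age = c(28.4, 7.0), height = c(169.1, 5.9), weight = c(63.9, 10.5))
  } else {
    list(age = c(28.3, 9.2), height = c(178.6, 7.3), weight = c(75.9, 11.4))
  }
}

#' Simulate per-subject reference parameters
#'
#' Draws rested-state questionnaire score (percent of maximum), reaction
#' time, hand-grip force and CMJ height from sex-specific distributions, and
#' fatigued-state values by applying the cohort-level changes (questionnaire
#' +15 percentage points; reaction time +1.3%; grip -2.9%) plus noise.  The
#' CMJ decrement is group-dependent: the significantly fatigued group's mean
#' decrement is strictly larger than the mild group's.
#'
#' @param profile One-row profile data frame with at least `sex`.
#' @param group `"mild"` or `"significant"`.
#' @param seed Integer seed.
#' @param group_structure As in [cohort_config()].
#' @return A data frame with columns `state`, `q_score`, `rt_ms`, `grip_n`,
#'   `cmj_cm` plus attribute `"cmj_change"` (percent).
#' @export
simulate_reference_params <- function(profile, group, seed,
                                      group_structure =
                                        cohort_config()$group_structure) {
  if (!group %in% c("mild", "significant")) {
    stop("'group' must be \"mild\" or \"significant\"")
  }
  sex <- as.character(profile$sex)
  with_seed(seed, {
    if (sex == "F") {
      q_rs <- rnorm_trunc(1, 12.1, 9.4, 0, 60)
      rt_rs <- rnorm_trunc(1, 206.8, 13.4, 150, 320)
      grip_rs <- rnorm_trunc(1, 294.2, 47.4, 120, 700)
      cmj_rs <- rnorm_trunc(1, 33.1, 3.3, 15, 70)
      q_shift <- 17.9; rt_dif <- 2.4; grip_dif <- -2.7
    } else {
      q_rs <- rnorm_trunc(1, 15.8, 5.3, 0, 60)
      rt_rs <- rnorm_trunc(1, 210.6, 9.4, 150, 320)
      grip_rs <- rnorm_trunc(1, 426.4, 93.8, 120, 700)
      cmj_rs <- rnorm_trunc(1, 43.3, 9.7, 15, 70)
      q_shift <- 12.5; rt_dif <- 0.2; grip_dif <- -3.1
    }
    gs <- group_structure
    cmj_mu <- if (group == "significant") gs$cmj_change_significant
              else gs$cmj_change_mild
    cmj_change <- stats::rnorm(1, cmj_mu, gs$cmj_change_sd)
    q_pfs <- max(0, q_rs + q_shift + stats::rnorm(1, 0, 5))
    rt_pfs <- rt_rs * (1 + rt_dif / 100) * exp(stats::rnorm(1, 0, 0.02))
    grip_pfs <- grip_rs * (1 + grip_dif / 100) * exp(stats::rnorm(1, 0, 0.03))
    cmj_pfs <- cmj_rs * (1 + cmj_change / 100)
    out <- data.frame(
      state = c("RS", "PFS"),
      q_score = c(q_rs, q_pfs),
      rt_ms = c(rt_rs, rt_pfs),
      grip_n = c(grip_rs, grip_pfs),
      cmj_cm = c(cmj_rs, cmj_pfs),
      stringsAsFactors = FALSE)
    attr(out, "cmj_change") <- cmj_change
    out
  })
}

# Draw one subject's fatigue-response profile.  Each HRV measure gets (i) an
# overall state multiplier, centred on the cohort-level effect with wide
# between-subject spread, applied to resting and recovery phases alike, and
# (ii) a rest-to-recovery ratio per state whose fatigued-state mean is
# group-dependent.  PAT gets an overall state shift plus a per-state
# recovery-dip level, with the fatigued-state dip group-dependent.  The
# overall responses are deliberately heterogeneous (subjects recover
# differently) and both states' ratios carry subject noise, so raw
# between-state changes are noisy markers of the fatigue group while the
# fatigued-state recovery-normalized composites carry the group signal.
draw_subject_effects <- function(group, eff, gs) {
  sgn <- if (group == "significant") -1 else 1
  ratio_pair <- function(delta, sd) {
    c(rs = 1 + stats::rnorm(1, 0, 3 * sd),
      pfs = max(0.5, 1 + stats::rnorm(1, sgn * delta, sd)))
  }
  list(
    hr = eff$hr * (1 + stats::rnorm(1, 0, 0.02)),
    sdnn_overall = eff$sdnn * exp(stats::rnorm(1, -0.22^2 / 2, 0.22)),
    sdnn_ratio = ratio_pair(gs$sdnn_rest_delta, gs$sdnn_delta_sd),
    rmssd_overall = eff$rmssd * exp(stats::rnorm(1, -0.18^2 / 2, 0.18)),
    rmssd_ratio = ratio_pair(gs$rmssd_rest_delta, gs$rmssd_delta_sd),
    pat_rest = eff$pat * exp(stats::rnorm(1, -0.10^2 / 2, 0.10)),
    pat_rec = c(rs = stats::rnorm(1, 0.95, 3 * gs$pat_rec_sd),
                pfs = stats::rnorm(1, if (group == "significant")
                  gs$pat_rec_significant else gs$pat_rec_mild,
                  gs$pat_rec_sd)))
}

# Per-phase target trajectories for one subject in one state.
phase_targets <- function(rest, state, subj_eff, jitter_draw) {
  # rest: list(hr, sdnn, rmssd, pat_norm) rested-state resting-phase targets
  ids <- c("resting", "cycling_60w", "recovery_1", "cycling_90w",
           "recovery_2", "cycling_120w", "recovery_3")
  hr_mult   <- c(1.00, 1.35, 1.10, 1.45, 1.12, 1.55, 1.15)
  sdnn_mult <- c(1.00, 0.40, 0.75, 0.35, 0.73, 0.30, 0.71)
  rmssd_mult<- c(1.00, 0.40, 0.70, 0.35, 0.68, 0.30, 0.66)
  pat_mult  <- c(1.00, 0.90, 0.95, 0.88, 0.94, 0.86, 0.93)
  se <- subj_eff
  st <- if (state == "PFS") "pfs" else "rs"
  state_mult <- if (state == "PFS") {
    list(hr = se$hr, sdnn = se$sdnn_overall, rmssd = se$rmssd_overall,
         pat = se$pat_rest)
  } else {
    list(hr = 1, sdnn = 1, rmssd = 1, pat = 1)
  }
  hr0 <- rest$hr * state_mult$hr
  sdnn0 <- rest$sdnn * state_mult$sdnn * se$sdnn_ratio[[st]]
  rmssd0 <- rest$rmssd * state_mult$rmssd * se$rmssd_ratio[[st]]
  pat0 <- rest$pat_norm * state_mult$pat
  # recovery phases sit at the overall level (ratio applies to rest only)
  sdnn_mult[c(3, 5, 7)] <- sdnn_mult[c(3, 5, 7)] / se$sdnn_ratio[[st]]
  rmssd_mult[c(3, 5, 7)] <- rmssd_mult[c(3, 5, 7)] / se$rmssd_ratio[[st]]
  pat_mult[c(3, 5, 7)] <- se$pat_rec[[st]] / 0.95 * c(0.95, 0.94, 0.93)
  jit <- jitter_draw(length(ids))
  out <- data.frame(
    phase_id = ids,
    hr = hr0 * hr_mult * jit$hr,
    sdnn = pmax(5, sdnn0 * sdnn_mult * jit$sdnn),
    rmssd = pmax(4, rmssd0 * rmssd_mult * jit$rmssd),
    pat_norm = pmax(120, pat0 * pat_mult * jit$pat),
    stringsAsFactors = FALSE)
  # keep every phase's target pair attainable by the RR generator:
  # below sqrt(2)*SDNN and above the slow-oscillation floor at this rate
  out$hr <- pmin(pmax(out$hr, 40), 200)
  out$rmssd <- pmin(out$rmssd, 1.3 * out$sdnn)
  floor_rmssd <- 2 * abs(sin(pi * 0.045 * (60 / out$hr))) * out$sdnn
  out$rmssd <- pmax(out$rmssd, floor_rmssd)
  out
}

#' Simulate a complete synthetic cohort
#'
#' Generates, deterministically from the config seed, a full two-state
#' cohort: subject profiles, group labels, per-phase ground-truth targets
#' (HR, SDNN, RMSSD, normalized PAT, blood pressure), beat-level series for
#' every session (NN intervals and per-beat PAT covering the whole
#' schedule), and reference-parameter tables.  Raw waveforms are rendered on
#' demand with [render_session()] so that cohort-scale statistical work does
#' not pay the waveform cost.
#'
#' Stored ground truth lets every detection and measurement stage be scored
#' against known targets.  Blood pressure is held constant within a state
#' (the generator's default; a per-phase drift can be introduced through
#' `bp_drift`), and raw (pre-normalization) PAT targets are derived from the
#' normalized targets via the 1 ms/mmHg relation, so normalizing measured
#' PAT downstream recovers the normalized targets.
#'
#' @param config A [cohort_config()].
#' @param bp_drift Optional per-phase systolic drift SD in mmHg (default 0:
#'   constant pressure within a state).
#' @return A list of class `"fatigue_cohort"`: `config`, `schedule`,
#'   `profiles`, `groups` (subject, group, cmj_change), `targets` (long data
#'   frame of per-subject/state/phase targets incl. `sbp` and raw `pat`),
#'   `bp` (per state/phase), `reference` (long reference-parameter table)
#'   and `beats` (nested list `[[subject]][[state]]` of beat annotations).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 4, seed = 7))
#' coh$groups
#' @export
simulate_cohort <- function(config = cohort_config(), bp_drift = 0) {
  stopifnot(inherits(config, "cohort_config"))
  sched <- build_schedule(durations_min = config$schedule_durations_min)
  n <- config$n_subjects
  eff <- config$state_effects
  gs <- config$group_structure
  nl <- config$noise_levels

  with_seed(config$seed, {
    n_f <- round(n * config$sex_ratio)
    sex <- c(rep("F", n_f), rep("M", n - n_f))
    ids <- sprintf("S%02d", seq_len(n))
    profiles <- do.call(rbind, lapply(seq_len(n), function(i) {
      a <- anthro_defaults(sex[i])
      age <- round(rnorm_trunc(1, a$age[1], a$age[2], 18, 60))
      height <- rnorm_trunc(1, a$height[1], a$height[2], 150, 200)
      weight <- rnorm_trunc(1, a$weight[1], a$weight[2], 45, 110)
      data.frame(subject_id = ids[i], sex = sex[i], age = age,
                 height = round(height, 1), weight = round(weight, 1),
                 bmi = round(weight / (height / 100)^2, 1),
                 stringsAsFactors = FALSE)
    }))

    n_sig <- round(n * gs$significant_fraction)
    if (n_sig < 2 || n - n_sig < 2) {
      n_sig <- max(2L, min(n - 2L, n_sig))
    }
    group <- sample(c(rep("significant", n_sig), rep("mild", n - n_sig)))

    jitter_draw <- function(k) {
      j <- nl$phase_jitter
      list(hr = exp(stats::rnorm(k, 0, j / 2)),
           sdnn = exp(stats::rnorm(k, 0, j)),
           rmssd = exp(stats::rnorm(k, 0, j)),
           pat = exp(stats::rnorm(k, 0, j / 2)))
    }

    groups <- data.frame(subject_id = ids, group = group,
                         cmj_change = NA_real_, stringsAsFactors = FALSE)
    targets <- NULL; bp <- NULL; reference <- NULL
    beats <- stats::setNames(vector("list", n), ids)

    for (i in seq_len(n)) {
      rest <- list(
        hr = rnorm_trunc(1, 98.5, nl$hr, 55, 150),
        sdnn = rnorm_trunc(1, 58.0, nl$sdnn, 18, 120),
        rmssd = NA,
        pat_norm = rnorm_trunc(1, 273.4, nl$pat, 160, 380))
      ratio <- rnorm_trunc(1, 0.61, 0.10, 0.45, 1.15)
      rest$rmssd <- rest$sdnn * ratio

      sbp_rs <- rnorm_trunc(1, 120, 10, 95, 165)
      sbp_pfs <- rnorm_trunc(1, sbp_rs + 5, 5, 95, 175)
      dbp_rs <- rnorm_trunc(1, sbp_rs - 42, 5, 50, 110)
      dbp_pfs <- rnorm_trunc(1, sbp_pfs - 40, 5, 50, 110)

      ref_seed <- sample.int(2^31 - 2, 1)
      ref <- simulate_reference_params(profiles[i, ], group[i], ref_seed,
                                       gs)
      groups$cmj_change[i] <- attr(ref, "cmj_change")
      reference <- rbind(reference,
                         cbind(subject_id = ids[i], ref,
                               stringsAsFactors = FALSE))

      subj_eff <- draw_subject_effects(group[i], eff, gs)
      for (state in c("RS", "PFS")) {
        tg <- phase_targets(rest, state, subj_eff, jitter_draw)
        sbp0 <- if (state == "RS") sbp_rs else sbp_pfs
        dbp0 <- if (state == "RS") dbp_rs else dbp_pfs
        sbp_phase <- sbp0 + if (bp_drift > 0)
          stats::rnorm(nrow(tg), 0, bp_drift) else 0
        tg$sbp <- round(sbp_phase, 1)
        tg$dbp <- round(pmin(dbp0, tg$sbp - 15), 1)
        tg$pat <- tg$pat_norm - (tg$sbp - 120)   # raw, pre-normalization
        tg <- cbind(subject_id = ids[i], state = state, tg,
                    stringsAsFactors = FALSE)
        targets <- rbind(targets, tg)
        bp <- rbind(bp, tg[, c("subject_id", "state", "phase_id",
                               "sbp", "dbp")])

        # beat-level series, phase by phase
        r_times <- numeric(0); nn_all <- numeric(0); nn_t <- numeric(0)
        pat_all <- numeric(0)
        for (p in seq_len(nrow(sched))) {
          ph <- tg[p, ]
          s_ph <- sample.int(2^31 - 2, 1)
          nn <- simulate_rr_series(ph$hr, ph$sdnn, ph$rmssd,
                                   duration = sched$end[p] - sched$start[p],
                                   seed = s_ph)
          rt <- sched$start[p] + cumsum(nn) / 1000
          nn <- nn[rt < sched$end[p]]
          rt <- rt[rt < sched$end[p]]
          pb <- pmin(pmax(ph$pat + stats::rnorm(length(rt), 0,
                                                nl$pat_beat_sd), 60), 590)
          r_times <- c(r_times, rt)
          nn_all <- c(nn_all, nn[-1L])
          nn_t <- c(nn_t, rt[-1L])
          pat_all <- c(pat_all, pb)
        }
        beats[[ids[i]]][[state]] <- structure(list(
          r_times = r_times, nn = nn_all, nn_times = nn_t,
          foot_times = r_times + pat_all / 1000,
          pat = pat_all,
          rejections = data.frame(index = integer(0), value = numeric(0),
                                  rule = character(0)),
          n_skipped_feet = 0L), class = "beat_annotations")
      }
    }
    rownames(targets) <- rownames(bp) <- rownames(reference) <- NULL
    structure(list(config = config, schedule = sched, profiles = profiles,
                   groups = groups, targets = targets, bp = bp,
                   reference = reference, beats = beats),
              class = "fatigue_cohort")
  })
}

#' Render the raw waveforms of one session of a cohort
#'
#' Produces the ECG and pulse-wave sample streams implied by a cohort
#' subject's stored beat-level series, at the config sampling rate (or an
#' override).  Both streams share a common time axis starting at 0 s and are
#' cut to equal length.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param subject_id Subject identifier, e.g. `"S01"`.
#' @param state `"RS"` or `"PFS"`.
#' @param fs Sampling rate, Hz (default: config value).
#' @return A list with `time`, `ecg`, `pulse`, `fs`, `r_times`,
#'   `foot_times`.
#' @export
render_session <- function(cohort, subject_id, state, fs = NULL) {
  stopifnot(inherits(cohort, "fatigue_cohort"))
  if (is.null(fs)) fs <- cohort$config$fs
  b <- cohort$beats[[subject_id]][[state]]
  if (is.null(b)) stop("no such subject/state: ", subject_id, "/", state)
  nn <- diff(c(0, b$r_times)) * 1000
  ecg <- render_ecg(nn, fs = fs)
  pulse <- render_pulse(nn, b$pat, fs = fs)
  n <- min(length(ecg$ecg), length(pulse$pulse))
  list(time = ecg$time[seq_len(n)], ecg = ecg$ecg[seq_len(n)],
       pulse = pulse$pulse[seq_len(n)], fs = fs,
       r_times = ecg$r_times, foot_times = pulse$foot_times)
}
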