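#' Detect R-peaks in a single-lead ECG
#'
#' A Hamilton-Tompkins style detector: band-pass filter (8-20 Hz,
#' zero-phase), absolute first difference, 80-ms moving-window integration,
#' then an adaptive dual-threshold peak picker with a 200-ms refractory
#' period and search-back for missed beats.  Detections are refined to the
#' local maximum of the raw signal within +/- 25 ms, so reported times sit on
#' the R wave itself rather than on the integrated envelope.
#'
#' All thresholds adapt to running signal/noise peak estimates, so a uniform
#' gain applied to the ECG leaves the detected times unchanged.  A flat
#' (all-equal) signal yields an empty result rather than an error.
#'
#' @param ecg Numeric vector of ECG samples (any units).
#' @param fs Sampling rate, Hz (>= 250).
#' @param refractory Minimum R-R separation in seconds (default 0.2).
#' @param threshold_coef Position of the detection threshold between the
#'   running noise and signal peak levels (default 0.3125).
#' @param searchback_factor Trigger search-back when the gap since the last
#'   accepted beat exceeds this multiple of the running mean RR (default 1.5).
#' @return Numeric vector of R-peak times in seconds, strictly increasing.
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.2,
                           threshold_coef = 0.3125,
                           searchback_factor = 1.5) {
  if (fs < 250) stop("'fs' must be >= 250 Hz for R-peak detection")
  if (length(ecg) < 2 * fs) stop("need at least 2 s of ECG signal")
  if (all(ecg == ecg[1])) return(numeric(0))

  bp <- signal::filtfilt(signal::butter(2, c(8, 20) / (fs / 2), type = "pass"),
                         ecg)
  env <- abs(c(diff(bp), 0))
  w <- max(3L, round(0.08 * fs))
  integ <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # candidate peaks: local maxima of the integrated envelope
  d <- diff(integ)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand) == 0L) return(numeric(0))
  h <- integ[cand]

  # adaptive state, initialized from the first 2 s
  init <- h[cand <= 2 * fs]
  if (length(init) == 0L) init <- h
  spk <- max(init)
  npk <- stats::median(init)
  if (npk >= spk) npk <- spk / 2
  thr <- npk + threshold_coef * (spk - npk)

  qrs <- integer(0)
  rr_hist <- numeric(0)
  noise_buf <- integer(0)  # sub-threshold candidates since last beat
  for (k in seq_along(cand)) {
    i <- cand[k]
    if (length(qrs) > 0 && (i - qrs[length(qrs)]) < refractory * fs) next
    if (h[k] > thr) {
      if (length(qrs) > 0) {
        rr_hist <- c(rr_hist, (i - qrs[length(qrs)]) / fs)
        if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
      }
      qrs <- c(qrs, i)
      spk <- 0.875 * spk + 0.125 * h[k]
      noise_buf <- integer(0)
    } else {
      npk <- 0.875 * npk + 0.125 * h[k]
      noise_buf <- c(noise_buf, k)
      # search-back: a long gap suggests a missed beat among noise peaks
      if (length(qrs) > 0 && length(rr_hist) >= 2) {
        gap <- (i - qrs[length(qrs)]) / fs
        if (gap > searchback_factor * mean(rr_hist) && length(noise_buf) > 0) {
          hb <- h[noise_buf]
          best <- noise_buf[which.max(hb)]
          if (h[best] > 0.5 * thr &&
              (cand[best] - qrs[length(qrs)]) >= refractory * fs) {
            qrs <- c(qrs, cand[best])
            qrs <- sort(qrs)
            spk <- 0.875 * spk + 0.125 * h[best]
            noise_buf <- integer(0)
          }
        }
      }
    }
    thr <- npk + threshold_coef * (spk - npk)
  }
  if (length(qrs) == 0L) return(numeric(0))

  # refine to the raw-signal local maximum, hill-climbing in +/- 25 ms steps
  half <- round(0.025 * fs)
  refined <- vapply(qrs, function(i) {
    for (iter in 1:5) {
      i0 <- max(1L, i - half)
      i1 <- min(length(ecg), i + half)
      j <- as.integer(i0 + which.max(ecg[i0:i1]) - 1L)
      if (j == i) break
      i <- j
    }
    i
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement
  keep <- c(TRUE, diff(refined) >= refractory * fs)
  (refined[keep] - 1L) / fs
}

#' Detect pulse-wave onset (foot) fiducials
#'
#' Locates, for every pulse cycle, the foot of the rising front.  The default
#' fiducial is the intersecting-tangent point: the tangent to the waveform at
#' the point of maximum upslope, intersected with the horizontal line through
#' the preceding local minimum.  Alternatives: the maximum-upslope instant
#' itself, or a fractional-amplitude threshold crossing (10% of the cycle's
#' pulse height above the preceding minimum).
#'
#' Cycles whose rising edge is degenerate (non-positive maximum slope) are
#' skipped; the number of skipped cycles is attached as attribute
#' `"n_skipped"`.
#'
#' @param pulse Numeric vector of pulse-wave samples (arbitrary units).
#' @param fs Sampling rate, Hz.
#' @param method Foot definition: `"tangent_intersection"` (default),
#'   `"max_slope"` or `"fractional_threshold"`.
#' @param min_cycle Minimum peak-to-peak separation in seconds (default 0.3).
#' @return Numeric vector of foot times in seconds, strictly increasing,
#'   with attribute `n_skipped`.
#' @export
detect_pulse_feet <- function(pulse, fs,
                              method = c("tangent_intersection", "max_slope",
                                         "fractional_threshold"),
                              min_cycle = 0.3) {
  method <- match.arg(method)
  if (length(pulse) < 2 * fs) stop("need at least 2 s of pulse signal")
  if (all(pulse == pulse[1])) {
    return(structure(numeric(0), n_skipped = 0L))
  }

  lo <- stats::quantile(pulse, 0.02, names = FALSE)
  hi <- stats::quantile(pulse, 0.98, names = FALSE)
  thr <- lo + 0.5 * (hi - lo)
  d <- diff(pulse)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  pk <- pk[pulse[pk] > thr]
  if (length(pk) == 0L) return(structure(numeric(0), n_skipped = 0L))
  # enforce minimum cycle length, keeping the taller of two close peaks
  kept <- integer(0)
  for (p in pk) {
    if (length(kept) == 0L || (p - kept[length(kept)]) >= min_cycle * fs) {
      kept <- c(kept, p)
    } else if (pulse[p] > pulse[kept[length(kept)]]) {
      kept[length(kept)] <- p
    }
  }
  pk <- kept

  feet <- numeric(0)
  n_skipped <- 0L
  back <- round(0.5 * fs)
  for (k in seq_along(pk)) {
    p <- pk[k]
    i0 <- max(1L, p - back)
    if (k > 1L) i0 <- max(i0, pk[k - 1L] + 1L)  # stay within this cycle
    seg <- pulse[i0:p]
    mi <- i0 + which.min(seg) - 1L
    if (mi >= p) { n_skipped <- n_skipped + 1L; next }
    rise <- pulse[mi:p]
    sl <- diff(rise) * fs
    m <- which.max(sl)
    slope <- sl[m]
    if (!is.finite(slope) || slope <= 0) { n_skipped <- n_skipped + 1L; next }
    im <- mi + m - 1L  # sample at the start of the steepest step
    y_min <- pulse[mi]
    ft <- switch(method,
      tangent_intersection = {
        tm <- (im - 1L) / fs
        tm - (pulse[im] - y_min) / slope
      },
      max_slope = (im - 1L) / fs,
      fractional_threshold = {
        target <- y_min + 0.1 * (pulse[p] - y_min)
        j <- which(rise >= target)[1]
        if (is.na(j) || j == 1L) {
          (mi - 1L) / fs
        } else {
          # linear interpolation between the straddling samples
          # rise[j] sits at absolute sample index mi + j - 1 (1-based)
          y0 <- rise[j - 1L]; y1 <- rise[j]
          frac <- if (y1 > y0) (target - y0) / (y1 - y0) else 0
          (mi + j - 3L + frac) / fs
        }
      })
    feet <- c(feet, ft)
  }
  feet <- feet[is.finite(feet)]
  feet <- sort(feet)
  feet <- feet[c(TRUE, diff(feet) > 0)]
  structure(feet, n_skipped = n_skipped)
}

#' Pair R-peaks with pulse feet into per-beat pulse arrival times
#'
#' Each R-peak is paired with the earliest pulse foot occurring after it and
#' before the next R-peak, provided the lag lies within plausibility bounds
#' (default 100-500 ms).  Beats with no admissible foot are left unmatched
#' (`NA`).
#'
#' @param r_times R-peak times, seconds, sorted.
#' @param foot_times Pulse-foot times, seconds, sorted.
#' @param bounds Admissible PAT interval in ms (default `c(100, 500)`).
#' @return Numeric vector of per-beat PAT in ms aligned with `r_times`;
#'   `NA` where unmatched.
#' @examples
#' match_beats(c(1, 2), c(1.27, 2.27)) # 270 270
#' @export
match_beats <- function(r_times, foot_times, bounds = c(100, 500)) {
  if (is.unsorted(r_times, strictly = FALSE) ||
      is.unsorted(foot_times, strictly = FALSE)) {
    stop("'r_times' and 'foot_times' must be sorted")
  }
  n <- length(r_times)
  pat <- rep(NA_real_, n)
  if (n == 0L || length(foot_times) == 0L) return(pat)
  for (i in seq_len(n)) {
    upper <- if (i < n) r_times[i + 1L] else Inf
    cands <- foot_times[foot_times > r_times[i] & foot_times < upper]
    if (length(cands) == 0L) next
    lag_ms <- (cands[1L] - r_times[i]) * 1000
    if (lag_ms >= bounds[1L] && lag_ms <= bounds[2L]) pat[i] <- lag_ms
  }
  pat
}

#' Automated NN-interval cleaning
#'
#' Replaces manual beat verification with two explicit rules: an absolute
#' bound (default 300-2000 ms) and a relative rule rejecting intervals that
#' deviate from the median of their 5 nearest surviving neighbours by more
#' than a configurable fraction (default 30%).  Every rejection is logged
#' with its index, value and the rule that fired.
#'
#' @param nn Numeric vector of NN intervals, ms.
#' @param min_ms,max_ms Absolute plausibility bounds, ms.
#' @param rel_tol Maximum allowed relative deviation from the neighbourhood
#'   median (default 0.3).
#' @param k Neighbourhood size for the relative rule (default 5).
#' @return A list with `accepted` (the surviving intervals), `accepted_idx`
#'   (their positions in the input) and `rejections` (data frame of
#'   `index`, `value`, `rule`).
#' @export
clean_nn_intervals <- function(nn, min_ms = 300, max_ms = 2000,
                               rel_tol = 0.3, k = 5) {
  idx <- seq_along(nn)
  rej <- data.frame(index = integer(0), value = numeric(0),
                    rule = character(0), stringsAsFactors = FALSE)
  bad_abs <- !is.finite(nn) | nn < min_ms | nn > max_ms
  if (any(bad_abs)) {
    rej <- rbind(rej, data.frame(index = idx[bad_abs], value = nn[bad_abs],
                                 rule = "absolute_bound",
                                 stringsAsFactors = FALSE))
  }
  keep_idx <- idx[!bad_abs]
  vals <- nn[keep_idx]
  if (length(vals) > k) {
    bad_rel <- logical(length(vals))
    for (j in seq_along(vals)) {
      others <- setdiff(seq_along(vals), j)
      nb <- others[order(abs(others - j))][seq_len(min(k, length(others)))]
      med <- stats::median(vals[nb])
      if (med > 0 && abs(vals[j] - med) / med > rel_tol) bad_rel[j] <- TRUE
    }
    if (any(bad_rel)) {
      rej <- rbind(rej, data.frame(index = keep_idx[bad_rel],
                                   value = vals[bad_rel],
                                   rule = "relative_median",
                                   stringsAsFactors = FALSE))
      keep_idx <- keep_idx[!bad_rel]
      vals <- vals[!bad_rel]
    }
  }
  rej <- rej[order(rej$index), , drop = FALSE]
  rownames(rej) <- NULL
  list(accepted = vals, accepted_idx = keep_idx, rejections = rej)
}

#' Annotate one session recording with beats, NN intervals and PAT
#'
#' Convenience wrapper running the full beat-level chain: R-peak detection,
#' pulse-foot detection, beat matching and NN cleaning.
#'
#' @param recording A list with `ecg`, `pulse`, `fs` (see
#'   [read_signal_csv()] or [render_session()]).
#' @param pat_bounds PAT plausibility bounds, ms.
#' @param foot_method Foot fiducial passed to [detect_pulse_feet()].
#' @param ... Cleaning rules passed to [clean_nn_intervals()].
#' @return A list of class `"beat_annotations"` with `r_times`, `nn` (cleaned,
#'   ms), `nn_times` (time of each accepted interval's defining later R-peak),
#'   `foot_times`, `pat` (per-beat, ms, `NA` unmatched), and `rejections`.
#' @export
annotate_beats <- function(recording, pat_bounds = c(100, 500),
                           foot_method = "tangent_intersection", ...) {
  r <- detect_r_peaks(recording$ecg, recording$fs)
  feet <- detect_pulse_feet(recording$pulse, recording$fs,
                            method = foot_method)
  pat <- match_beats(r, as.numeric(feet), bounds = pat_bounds)
  nn_raw <- diff(r) * 1000
  cl <- clean_nn_intervals(nn_raw, ...)
  structure(list(
    r_times = r,
    nn = cl$accepted,
    nn_times = r[-1L][cl$accepted_idx],
    foot_times = as.numeric(feet),
    pat = pat,
    rejections = cl$rejections,
    n_skipped_feet = attr(feet, "n_skipped")
  ), class = "beat_annotations")
}
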