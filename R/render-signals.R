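#' Render a synthetic ECG stream from an NN-interval sequence
#'
#' Builds a template-based ECG: every beat contributes a P-QRS-T complex made
#' of Gaussian bumps, with the R-peak placed exactly at the beat's cumulative
#' NN time.  The true R-peak times are returned alongside the samples so that
#' detection stages can be scored against ground truth.
#'
#' @param nn Numeric vector of NN intervals in ms; beat k occurs at
#'   `sum(nn[1:k]) / 1000` seconds, so `length(nn)` beats are rendered.
#' @param fs Sampling rate in Hz (>= 250; the study hardware used 1 kHz).
#' @return A list with `time` (s), `ecg` (mV), `r_times` (s, ground truth)
#'   and `fs`.
#' @examples
#' ecg <- render_ecg(rep(1000, 10), fs = 500)
#' length(ecg$r_times)
#' @export
render_ecg <- function(nn, fs = 1000) {
  if (length(nn) == 0L) stop("'nn' must contain at least one interval")
  if (any(!is.finite(nn)) || any(nn <= 0)) stop("'nn' must be positive")
  if (fs < 250) stop("'fs' must be >= 250 Hz")

  r_times <- cumsum(nn) / 1000
  total <- r_times[length(r_times)] + 0.5
  n <- ceiling(total * fs)
  tt <- (seq_len(n) - 1L) / fs
  sig <- numeric(n)

  # P-QRS-T template: (offset s, amplitude mV, width s) per Gaussian bump
  waves <- rbind(
    p = c(-0.200,  0.15, 0.025),
    q = c(-0.026, -0.15, 0.008),
    r = c( 0.000,  1.00, 0.012),
    s = c( 0.026, -0.20, 0.008),
    t = c( 0.250,  0.30, 0.050)
  )
  half <- 0.45
  for (rt in r_times) {
    i0 <- max(1L, floor((rt - half) * fs) + 1L)
    i1 <- min(n, ceiling((rt + half) * fs) + 1L)
    tl <- tt[i0:i1] - rt
    seg <- numeric(length(tl))
    for (w in seq_len(nrow(waves))) {
      seg <- seg + waves[w, 2] * exp(-((tl - waves[w, 1])^2) /
                                       (2 * waves[w, 3]^2))
    }
    sig[i0:i1] <- sig[i0:i1] + seg
  }
  list(time = tt, ecg = sig, r_times = r_times, fs = fs)
}

#' Render a synthetic pulse-wave stream with known foot times
#'
#' Each beat contributes a pulse of the form `A * x/tau * exp(1 - x/tau)`
#' (x = time since the pulse foot), whose onset — the foot of the rising
#' front — lags the corresponding R-peak by exactly the supplied pulse
#' arrival time.  The linear leading edge puts the maximum upslope at the
#' foot itself, so onset fiducials are well defined.  True foot times are
#' returned as ground truth.
#'
#' @param nn NN intervals in ms, as in [render_ecg()].
#' @param pat Per-beat pulse arrival times in ms, same length as `nn`,
#'   each within [50, 600].
#' @param fs Sampling rate, Hz (>= 250).
#' @param tau Pulse time constant, s (peak occurs `tau` after the foot).
#' @return A list with `time` (s), `pulse` (a.u.), `foot_times` (s),
#'   `r_times` (s) and `fs`.
#' @export
render_pulse <- function(nn, pat, fs = 1000, tau = 0.15) {
  if (length(nn) == 0L) stop("'nn' must contain at least one interval")
  if (length(pat) != length(nn)) {
    stop("'pat' must have one value per beat (length mismatch: ",
         length(pat), " vs ", length(nn), ")")
  }
  if (any(!is.finite(pat)) || any(pat < 50) || any(pat > 600)) {
    stop("per-beat PAT must lie in [50, 600] ms")
  }
  if (fs < 250) stop("'fs' must be >= 250 Hz")

  r_times <- cumsum(nn) / 1000
  foot_times <- r_times + pat / 1000
  total <- foot_times[length(foot_times)] + 1.0
  n <- ceiling(total * fs)
  tt <- (seq_len(n) - 1L) / fs
  sig <- numeric(n)
  span <- 1.0  # render each pulse for 1 s past its foot
  for (ft in foot_times) {
    i0 <- max(1L, floor(ft * fs) + 1L)
    i1 <- min(n, ceiling((ft + span) * fs) + 1L)
    x <- tt[i0:i1] - ft
    seg <- ifelse(x >= 0, (x / tau) * exp(1 - x / tau), 0)
    sig[i0:i1] <- sig[i0:i1] + seg
  }
  list(time = tt, pulse = sig, foot_times = foot_times,
       r_times = r_times, fs = fs)
}
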