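# Run code with a private RNG stream: restores the caller's .Random.seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate an NN-interval series with target SDNN and RMSSD
#'
#' Generates a beat-to-beat NN (normal-to-normal) interval sequence by
#' superposing a slow oscillation (default 0.1 Hz, the baroreflex /
#' Mayer-wave band), a fast oscillation (default 0.25 Hz, the respiratory
#' band) and white noise on a constant base interval `60000 / mean_hr` ms.
#'
#' The three component variances are solved in closed form so that the
#' expected SDNN and RMSSD of the series equal the targets.  For a sinusoid
#' of amplitude A and frequency f sampled every T seconds (T = mean NN), the
#' contribution to SDNN^2 is A^2/2 and to RMSSD^2 is `4 sin^2(pi f T)` times
#' that; white noise contributes its variance to SDNN^2 and twice its
#' variance to RMSSD^2.  The attainable RMSSD/SDNN ratio is therefore
#' bounded: RMSSD can never exceed `sqrt(2) * SDNN`, and at a given heart
#' rate it cannot fall below the slow-oscillation limit
#' `2 |sin(pi f_slow T)| * SDNN`.  Target pairs outside this band are
#' rejected with an error naming the violated constraint.
#'
#' @param mean_hr Target mean heart rate, bpm (30-220).
#' @param target_sdnn Target SDNN, ms (>= 0).
#' @param target_rmssd Target RMSSD, ms (>= 0).
#' @param duration Series duration, seconds (> 0).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param f_slow,f_fast Component frequencies, Hz.
#' @return Numeric vector of NN intervals in ms, one per beat, covering
#'   `duration` seconds.
#' @examples
#' nn <- simulate_rr_series(60, 50, 30, duration = 300, seed = 1)
#' c(hr = compute_hr(nn), sdnn = compute_sdnn(nn), rmssd = compute_rmssd(nn))
#' @export
simulate_rr_series <- function(mean_hr, target_sdnn, target_rmssd,
                               duration, seed,
                               f_slow = 0.1, f_fast = 0.25) {
  stopifnot(is.numeric(mean_hr), length(mean_hr) == 1L)
  if (mean_hr < 30 || mean_hr > 220) stop("'mean_hr' must be in [30, 220] bpm")
  if (target_sdnn < 0 || target_rmssd < 0) stop("targets must be >= 0")
  if (duration <= 0) stop("'duration' must be positive")

  base <- 60000 / mean_hr              # ms
  t_beat <- base / 1000                # s
  n <- max(2L, floor(duration / t_beat))

  if (target_sdnn == 0 && target_rmssd == 0) {
    return(rep(base, n))
  }

  s2 <- target_sdnn^2
  r2 <- target_rmssd^2
  r_s <- 4 * sin(pi * f_slow * t_beat)^2   # RMSSD^2 per unit SDNN^2, slow
  r_f <- 4 * sin(pi * f_fast * t_beat)^2   # ... fast oscillation
  r_n <- 2                                 # ... white noise

  if (r2 > max(r_f, r_n) * s2 + 1e-9) {
    stop("infeasible target pair: RMSSD target ", target_rmssd,
         " exceeds the attainable sqrt(2) * SDNN = ",
         round(sqrt(2) * target_sdnn, 2), " ms")
  }
  if (r2 < r_s * s2 - 1e-9) {
    # the requested RMSSD/SDNN ratio is below the floor at f_slow: slide the
    # slow oscillation down within the low-frequency band (>= 0.04 Hz)
    ratio <- sqrt(r2 / (4 * s2))
    f_need <- if (ratio >= 1) f_slow else 0.95 * asin(ratio) / (pi * t_beat)
    if (f_need < 0.04) {
      stop("infeasible target pair: RMSSD target ", target_rmssd,
           " is below the slow-oscillation floor ",
           round(2 * abs(sin(pi * 0.04 * t_beat)) * target_sdnn, 2),
           " ms attainable at this heart rate (slow band limited to ",
           ">= 0.04 Hz)")
    }
    f_slow <- max(0.04, f_need)
    r_s <- 4 * sin(pi * f_slow * t_beat)^2
  }

  # Variance split: slow component v_s plus an equal share u in each of the
  # fast oscillation and white noise; fall back to fast+noise only when the
  # requested ratio is too high for any slow contribution.
  u <- (r2 - r_s * s2) / (r_f + r_n - 2 * r_s)
  v_s <- s2 - 2 * u
  if (u >= 0 && v_s >= 0) {
    v_f <- u
    v_n <- u
  } else {
    v_s <- 0
    if (abs(r_n - r_f) < 1e-9) {
      v_f <- s2 / 2
      v_n <- s2 / 2
    } else {
      v_n <- (r2 - r_f * s2) / (r_n - r_f)
      v_n <- min(max(v_n, 0), s2)
      v_f <- s2 - v_n
    }
  }

  with_seed(seed, {
    phi_s <- stats::runif(1, 0, 2 * pi)
    phi_f <- stats::runif(1, 0, 2 * pi)
    tt <- (seq_len(n) - 1L) * t_beat
    nn <- base +
      sqrt(2 * v_s) * sin(2 * pi * f_slow * tt + phi_s) +
      sqrt(2 * v_f) * sin(2 * pi * f_fast * tt + phi_f) +
      stats::rnorm(n, 0, sqrt(v_n))
    pmax(nn, 250)  # physiological floor; inactive at default noise levels
  })
}
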