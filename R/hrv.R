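#' Time-domain heart-rate and HRV measures
#'
#' `compute_hr` returns the mean heart rate implied by a sequence of NN
#' (normal-to-normal) intervals, `compute_sdnn` their sample standard
#' deviation and `compute_rmssd` the root mean square of successive
#' differences.  Only time-domain measures are provided; frequency-domain and
#' non-linear HRV indices are deliberately out of scope.
#'
#' SDNN uses the sample (n - 1) standard deviation, the dominant convention
#' in HRV work.  RMSSD is the standard root-mean-square of successive NN
#' differences, `sqrt(mean(diff(nn)^2))`.
#'
#' @param nn Numeric vector of NN intervals in milliseconds.
#' @return Heart rate in beats per minute (`compute_hr`) or a dispersion
#'   measure in milliseconds (`compute_sdnn`, `compute_rmssd`).
#' @examples
#' compute_hr(c(1000, 1000, 1000))   # 60 bpm
#' compute_sdnn(c(800, 820, 780, 800))
#' compute_rmssd(c(800, 810, 790))
#' @export
compute_hr <- function(nn) {
  if (length(nn) == 0L) stop("cannot compute HR from an empty NN sequence")
  if (any(!is.finite(nn)) || any(nn <= 0)) {
    stop("NN intervals must be positive and finite")
  }
  60000 / mean(nn)
}

#' @rdname compute_hr
#' @export
compute_sdnn <- function(nn) {
  if (length(nn) < 2L) stop("SDNN needs at least 2 NN intervals")
  if (any(!is.finite(nn))) stop("NN intervals must be finite")
  stats::sd(nn)
}

#' @rdname compute_hr
#' @export
compute_rmssd <- function(nn) {
  if (length(nn) < 2L) stop("RMSSD needs at least 2 NN intervals")
  if (any(!is.finite(nn))) stop("NN intervals must be finite")
  d <- diff(nn)
  sqrt(mean(d^2))
}

#' Normalize pulse arrival time to a reference systolic blood pressure
#'
#' PAT shortens as blood pressure rises (roughly 1 ms per mmHg around typical
#' adult pressures).  To compare PAT across subjects and states, observed
#' values are referred to a common systolic pressure (default 120 mmHg): a
#' measurement taken at above-reference pressure is lengthened back by
#' 1 ms per mmHg of excess pressure, and vice versa:
#' `pat_norm = pat + (sbp - reference_sbp) * 1 ms/mmHg`.
#' The correction is exactly invertible.
#'
#' @param pat Observed PAT in milliseconds (> 0).
#' @param sbp Systolic blood pressure at measurement time, mmHg.
#' @param reference_sbp Reference systolic pressure, mmHg (default 120).
#' @param slope_ms_per_mmhg PAT/pressure sensitivity (default 1 ms/mmHg).
#' @return Normalized PAT in milliseconds.
#' @examples
#' normalize_pat(270, 120) # unchanged at the reference pressure
#' normalize_pat(260, 130) # 270: high pressure shortened the observed PAT
#' @export
normalize_pat <- function(pat, sbp, reference_sbp = 120,
                          slope_ms_per_mmhg = 1) {
  if (any(!is.finite(pat)) || any(pat <= 0)) stop("'pat' must be positive")
  if (any(!is.finite(sbp)) || any(sbp <= 60) || any(sbp >= 260)) {
    stop("'sbp' outside physiological bounds (60, 260) mmHg")
  }
  pat + (sbp - reference_sbp) * slope_ms_per_mmhg
}
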