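#' Summarize one resting/recovery phase into cardiovascular measures
#'
#' Computes HR, SDNN and RMSSD from the NN intervals whose defining (later)
#' R-peak falls inside the phase's 2-min HRV window, and PAT as the mean of
#' matched per-beat PAT values whose R-peak falls inside the phase's 1-min
#' PAT window, normalized to the reference systolic pressure when a blood
#' pressure reading is supplied.  Windows are closed-open `[start, end)`.
#'
#' Phases with fewer accepted beats than the minimum are flagged missing
#' (`NA`) rather than fabricated.
#'
#' @param annotations A `beat_annotations` list (see [annotate_beats()]):
#'   `nn`, `nn_times`, `r_times`, `pat`.
#' @param phase One-row schedule data frame (`kind == "rest_or_recovery"`).
#' @param sbp Systolic blood pressure for the phase, mmHg, or `NA`.
#' @param min_beats Minimum NN count in the HRV window (default 30).
#' @param min_pat_beats Minimum matched-beat count in the PAT window
#'   (default 10).
#' @param pat_agg Aggregator for per-beat PAT within the window: `"mean"`
#'   (default) or `"median"`.
#' @return One-row data frame: `phase_id`, `hr`, `sdnn`, `rmssd`, `pat`,
#'   `pat_norm`, `n_beats`, `n_pat_beats`.
#' @export
summarize_phase <- function(annotations, phase, sbp = NA,
                            min_beats = 30, min_pat_beats = 10,
                            pat_agg = c("mean", "median")) {
  pat_agg <- match.arg(pat_agg)
  phase <- as_phase_row(phase)
  hw <- hrv_window(phase)
  pw <- pat_window(phase)

  in_hw <- annotations$nn_times >= hw[1] & annotations$nn_times < hw[2]
  nn <- annotations$nn[in_hw]
  n_beats <- length(nn)
  if (n_beats >= max(min_beats, 2L)) {
    hr <- compute_hr(nn); sdnn <- compute_sdnn(nn); rmssd <- compute_rmssd(nn)
  } else {
    hr <- sdnn <- rmssd <- NA_real_
  }

  in_pw <- annotations$r_times >= pw[1] & annotations$r_times < pw[2] &
    !is.na(annotations$pat)
  pats <- annotations$pat[in_pw]
  n_pat <- length(pats)
  if (n_pat >= max(min_pat_beats, 1L)) {
    pat <- if (pat_agg == "mean") mean(pats) else stats::median(pats)
    pat_norm <- if (is.finite(sbp)) normalize_pat(pat, sbp) else NA_real_
  } else {
    pat <- pat_norm <- NA_real_
  }

  data.frame(phase_id = phase$phase_id, hr = hr, sdnn = sdnn, rmssd = rmssd,
             pat = pat, pat_norm = pat_norm, n_beats = n_beats,
             n_pat_beats = n_pat, stringsAsFactors = FALSE)
}

#' Mean heart rate over the cycling phases
#'
#' The mean of per-beat instantaneous rates (60000 / NN) over all NN
#' intervals whose defining R-peak falls inside any cycling phase.  Used by
#' the summary-statistics layer, where the HR change is taken between the
#' resting heart rate and the average cycling heart rate.
#'
#' @param annotations A `beat_annotations` list.
#' @param schedule Schedule data frame from [build_schedule()].
#' @return Mean cycling HR in bpm, or `NA` if no beats fall in any cycling
#'   phase.
#' @export
cycling_hr <- function(annotations, schedule) {
  cyc <- schedule[schedule$kind == "cycling", , drop = FALSE]
  sel <- rep(FALSE, length(annotations$nn))
  for (p in seq_len(nrow(cyc))) {
    sel <- sel | (annotations$nn_times >= cyc$start[p] &
                    annotations$nn_times < cyc$end[p])
  }
  if (!any(sel)) return(NA_real_)
  mean(60000 / annotations$nn[sel])
}

#' Phase measures for a full session
#'
#' Applies [summarize_phase()] to every resting/recovery phase of a session
#' and returns the long measures table.
#'
#' @inheritParams summarize_phase
#' @param schedule Schedule data frame.
#' @param bp Data frame with `phase_id` and `sbp_mmhg` (or `sbp`) for the
#'   session's phases; may be `NULL`.
#' @param ... Passed to [summarize_phase()].
#' @return Data frame with one row per resting/recovery phase.
#' @export
session_measures <- function(annotations, schedule, bp = NULL, ...) {
  rows <- lapply(which(schedule$kind == "rest_or_recovery"), function(p) {
    ph <- schedule[p, , drop = FALSE]
    sbp <- NA_real_
    if (!is.null(bp)) {
      col <- if ("sbp_mmhg" %in% names(bp)) "sbp_mmhg" else "sbp"
      m <- bp[[col]][bp$phase_id == ph$phase_id]
      if (length(m) >= 1L) sbp <- m[1L]
    }
    summarize_phase(annotations, ph, sbp = sbp, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phase measures for every subject and state of a cohort
#'
#' Runs the measurement stage over a synthetic cohort's stored beat-level
#' series (the fast path: no waveform rendering or detection involved) and
#' returns the cohort-long measures table.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param ... Passed to [summarize_phase()].
#' @return Data frame with columns `subject_id`, `state`, `phase_id`, the
#'   measures, and `cycling_hr` (repeated per row of a session).
#' @export
cohort_measures <- function(cohort, ...) {
  stopifnot(inherits(cohort, "fatigue_cohort"))
  out <- NULL
  for (sid in names(cohort$beats)) {
    for (state in names(cohort$beats[[sid]])) {
      ann <- cohort$beats[[sid]][[state]]
      bp <- cohort$bp[cohort$bp$subject_id == sid &
                        cohort$bp$state == state, ]
      m <- session_measures(ann, cohort$schedule, bp = bp, ...)
      m <- cbind(subject_id = sid, state = state, m,
                 stringsAsFactors = FALSE)
      m$cycling_hr <- cycling_hr(ann, cohort$schedule)
      out <- rbind(out, m)
    }
  }
  rownames(out) <- NULL
  out
}
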