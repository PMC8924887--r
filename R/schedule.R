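#' Cycle-ergometer session schedule
#'
#' Builds the phase timeline of the structured veloergometer session: a 5-min
#' seated resting phase followed by three 3-min cycling bouts at increasing
#' power (60, 90, 120 W), each bout followed by a 5-min seated recovery phase.
#' The default schedule lasts 29 minutes.  The schedule is data, not code:
#' alternative phase durations (in minutes) may be supplied, but the phase
#' sequence (rest, three cycling/recovery pairs) is fixed.
#'
#' Phase windows are closed-open intervals `[start, end)` in seconds; beats
#' are assigned to a phase (and to the analysis sub-windows below) by their
#' R-peak time.
#'
#' @param start_offset Start time of the first phase in seconds (default 0).
#' @param durations_min Numeric vector of 7 phase durations in minutes, in
#'   session order (resting, cycling 60 W, recovery 1, cycling 90 W,
#'   recovery 2, cycling 120 W, recovery 3).
#' @return A data frame of class `"fatigue_schedule"` with columns
#'   `phase_id`, `kind` (`"rest_or_recovery"` or `"cycling"`), `start` and
#'   `end` (seconds).
#' @examples
#' sched <- build_schedule()
#' sum(sched$end - sched$start) # 1740 s = 29 min
#' @export
build_schedule <- function(start_offset = 0,
                           durations_min = c(5, 3, 5, 3, 5, 3, 5)) {
  stopifnot(is.numeric(start_offset), length(start_offset) == 1L,
            is.finite(start_offset))
  if (length(durations_min) != 7L || any(!is.finite(durations_min)) ||
      any(durations_min <= 0)) {
    stop("'durations_min' must be 7 positive phase durations in minutes")
  }
  phase_id <- c("resting", "cycling_60w", "recovery_1", "cycling_90w",
                "recovery_2", "cycling_120w", "recovery_3")
  kind <- c("rest_or_recovery", "cycling", "rest_or_recovery", "cycling",
            "rest_or_recovery", "cycling", "rest_or_recovery")
  ends <- start_offset + cumsum(durations_min * 60)
  starts <- c(start_offset, ends[-7L])
  out <- data.frame(phase_id = phase_id, kind = kind,
                    start = starts, end = ends,
                    stringsAsFactors = FALSE)
  class(out) <- c("fatigue_schedule", "data.frame")
  out
}

#' Names of the rest/recovery phases, in session order
#' @return Character vector of the four non-cycling phase ids.
#' @keywords internal
rest_phase_ids <- function() {
  c("resting", "recovery_1", "recovery_2", "recovery_3")
}

as_phase_row <- function(phase) {
  if (is.data.frame(phase)) {
    if (nrow(phase) != 1L) stop("'phase' must be a single schedule row")
    return(phase)
  }
  stop("'phase' must be a one-row schedule data frame")
}

#' Heart-rate-variability analysis window of a phase
#'
#' HRV measures (HR, SDNN, RMSSD) are computed from a 2-min section of the
#' slow phase of heart-rate recovery, between 2.5 and 4.5 min after the start
#' of a resting or recovery phase.
#'
#' @param phase A one-row schedule data frame (see [build_schedule()]).
#' @return Numeric `c(start, end)` in seconds, a closed-open interval.
#' @export
hrv_window <- function(phase) {
  phase <- as_phase_row(phase)
  if (phase$kind != "rest_or_recovery") {
    stop("HRV windows are defined only for resting/recovery phases, not '",
         phase$phase_id, "'")
  }
  c(phase$start + 150, phase$start + 270)
}

#' Pulse-arrival-time analysis window of a phase
#'
#' PAT is computed from a 1-min section between 3 and 4 min after the start
#' of a resting or recovery phase (blood pressure is measured in the same
#' section).
#'
#' @inheritParams hrv_window
#' @return Numeric `c(start, end)` in seconds, a closed-open interval.
#' @export
pat_window <- function(phase) {
  phase <- as_phase_row(phase)
  if (phase$kind != "rest_or_recovery") {
    stop("PAT windows are defined only for resting/recovery phases, not '",
         phase$phase_id, "'")
  }
  c(phase$start + 180, phase$start + 240)
}

#' Write / read a schedule as JSON
#'
#' @param schedule A schedule data frame from [build_schedule()].
#' @param path File path.
#' @return `read_schedule_json` returns the schedule data frame.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(as.data.frame(schedule), path, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  out <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("fatigue_schedule", "data.frame")
  out
}
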