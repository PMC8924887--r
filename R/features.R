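#' Derived subparameter family
#'
#' From a subject's per-phase, per-state measures the package derives a
#' family of named subparameters following the grammar
#' `<MEASURE>_<STATE>_<VARIANT>` and `<MEASURE>_DIF_<VARIANT>` with
#' MEASURE in \{SDNN, RMSSD, PAT, HR\}, STATE in \{RS, PFS\} and VARIANT in
#' \{REST, REC1, REC2, REC3, AVG, MIN, N_AVG, N_MIN\}:
#' \itemize{
#'   \item REST / REC1..REC3 — the phase values themselves (PAT uses the
#'     blood-pressure-normalized value);
#'   \item AVG / MIN — mean / minimum over the three recovery phases;
#'   \item N_AVG = REST / AVG and N_MIN = REST / MIN — resting value
#'     normalized by the recovery level (dimensionless);
#'   \item DIF variants — percent relative change of the variant between
#'     states, `100 * (PFS - RS) / RS`.
#' }
#' The full grammar yields 96 features.  Features whose inputs are missing
#' are absent (`NA`), never imputed; AVG and MIN require all three recovery
#' phases.  The name list is stable and sorted.
#'
#' @param measures Data frame for one subject with columns `state`,
#'   `phase_id`, `hr`, `sdnn`, `rmssd`, `pat_norm` covering both states.
#' @param feature_set Optional character vector restricting the returned
#'   features (e.g. a screened subset).
#' @return Named numeric vector of subparameter values (sorted by name).
#' @examples
#' \dontrun{
#' fv <- enumerate_features(subset(meas, subject_id == "S01"))
#' fv[c("SDNN_DIF_N_AVG", "PAT_PFS_N_MIN")]
#' }
#' @export
enumerate_features <- function(measures, feature_set = NULL) {
  if (!all(c("RS", "PFS") %in% measures$state)) {
    stop("'measures' must contain both states (RS and PFS)")
  }
  cols <- c(SDNN = "sdnn", RMSSD = "rmssd", PAT = "pat_norm", HR = "hr")
  variants <- c("REST", "REC1", "REC2", "REC3", "AVG", "MIN",
                "N_AVG", "N_MIN")
  rec_ids <- c("recovery_1", "recovery_2", "recovery_3")

  state_variants <- function(state, col) {
    m <- measures[measures$state == state, ]
    val <- function(pid) {
      v <- m[[col]][m$phase_id == pid]
      if (length(v) == 0L) NA_real_ else v[1L]
    }
    rest <- val("resting")
    recs <- vapply(rec_ids, val, numeric(1))
    avg <- if (any(is.na(recs))) NA_real_ else mean(recs)
    mn <- if (any(is.na(recs))) NA_real_ else min(recs)
    n_avg <- if (is.na(rest) || is.na(avg) || avg == 0) NA_real_ else
      rest / avg
    n_min <- if (is.na(rest) || is.na(mn) || mn == 0) NA_real_ else rest / mn
    stats::setNames(c(rest, recs, avg, mn, n_avg, n_min), variants)
  }

  out <- numeric(0)
  for (meas in names(cols)) {
    rs <- state_variants("RS", cols[[meas]])
    pfs <- state_variants("PFS", cols[[meas]])
    dif <- ifelse(is.na(rs) | is.na(pfs) | rs == 0, NA_real_,
                  100 * (pfs - rs) / rs)
    names(rs) <- paste(meas, "RS", variants, sep = "_")
    names(pfs) <- paste(meas, "PFS", variants, sep = "_")
    names(dif) <- paste(meas, "DIF", variants, sep = "_")
    out <- c(out, rs, pfs, dif)
  }
  out <- out[order(names(out))]
  if (!is.null(feature_set)) out <- out[names(out) %in% feature_set]
  out
}

#' The two headline subparameters
#'
#' `sdnn_dif_n_avg` is the percent change, between states, of the resting
#' SDNN normalized by the mean recovery SDNN:
#' `N(s) = SDNN_rest(s) / mean(SDNN_rec1..3(s))`, result
#' `100 * (N(PFS) - N(RS)) / N(RS)`.  `pat_pfs_n_min` is the fatigued-state
#' resting PAT divided by the lowest fatigued-state recovery PAT (normalized
#' values), a dimensionless ratio.
#'
#' @inheritParams enumerate_features
#' @return A single numeric value.
#' @export
sdnn_dif_n_avg <- function(measures) {
  fv <- enumerate_features(measures)
  v <- fv[["SDNN_DIF_N_AVG"]]
  if (is.na(v)) stop("SDNN_DIF_N_AVG undefined: missing phase values or ",
                     "zero recovery mean")
  v
}

#' @rdname sdnn_dif_n_avg
#' @export
pat_pfs_n_min <- function(measures) {
  fv <- enumerate_features(measures)
  v <- fv[["PAT_PFS_N_MIN"]]
  if (is.na(v)) stop("PAT_PFS_N_MIN undefined: missing fatigued-state PAT ",
                     "phase values or zero recovery minimum")
  v
}

#' Subject-by-feature matrix for a cohort measures table
#'
#' @param measures Cohort-long measures table (see [cohort_measures()]).
#' @param feature_set Optional restriction, as in [enumerate_features()].
#' @return Data frame, one row per subject (rownames = subject ids), one
#'   column per feature.
#' @export
feature_matrix <- function(measures, feature_set = NULL) {
  ids <- unique(measures$subject_id)
  rows <- lapply(ids, function(sid) {
    enumerate_features(measures[measures$subject_id == sid, ],
                       feature_set = feature_set)
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- ids
  out
}

#' The reference screened feature set
#'
#' The full grammar over-generates relative to what a fatigue screening
#' should consider: subparameters built purely from raw rested-state levels
#' (`<MEASURE>_RS_REST`, `_RS_REC1..3`, `_RS_AVG`, `_RS_MIN`) are subject
#' baselines measured before any fatigue was induced, so they cannot express
#' a fatigue response and are excluded from the reference screened set.
#' Rested-state recovery-normalized composites (`_RS_N_AVG`, `_RS_N_MIN`)
#' are retained: they describe the subject's rest-to-recovery contrast,
#' which the fatigued-state and between-state variants are compared against.
#' This leaves 72 of the 96 grammar features.
#'
#' @return Character vector of feature names (sorted).
#' @export
reference_feature_set <- function() {
  all_names <- names(enumerate_features(make_grammar_template()))
  raw_rs <- as.vector(outer(c("SDNN", "RMSSD", "PAT", "HR"),
                            c("RS_REST", "RS_REC1", "RS_REC2", "RS_REC3",
                              "RS_AVG", "RS_MIN"), paste, sep = "_"))
  sort(setdiff(all_names, raw_rs))
}

# Complete dummy measures table used to enumerate the grammar's name list.
make_grammar_template <- function() {
  ph <- c("resting", "recovery_1", "recovery_2", "recovery_3")
  rbind(
    data.frame(state = "RS", phase_id = ph, hr = c(60, 70, 71, 72),
               sdnn = c(60, 40, 41, 42), rmssd = c(40, 30, 31, 32),
               pat_norm = c(270, 260, 261, 262), stringsAsFactors = FALSE),
    data.frame(state = "PFS", phase_id = ph, hr = c(66, 77, 78, 79),
               sdnn = c(45, 35, 36, 37), rmssd = c(30, 22, 23, 24),
               pat_norm = c(265, 250, 251, 252), stringsAsFactors = FALSE))
}

#' Feature dictionary
#'
#' Human-readable definitions of the subparameter grammar, suitable for
#' export as JSON alongside a feature matrix.
#'
#' @return Named list mapping feature-name patterns to definitions.
#' @export
feature_dictionary <- function() {
  list(
    "<MEASURE>_<STATE>_REST" = "phase value in the 5-min resting phase",
    "<MEASURE>_<STATE>_REC1..REC3" = "phase value in recovery 1..3",
    "<MEASURE>_<STATE>_AVG" = "mean over the three recovery phases",
    "<MEASURE>_<STATE>_MIN" = "minimum over the three recovery phases",
    "<MEASURE>_<STATE>_N_AVG" = "resting value / mean recovery value",
    "<MEASURE>_<STATE>_N_MIN" = "resting value / minimum recovery value",
    "<MEASURE>_DIF_<VARIANT>" =
      "percent relative change of the variant, fatigued vs rested state",
    MEASURES = c("SDNN", "RMSSD", "PAT (blood-pressure-normalized)", "HR"),
    STATES = c("RS (rested)", "PFS (physically fatigued)"))
}
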