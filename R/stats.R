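#' Rested-vs-fatigued change summary for one parameter
#'
#' Summarizes paired rested-state (RS) and fatigued-state (PFS) values as
#' group means with SDs, the between-state difference under one of two
#' conventions, and a paired t-test.  Parameters measured on their own
#' percent scale (the fatigue-questionnaire score) use percentage points
#' (`mean_PFS - mean_RS`); everything else uses relative percent
#' (`100 * (mean_PFS - mean_RS) / mean_RS`).  Values are kept at full
#' precision; rounding to one decimal happens only at report time.
#'
#' @param rs,pfs Paired numeric vectors (equal length, same subjects).
#' @param convention `"relative_percent"` (default) or
#'   `"percentage_points"`.
#' @param parameter Optional parameter name carried into the output.
#' @param subgroup Optional subgroup tag (`"A"`, `"F"`, `"M"`).
#' @return One-row data frame: `parameter`, `subgroup`, `rs_mean`, `rs_sd`,
#'   `pfs_mean`, `pfs_sd`, `dif`, `convention`, `t`, `p_value`,
#'   `significant` (at 0.05; `NA` when the test is degenerate).
#' @examples
#' change_summary(c(90, 100, 110), c(100, 108, 119))
#' @export
change_summary <- function(rs, pfs,
                           convention = c("relative_percent",
                                          "percentage_points"),
                           parameter = NA_character_,
                           subgroup = NA_character_) {
  convention <- match.arg(convention)
  if (length(rs) != length(pfs) || length(rs) == 0L) {
    stop("'rs' and 'pfs' must be paired, non-empty and of equal length")
  }
  m_rs <- mean(rs); m_pfs <- mean(pfs)
  if (convention == "relative_percent") {
    if (m_rs == 0) stop("zero rested-state mean: relative change undefined")
    dif <- 100 * (m_pfs - m_rs) / m_rs
  } else {
    dif <- m_pfs - m_rs
  }
  tt <- tryCatch(paired_t_test(rs, pfs), error = function(e) NULL)
  data.frame(parameter = parameter, subgroup = subgroup,
             rs_mean = m_rs, rs_sd = stats::sd(rs),
             pfs_mean = m_pfs, pfs_sd = stats::sd(pfs),
             dif = dif, convention = convention,
             t = if (is.null(tt)) NA_real_ else tt["t"],
             p_value = if (is.null(tt)) NA_real_ else tt["p"],
             significant = if (is.null(tt)) NA else tt["p"] < 0.05,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided paired t-test
#'
#' Thin wrapper around [stats::t.test()] on the paired differences, with an
#' explicit error (rather than a spurious p-value) when the differences
#' have zero variance.
#'
#' @param rs,pfs Paired numeric vectors.
#' @return Named numeric `c(t, p)`; `t` is for PFS - RS.
#' @export
paired_t_test <- function(rs, pfs) {
  if (length(rs) != length(pfs) || length(rs) < 2L) {
    stop("need >= 2 pairs")
  }
  d <- pfs - rs
  if (stats::sd(d) == 0) {
    stop("paired differences have zero variance: t-test degenerate")
  }
  ht <- stats::t.test(d)
  c(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Pairwise Pearson correlation matrix of per-subject changes
#'
#' Pearson coefficients between every pair of columns, with pairwise
#' deletion of missing values.  A pair with fewer than 3 complete subjects,
#' or a constant column, yields `NA`.  A logical highlight mask marks
#' |R| > 0.5, mirroring the convention of bolding strong correlations in
#' summary tables.  No multiple-testing correction is applied.
#'
#' @param changes Data frame or matrix, subjects x parameters.
#' @return Correlation matrix with unit diagonal and attribute
#'   `"highlight"` (logical matrix, `|R| > 0.5`, `NA` off the defined set).
#' @export
correlation_matrix <- function(changes) {
  x <- as.matrix(changes)
  p <- ncol(x)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  diag(r) <- 1
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i) next
      ok <- stats::complete.cases(x[, c(i, j)])
      if (sum(ok) < 3L) next
      xi <- x[ok, i]; xj <- x[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      r[i, j] <- r[j, i] <- stats::cor(xi, xj)
    }
  }
  attr(r, "highlight") <- abs(r) > 0.5 & row(r) != col(r)
  r
}

#' Aggregation helpers for administered reference tests
#'
#' Hand-grip strength is scored as the mean of the maxima of five maximal
#' voluntary contractions; CMJ performance as the mean height over the five
#' jump repetitions.
#'
#' @param maxima Numeric vector of per-repetition maximal forces (N).
#' @return The summary value.
#' @export
grip_strength_score <- function(maxima) {
  if (length(maxima) == 0L) stop("no repetitions supplied")
  mean(maxima)
}

#' @rdname grip_strength_score
#' @param heights Numeric vector of per-jump heights (cm).
#' @export
cmj_height_score <- function(heights) {
  if (length(heights) == 0L) stop("no jumps supplied")
  mean(heights)
}

#' Per-subject percent changes of the test-battery parameters
#'
#' Builds the subjects x parameters table of relative changes (percent,
#' PFS vs RS) that feeds [correlation_matrix()]: questionnaire score,
#' reaction time, grip force, CMJ height from the reference table, and
#' SDNN, RMSSD, normalized PAT (resting phase) and HR (resting HR vs mean
#' cycling HR) from the measures table.
#'
#' @param reference Long reference table (`subject_id`, `state`, `q_score`,
#'   `rt_ms`, `grip_n`, `cmj_cm`).
#' @param measures Cohort measures table from [cohort_measures()]
#'   (needs `cycling_hr`).
#' @return Data frame, one row per subject, columns `Q`, `RT`, `DYN`,
#'   `CMJ`, `SDNN`, `RMSSD`, `PAT`, `HR`.
#' @export
parameter_changes <- function(reference, measures) {
  ids <- unique(reference$subject_id)
  rel <- function(rs, pfs) if (length(rs) && length(pfs) && is.finite(rs) &&
                                is.finite(pfs) && rs != 0)
    100 * (pfs - rs) / rs else NA_real_
  rows <- lapply(ids, function(sid) {
    rr <- reference[reference$subject_id == sid & reference$state == "RS", ]
    rp <- reference[reference$subject_id == sid & reference$state == "PFS", ]
    mr <- measures[measures$subject_id == sid & measures$state == "RS" &
                     measures$phase_id == "resting", ]
    mp <- measures[measures$subject_id == sid & measures$state == "PFS" &
                     measures$phase_id == "resting", ]
    hr_cyc_rs <- unique(measures$cycling_hr[
      measures$subject_id == sid & measures$state == "RS"])
    data.frame(
      subject_id = sid,
      Q = rp$q_score - rr$q_score,   # questionnaire: percentage points
      RT = rel(rr$rt_ms, rp$rt_ms),
      DYN = rel(rr$grip_n, rp$grip_n),
      CMJ = rel(rr$cmj_cm, rp$cmj_cm),
      SDNN = rel(mr$sdnn, mp$sdnn),
      RMSSD = rel(mr$rmssd, mp$rmssd),
      PAT = rel(mr$pat_norm, mp$pat_norm),
      HR = rel(mr$hr, hr_cyc_rs[1]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regenerate the cohort summary tables
#'
#' Produces, from any cohort's reference and measures tables, the standard
#' summary layouts: mean +/- SD per state and subgroup (whole group A,
#' female F, male M) with the between-state difference and paired-test
#' significance per parameter.
#'
#' @param reference Long reference table (see [parameter_changes()]).
#' @param measures Cohort measures table.
#' @param profiles Profile table with `subject_id` and `sex`.
#' @return A list with data frames `reference` and `cardiovascular`, one
#'   row per parameter x subgroup.
#' @export
summary_tables <- function(reference, measures, profiles) {
  sub_ids <- list(A = profiles$subject_id,
                  F = profiles$subject_id[profiles$sex == "F"],
                  M = profiles$subject_id[profiles$sex == "M"])
  ref_par <- c(Q = "q_score", RT = "rt_ms", DYN = "grip_n", CMJ = "cmj_cm")
  ref_rows <- NULL
  for (p in names(ref_par)) {
    for (s in names(sub_ids)) {
      ids <- sub_ids[[s]]
      if (length(ids) < 2L) next
      rs <- vapply(ids, function(i) reference[[ref_par[[p]]]][
        reference$subject_id == i & reference$state == "RS"][1], numeric(1))
      pfs <- vapply(ids, function(i) reference[[ref_par[[p]]]][
        reference$subject_id == i & reference$state == "PFS"][1], numeric(1))
      conv <- if (p == "Q") "percentage_points" else "relative_percent"
      ref_rows <- rbind(ref_rows,
                        change_summary(rs, pfs, conv, parameter = p,
                                       subgroup = s))
    }
  }
  cv_col <- c(HR = "hr", SDNN = "sdnn", RMSSD = "rmssd", PAT = "pat_norm")
  cv_rows <- NULL
  for (p in names(cv_col)) {
    for (s in names(sub_ids)) {
      ids <- sub_ids[[s]]
      if (length(ids) < 2L) next
      pick <- function(state) vapply(ids, function(i) {
        measures[[cv_col[[p]]]][measures$subject_id == i &
                                  measures$state == state &
                                  measures$phase_id == "resting"][1]
      }, numeric(1))
      rs <- pick("RS"); pfs <- pick("PFS")
      ok <- is.finite(rs) & is.finite(pfs)
      if (sum(ok) < 2L) next
      cv_rows <- rbind(cv_rows,
                       change_summary(rs[ok], pfs[ok], "relative_percent",
                                      parameter = p, subgroup = s))
    }
  }
  list(reference = ref_rows, cardiovascular = cv_rows)
}
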